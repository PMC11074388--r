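# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# ratio of atomic masses N/C; converts a mass C:N ratio to an atomic one
CN_ATOMIC_FACTOR <- 14.007 / 12.011

stop_bi <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bi(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    stop_bi(sprintf("'%s' must be > 0", name))
  invisible(x)
}

# FNV-1a 32-bit hash of a character scalar; used to fingerprint run configs
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); bitwXor cannot take h > 2^31
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, split into 16-bit
    # halves so every intermediate stays inside exact double-integer range
    h <- ((h %/% 65536 * 16777619) %% 65536 * 65536 + h %% 65536 * 16777619) %%
      4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Draw n points from N(mu, Sigma) via Cholesky; internal use (tests, bayes checks)
rmvnorm2 <- function(n, mu, Sigma) {
  z <- matrix(stats::rnorm(2L * n), ncol = 2L)
  sweep(z %*% chol(Sigma), 2L, mu, `+`)
}
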
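# Shared fixtures and independent oracles, built in code at test time.

# A plate whose isotopes are explicit functions of the time coordinate
# (t = 0 at the distal tip, i.e. oldest growth).
make_series <- function(n = 90, f13 = function(t) -24 + sin(2 * pi * t / 15),
                        f15 = function(t) 6.6 + 0.5 * sin(2 * pi * t / 15),
                        plate_id = "T01", species = "blue", spacing = 1) {
  position <- (seq_len(n) - 1) * spacing
  t <- max(position) - position
  baleen_series(plate_id, species,
                data.frame(position_cm = position, d13C = f13(t), d15N = f15(t)))
}

# Brute-force oracle for the Gaussian low-pass: explicit double loop over a
# kernel of radius 4*sigma with index folding for the reflective boundary.
oracle_gaussian_lowpass <- function(x, sigma, spacing = 1) {
  n <- length(x)
  r <- ceiling(4 * sigma / spacing)
  w <- dnorm(seq(-r, r) * spacing, sd = sigma)
  w <- w / sum(w)
  reflect <- function(i) {
    period <- 2 * n - 2
    j <- (i - 1) %% period
    if (j >= n) j <- period - j
    j + 1
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in -r:r) acc <- acc + w[k + r + 1] * x[reflect(i + k)]
    out[i] <- acc
  }
  out
}

# Correlated bivariate normal sample (Cholesky), for niche oracles.
draw_mvn <- function(n, mu, Sigma) {
  z <- matrix(rnorm(2 * n), ncol = 2)
  sweep(z %*% chol(Sigma), 2, mu, `+`)
}
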
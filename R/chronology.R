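#' Gaussian low-pass detrending of an isotope series
#'
#' Separates a series into a slow trend (Gaussian-kernel moving average with
#' reflective edge handling) and residuals carrying the annual oscillation.
#' The kernel SD should sit between the annual wavelength and the multi-year
#' drift one wants to remove; the package default of 8 cm is roughly half the
#' expected annual wavelength for both species, so the annual cycle passes
#' into the residuals while slower drift is absorbed by the trend.
#'
#' Interior \code{NA} gaps are linearly interpolated before filtering (and
#' flagged in the result); leading or trailing gaps are an error. Residuals
#' plus trend reconstruct the (gap-filled) input exactly.
#'
#' @param values numeric series on a regular grid (>= 8 samples), ordered in
#'   time (oldest first); use \code{\link{time_order}}.
#' @param sigma_cm kernel SD in cm (> 0); the series must span at least
#'   \code{2 * sigma_cm}.
#' @param spacing_cm grid spacing in cm (default 1).
#' @param positions optional time coordinates (cm), oldest first; defaults to
#'   \code{0, spacing, 2*spacing, ...}.
#' @return object of class \code{detrended_series} with elements
#'   \code{positions}, \code{values} (gap-filled input), \code{residuals},
#'   \code{trend}, \code{filter_sigma_cm}, \code{interpolated}.
#' @export
detrend_gaussian <- function(values, sigma_cm = 8, spacing_cm = 1,
                             positions = NULL) {
  assert_scalar_num(sigma_cm, "sigma_cm", positive = TRUE)
  n <- length(values)
  if (n < 8L) stop_bi("detrend_gaussian: need at least 8 samples")
  if (is.null(positions)) positions <- (seq_len(n) - 1) * spacing_cm
  if (diff(range(positions)) < 2 * sigma_cm)
    stop_bi("detrend_gaussian: series shorter than 2 * sigma_cm")
  interpolated <- is.na(values)
  if (any(interpolated)) {
    if (is.na(values[1L]) || is.na(values[n]))
      stop_bi("detrend_gaussian: leading/trailing gaps cannot be interpolated")
    values <- stats::approx(positions[!interpolated], values[!interpolated],
                            xout = positions)$y
  }
  r <- ceiling(4 * sigma_cm / spacing_cm)
  w <- stats::dnorm(seq(-r, r) * spacing_cm, sd = sigma_cm)
  w <- w / sum(w)
  # reflective padding about the end samples (edge sample not repeated);
  # indices are folded so kernels wider than the series still reflect properly
  idx <- seq(1L - r, n + r)
  j <- (idx - 1L) %% (2L * n - 2L)
  j <- ifelse(j >= n, 2L * n - 2L - j, j)
  padded <- values[j + 1L]
  trend <- vapply(seq_len(n), function(i) sum(w * padded[i:(i + 2L * r)]),
                  numeric(1))
  structure(list(positions = positions, values = values,
                 residuals = values - trend, trend = trend,
                 filter_sigma_cm = sigma_cm, spacing_cm = spacing_cm,
                 interpolated = interpolated),
            class = "detrended_series")
}

#' @export
print.detrended_series <- function(x, ...) {
  cat(sprintf("<detrended_series> %d samples, Gaussian sigma %.1f cm, residual SD %.3f\n",
              length(x$residuals), x$filter_sigma_cm, stats::sd(x$residuals)))
  invisible(x)
}

#' Estimate the dominant cycle length of a detrended series
#'
#' Computes the FFT periodogram of the zero-mean residuals (zero-padded to at
#' least four times the series length, rounded up to a power of two) and takes
#' the in-band power maximum as the annual cycle; the peak frequency is
#' converted to cm/cycle as 1/frequency. Ties break toward the lower
#' frequency (longer cycle). A parabolic interpolation over the peak and its
#' neighbouring bins refines the frequency below bin resolution.
#'
#' The peak is flagged low-confidence when its power is less than
#' \code{power_ratio_threshold} times the median in-band power. The median
#' is used as the noise-floor reference because a genuine oscillation
#' concentrates power in one spectral lobe (leaving the median at the
#' sidelobe floor), whereas a white-noise periodogram rarely exceeds about
#' ten times its median; the default threshold of 10 separates the two
#' regimes. All-zero residuals give a "no cycle" result rather than an
#' error.
#'
#' @param d a \code{\link{detrend_gaussian}} result.
#' @param band_cm numeric length-2: admissible wavelength window in cm
#'   (default \code{c(8, 30)}, bracketing plausible annual growth).
#' @param pad_factor zero-padding factor (default 4).
#' @param power_ratio_threshold low-confidence threshold on
#'   peak power / median in-band power (default 10).
#' @param refine logical: parabolic sub-bin refinement of the peak.
#' @return object of class \code{spectral_estimate}: \code{peak_frequency}
#'   (cycles/cm), \code{cycle_length_cm} (= 1/peak_frequency), \code{n_cycles}
#'   (floor of span / cycle length), \code{power_spectrum} (in-band data
#'   frame), \code{power_ratio}, \code{low_confidence}, \code{no_cycle},
#'   \code{bin_width_cm} (wavelength resolution of the padded grid at the
#'   peak), and \code{isotope_used} (filled by \code{\link{plate_chronology}}).
#' @export
estimate_cycle_length <- function(d, band_cm = c(8, 30), pad_factor = 4,
                                  power_ratio_threshold = 10, refine = TRUE) {
  stopifnot(inherits(d, "detrended_series"))
  if (length(band_cm) != 2L || !all(is.finite(band_cm)) || band_cm[1] >= band_cm[2] ||
      band_cm[1] <= 0)
    stop_bi("estimate_cycle_length: 'band_cm' must be an increasing positive pair")
  r <- d$residuals - mean(d$residuals)
  n <- length(r)
  spacing <- d$spacing_cm
  span <- diff(range(d$positions))
  if (span < 2 * band_cm[1])
    stop_bi("estimate_cycle_length: series shorter than two cycles of the shortest band wavelength")
  est <- structure(list(peak_frequency = NA_real_, cycle_length_cm = NA_real_,
                        n_cycles = NA_integer_, power_spectrum = NULL,
                        power_ratio = NA_real_, low_confidence = TRUE,
                        no_cycle = TRUE, bin_width_cm = NA_real_,
                        isotope_used = NA_character_, span_cm = span),
                   class = "spectral_estimate")
  if (max(abs(r)) < 1e-12) return(est)

  npad <- 2^ceiling(log2(pad_factor * n))
  P <- Mod(stats::fft(c(r, rep(0, npad - n))))^2 / n
  k <- seq_len(floor(npad / 2))            # skip the zero-frequency term
  freq <- k / (npad * spacing)
  wl <- 1 / freq
  inband <- which(wl >= band_cm[1] & wl <= band_cm[2])
  if (!length(inband)) stop_bi("estimate_cycle_length: empty wavelength band")
  pow <- P[k + 1L]
  spectrum <- data.frame(frequency = freq[inband], wavelength_cm = wl[inband],
                         power = pow[inband])
  # k ascending => first maximum is the lowest in-band frequency (longest cycle)
  pk_local <- which(spectrum$power == max(spectrum$power))[1L]
  pk <- inband[pk_local]
  power_ratio <- spectrum$power[pk_local] / stats::median(spectrum$power)
  k_star <- k[pk]
  if (refine && pk > 1L && pk < length(k)) {
    p0 <- pow[pk - 1L]; p1 <- pow[pk]; p2 <- pow[pk + 1L]
    den <- p0 - 2 * p1 + p2
    if (is.finite(den) && den < 0)
      k_star <- k[pk] + 0.5 * (p0 - p2) / den
  }
  f_star <- k_star / (npad * spacing)
  lam <- 1 / f_star
  lam <- min(max(lam, band_cm[1]), band_cm[2])
  est$peak_frequency <- 1 / lam
  est$cycle_length_cm <- lam
  est$n_cycles <- as.integer(floor(span / lam))
  est$power_spectrum <- spectrum
  est$power_ratio <- power_ratio
  est$low_confidence <- power_ratio < power_ratio_threshold
  est$no_cycle <- FALSE
  est$bin_width_cm <- lam^2 / (npad * spacing)
  est
}

#' @export
print.spectral_estimate <- function(x, ...) {
  if (x$no_cycle) {
    cat("<spectral_estimate> no cycle detected (flat residuals)\n")
  } else {
    cat(sprintf("<spectral_estimate> cycle length %.2f cm/cycle (%s%d cycles, power ratio %.1f%s)\n",
                x$cycle_length_cm,
                if (is.na(x$isotope_used)) "" else paste0(x$isotope_used, ", "),
                x$n_cycles, x$power_ratio,
                if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  }
  invisible(x)
}

#' Per-plate chronology: detrend and estimate the annual cycle
#'
#' Runs \code{\link{detrend_gaussian}} and \code{\link{estimate_cycle_length}}
#' on a plate's time-ordered record. Nitrogen is the default cycle-detection
#' isotope because its annual cycles are usually better resolved in baleen;
#' when its spectral peak is low-confidence (or flat) and \code{fallback} is
#' \code{TRUE}, the carbon series is tried and used if it does better.
#'
#' @param series a \code{\link{baleen_series}}.
#' @param isotope primary isotope for cycle detection.
#' @param sigma_cm Gaussian filter SD (cm).
#' @param band_cm admissible wavelength window (cm).
#' @param fallback try the other isotope when the primary peak is weak.
#' @param n_cycles_override optional manually counted number of cycles
#'   (peak-to-peak visual counts), replacing the span-based count.
#' @param ... passed to \code{\link{estimate_cycle_length}}.
#' @return a \code{spectral_estimate} with \code{isotope_used} and
#'   \code{plate_id} filled.
#' @export
plate_chronology <- function(series, isotope = c("d15N", "d13C"),
                             sigma_cm = 8, band_cm = c(8, 30),
                             fallback = TRUE, n_cycles_override = NULL, ...) {
  stopifnot(inherits(series, "baleen_series"))
  isotope <- match.arg(isotope)
  to <- time_order(series)
  run <- function(iso) {
    d <- detrend_gaussian(to[[iso]], sigma_cm = sigma_cm,
                          spacing_cm = stats::median(diff(to$time_cm)),
                          positions = to$time_cm)
    est <- estimate_cycle_length(d, band_cm = band_cm, ...)
    est$isotope_used <- iso
    est
  }
  est <- run(isotope)
  if ((est$low_confidence || est$no_cycle) && fallback) {
    other <- setdiff(c("d15N", "d13C"), isotope)
    alt <- run(other)
    if (!alt$no_cycle &&
        (est$no_cycle || (is.finite(alt$power_ratio) && alt$power_ratio > est$power_ratio)))
      est <- alt
  }
  if (!is.null(n_cycles_override)) est$n_cycles <- as.integer(n_cycles_override)
  est$plate_id <- series$plate_id
  est
}

#' Growth-rate estimates for every plate of a cohort
#'
#' @param cohort list of \code{\link{baleen_series}}.
#' @param ... passed to \code{\link{plate_chronology}}.
#' @return data frame with one row per plate: \code{plate_id}, \code{species},
#'   \code{cycle_length_cm}, \code{n_cycles}, \code{power_ratio},
#'   \code{low_confidence}, \code{isotope_used}, \code{span_cm},
#'   \code{years}, \code{years_rounded}.
#' @export
cohort_growth_rates <- function(cohort, ...) {
  rows <- lapply(cohort, function(b) {
    est <- plate_chronology(b, ...)
    yr <- years_represented(b, est)
    data.frame(plate_id = b$plate_id, species = b$species,
               cycle_length_cm = est$cycle_length_cm,
               n_cycles = est$n_cycles,
               power_ratio = est$power_ratio,
               low_confidence = est$low_confidence,
               isotope_used = est$isotope_used,
               span_cm = est$span_cm,
               years = yr$years, years_rounded = yr$years_rounded,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species-average baleen growth rate
#'
#' Averages per-individual growth rates (cm/cycle = cm/yr) over the
#' individuals with at least \code{min_cycles} annual cycles; individuals
#' with fewer cycles are reported as excluded. The SD uses the sample (n-1)
#' denominator and is \code{NA} when only one individual qualifies.
#'
#' @param rates numeric per-individual rates (cm/yr), or a data frame with
#'   columns \code{rate} (or \code{cycle_length_cm}) and \code{n_cycles}.
#' @param n_cycles integer cycle counts, parallel to \code{rates}.
#' @param individuals optional identifiers, parallel to \code{rates}.
#' @param min_cycles minimum annual cycles to qualify (default 3).
#' @return object of class \code{growth_rate_summary}: \code{rates},
#'   \code{mean}, \code{sd}, \code{n_individuals}, \code{excluded},
#'   \code{min_cycles}.
#' @examples
#' species_growth_rate(c(15.20, 13.50), c(5, 6))   # 14.35 +/- 1.20
#' @export
species_growth_rate <- function(rates, n_cycles, individuals = NULL,
                                min_cycles = 3L) {
  if (is.data.frame(rates)) {
    df <- rates
    rcol <- if ("rate" %in% names(df)) "rate" else "cycle_length_cm"
    individuals <- individuals %||% df$plate_id %||% as.character(seq_len(nrow(df)))
    n_cycles <- df$n_cycles
    rates <- df[[rcol]]
  }
  if (length(rates) != length(n_cycles))
    stop_bi("species_growth_rate: 'rates' and 'n_cycles' lengths differ")
  individuals <- individuals %||% as.character(seq_along(rates))
  qualify <- !is.na(rates) & !is.na(n_cycles) & n_cycles >= min_cycles
  if (!any(qualify))
    stop_bi(sprintf(
      "species_growth_rate: no individual with >= %d cycles (cycle counts: %s)",
      min_cycles, paste(individuals, n_cycles, sep = "=", collapse = ", ")))
  r <- rates[qualify]
  structure(list(
    rates = r, individuals = individuals[qualify],
    mean = mean(r), sd = if (length(r) > 1L) stats::sd(r) else NA_real_,
    n_individuals = length(r),
    excluded = data.frame(individual = individuals[!qualify],
                          n_cycles = n_cycles[!qualify],
                          stringsAsFactors = FALSE),
    min_cycles = min_cycles),
    class = "growth_rate_summary")
}

#' @export
print.growth_rate_summary <- function(x, ...) {
  cat(sprintf("<growth_rate_summary> %.2f +/- %s cm/yr over %d individuals (>= %d cycles)\n",
              x$mean, if (is.na(x$sd)) "NA" else sprintf("%.2f", x$sd),
              x$n_individuals, x$min_cycles))
  if (nrow(x$excluded))
    cat("  excluded:", paste(x$excluded$individual, x$excluded$n_cycles,
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Years of growth represented by a plate
#'
#' Plate span divided by the annual cycle length; the rounded value is the
#' headline figure, the exact ratio is retained.
#'
#' @param series a \code{\link{baleen_series}}.
#' @param est a \code{spectral_estimate} with a valid cycle length.
#' @return list with \code{years} (exact) and \code{years_rounded}.
#' @export
years_represented <- function(series, est) {
  span <- diff(range(series$samples$position_cm))
  lam <- est$cycle_length_cm
  if (is.null(lam) || is.na(lam))
    return(list(years = NA_real_, years_rounded = NA_integer_))
  list(years = span / lam, years_rounded = as.integer(round(span / lam)))
}
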
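test_that("Gaussian detrend matches the brute-force convolution oracle", {
  set.seed(3)
  x <- -24 + sin(2 * pi * (0:89) / 15) + 0.02 * (0:89) + rnorm(90, 0, 0.2)
  d <- detrend_gaussian(x, sigma_cm = 8)
  expect_equal(d$trend, oracle_gaussian_lowpass(x, 8), tolerance = 1e-12)
  expect_equal(d$residuals + d$trend, x, tolerance = 1e-9)
})

test_that("detrending preserves constants and nearly annihilates linear ramps", {
  d <- detrend_gaussian(rep(5.5, 40), sigma_cm = 8)
  expect_true(all(abs(d$residuals) < 1e-12))

  ramp <- 0.05 * (0:79)
  dr <- detrend_gaussian(ramp, sigma_cm = 8)
  interior <- 33:48                               # beyond one kernel radius
  expect_true(all(abs(dr$residuals[interior]) < 0.02))

  t <- 0:89
  x <- sin(2 * pi * t / 15) + 0.03 * t
  ds <- detrend_gaussian(x, sigma_cm = 8)
  inner <- 33:58
  expect_gt(cor(ds$residuals[inner], sin(2 * pi * t[inner] / 15)), 0.98)
})

test_that("detrend validates its inputs and interpolates interior gaps", {
  expect_error(detrend_gaussian(rnorm(40), sigma_cm = 0), "> 0")
  expect_error(detrend_gaussian(rnorm(5), sigma_cm = 2), "at least 8")
  expect_error(detrend_gaussian(rnorm(10), sigma_cm = 8), "shorter than 2")

  x <- sin(2 * pi * (0:59) / 15)
  x[20] <- NA
  d <- detrend_gaussian(x, sigma_cm = 8)
  expect_true(d$interpolated[20])
  expect_equal(d$values[20], (x[19] + x[21]) / 2, tolerance = 1e-9)
  x[1] <- NA
  expect_error(detrend_gaussian(x, sigma_cm = 8), "leading/trailing")
})

test_that("periodogram peak finds a pure sine exactly at its FFT bin", {
  # n = 90, lambda = 15: k = 6 of the unpadded grid, an exact bin; padding
  # and parabolic refinement must stay within one padded bin of 15.0
  t <- 0:89
  d <- detrend_gaussian(sin(2 * pi * t / 15), sigma_cm = 8)
  est <- estimate_cycle_length(d)
  expect_lt(abs(est$cycle_length_cm - 15), est$bin_width_cm)
  expect_identical(est$cycle_length_cm, 1 / est$peak_frequency)
  expect_equal(est$n_cycles, floor(89 / est$cycle_length_cm))
  expect_false(est$low_confidence)
  expect_false(est$no_cycle)
})

test_that("flat residuals give a no-cycle result, white noise a low-confidence flag", {
  d0 <- detrend_gaussian(rep(1.25, 64), sigma_cm = 8)
  est0 <- estimate_cycle_length(d0)
  expect_true(est0$no_cycle)
  expect_true(is.na(est0$cycle_length_cm))

  flagged <- vapply(1:200, function(i) {
    set.seed(i)
    d <- detrend_gaussian(rnorm(80), sigma_cm = 8)
    estimate_cycle_length(d)$low_confidence
  }, logical(1))
  expect_gt(mean(flagged), 0.9)

  expect_error(estimate_cycle_length(d0, band_cm = c(5, 4)), "band")
})

test_that("cycle estimate is invariant to constant offsets and linear trends", {
  t <- 0:89
  base <- sin(2 * pi * t / 14)
  est0 <- estimate_cycle_length(detrend_gaussian(base, 8))
  lam0 <- est0$cycle_length_cm
  # a constant offset is removed exactly (zero-mean periodogram)
  lam_c <- estimate_cycle_length(detrend_gaussian(base + 3.7, 8))$cycle_length_cm
  expect_identical(lam_c, lam0)
  # linear trends are absorbed by the low-pass up to edge effects, which may
  # move the refined peak by a small fraction of a frequency bin
  for (shift in list(0.05 * t, 2 - 0.04 * t)) {
    lam <- estimate_cycle_length(detrend_gaussian(base + shift, 8))$cycle_length_cm
    expect_lt(abs(lam - lam0), est0$bin_width_cm / 2)
  }
})

test_that("lower noise gives a monotonically stronger spectral peak", {
  ratios <- vapply(c(0.8, 0.4, 0.2, 0.05), function(sd) {
    cfg <- synthetic_config(15, 90, d15N_amplitude = 0.5, noise_sd_N = sd,
                            seed = 7)
    b <- simulate_series(cfg)
    to <- time_order(b)
    estimate_cycle_length(detrend_gaussian(to$d15N, 8))$power_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("simulated-plate recovery stays within one padded-FFT bin (median)", {
  set.seed(13)
  errs <- vapply(1:30, function(i) {
    lam <- runif(1, 12, 20)
    cfg <- synthetic_config(lam, 90, d15N_amplitude = 0.5,
                            noise_sd_N = runif(1, 0, 0.4),
                            seed = sample.int(1e6, 1))
    est <- plate_chronology(simulate_series(cfg))
    stopifnot(est$cycle_length_cm >= 8, est$cycle_length_cm <= 30)
    abs(est$cycle_length_cm - lam) / est$bin_width_cm
  }, numeric(1))
  expect_lte(median(errs), 1)
})

test_that("species growth-rate aggregation uses only qualifying individuals", {
  blue <- species_growth_rate(c(15.20, 13.50), c(5, 6))
  expect_equal(blue$mean, 14.35)
  expect_equal(blue$sd, 1.20, tolerance = 0.005)

  fin <- species_growth_rate(c(16.25, 14.80, 18.50), c(4, 5, 4))
  expect_equal(fin$mean, 16.52, tolerance = 0.005)
  expect_equal(fin$sd, 1.86, tolerance = 0.005)

  mixed <- species_growth_rate(c(15.20, 12.0, 13.50), c(5, 2, 6),
                               individuals = c("a", "b", "c"))
  expect_equal(mixed$n_individuals, 2)
  expect_equal(mixed$excluded$individual, "b")
  expect_equal(mixed$mean, 14.35)

  single <- species_growth_rate(16.25, 4)
  expect_equal(single$mean, 16.25)
  expect_true(is.na(single$sd))

  err <- expect_error(species_growth_rate(c(15, 16), c(1, 2)))
  expect_match(conditionMessage(err), "1")
  expect_match(conditionMessage(err), "2")
})

test_that("years represented divide span by cycle length", {
  b86 <- make_series(n = 87)                      # span 86 cm
  expect_equal(years_represented(b86, list(cycle_length_cm = 14.35))$years_rounded, 6)
  b72 <- make_series(n = 73)                      # span 72 cm
  expect_equal(years_represented(b72, list(cycle_length_cm = 16.52))$years_rounded, 4)
  blam <- make_series(n = 16)                     # span 15 = one wavelength
  expect_equal(years_represented(blam, list(cycle_length_cm = 15))$years_rounded, 1)
  expect_equal(years_represented(blam, list(cycle_length_cm = 15))$years, 1)
})
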
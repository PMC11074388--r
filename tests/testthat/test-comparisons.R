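test_that("Mann-Whitney W and exact p match rank-assignment enumeration", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_identical(r$statistic_W, 0)
  # enumeration oracle: all C(4,2) assignments of ranks to the first group;
  # two-sided p doubles the tail probability of the observed U = 0
  Ws <- apply(combn(4, 2), 2, function(idx) sum(idx) - 3)
  expect_equal(r$p_value, 2 * mean(Ws <= 0), tolerance = 1e-12)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_true(r$exact)

  # one value above all others: W = rank sum - min rank sum
  r2 <- mann_whitney(5, c(1, 2, 3))
  expect_identical(r2$statistic_W, 3)

  # identical multisets: midranks give W = n^2 / 2
  x <- c(1.5, 2.5, 7, 9)
  r3 <- mann_whitney(x, x)
  expect_identical(r3$statistic_W, 16 / 2)

  expect_warning(r4 <- mann_whitney(rep(3, 4), rep(3, 6)), "identical")
  expect_identical(r4$p_value, 1)
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(17)
  a <- rnorm(15); b <- rnorm(20, 0.5)
  base <- mann_whitney(a, b)
  for (tf in list(function(x) x^3, function(x) exp(x),
                  function(x) atan(x) * 10)) {
    tr <- mann_whitney(tf(a), tf(b))
    expect_identical(tr$statistic_W, base$statistic_W)
    expect_equal(tr$p_value, base$p_value, tolerance = 1e-12)
  }
})

test_that("distribution screening routes by normality and variance checks", {
  set.seed(23)
  rejections <- vapply(1:100, function(i) {
    set.seed(i)
    x <- rnorm(200)
    shapiro.test(x)$p.value < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.10)              # type-I calibration

  set.seed(29)
  gaussians <- data.frame(v = c(rnorm(200), rnorm(200, 1)),
                          g = rep(c("a", "b"), each = 200))
  sg <- screen_distributions(gaussians$v, gaussians$g)
  expect_true(all(sg$per_group$note == ""))

  heavy <- data.frame(v = c(rt(200, df = 1), rnorm(200)),
                      g = rep(c("a", "b"), each = 200))
  sh <- screen_distributions(heavy$v, heavy$g)
  expect_identical(sh$routing, "rank")

  const <- screen_distributions(c(rep(1, 10), rnorm(10)),
                                rep(c("a", "b"), each = 10))
  expect_match(const$per_group$note[1], "constant")
})

test_that("cross-correlation peaks where the signals align", {
  t <- 0:79
  x <- sin(2 * pi * t / 16)
  self <- ccf_series(x, x, max_lag = 10)
  expect_identical(self$peak_lag, 0L)
  expect_equal(self$peak_r, 1, tolerance = 1e-12)
  anti <- ccf_series(x, -x, max_lag = 10)
  expect_equal(anti$peak_r, -1, tolerance = 1e-12)
  expect_identical(anti$classification, "negative")

  # y lags x by a quarter wavelength (4 cm)
  y <- sin(2 * pi * (t - 4) / 16)
  lagged <- ccf_series(x, y, max_lag = 8)
  expect_identical(lagged$peak_lag, 4L)
  swapped <- ccf_series(y, x, max_lag = 8)
  expect_identical(swapped$peak_lag, -4L)

  expect_error(ccf_series(x, rep(1, 80), max_lag = 10), "zero-variance")
  expect_error(ccf_series(x, x[-1], max_lag = 10), "lengths differ")
  expect_error(ccf_series(x[1:20], x[1:20], max_lag = 10), "exceed")
})

test_that("cross-correlation agrees with stats::ccf on long centered series", {
  set.seed(41)
  n <- 2000
  x <- as.numeric(arima.sim(list(ar = 0.5), n))
  y <- c(x[-(1:3)], rnorm(3)) + rnorm(n, 0, 0.3)
  ours <- ccf_series(x, y, max_lag = 10)
  ref <- stats::ccf(y, x, lag.max = 10, plot = FALSE)   # ccf(y,x): y[t+k] vs x[t]
  expect_equal(ours$correlations, as.numeric(ref$acf), tolerance = 0.02)
  expect_identical(ours$peak_lag, -3L)
})

test_that("plate-aware Breusch-Godfrey matches lmtest on a single plate", {
  set.seed(51)
  y <- as.numeric(arima.sim(list(ar = 0.4), 120))
  ours <- bg_test_panel(y, rep("P1", 120))
  ref <- lmtest::bgtest(lm(y ~ 1), order = 1, fill = 0)
  expect_equal(ours$lm_stat, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("subsampling draws the exact design and is reproducible", {
  co <- simulate_cohort(5, seed = 61)
  ck <- pseudoreplication_check(co, per_plate = 40, n_datasets = 5,
                                seed = 7, refit_niche = FALSE)
  expect_equal(ck$dataset_size, 400)
  expect_length(ck$datasets, 5)
  for (d in ck$datasets) {
    expect_equal(nrow(d), 400)
    expect_true(all(table(d$plate_id) == 40))
    # without replacement: no duplicated positions within a plate
    expect_false(any(duplicated(d[, c("plate_id", "position_cm")])))
  }
  ck2 <- pseudoreplication_check(co, per_plate = 40, n_datasets = 5,
                                 seed = 7, refit_niche = FALSE)
  expect_identical(ck$datasets, ck2$datasets)
  expect_equal(nrow(ck$autocorr), 10)             # 5 datasets x 2 isotopes

  short <- lapply(co[1:2], function(b) {
    b$samples <- b$samples[1:20, ]; b
  })
  w <- capture_warnings(pseudoreplication_check(short, per_plate = 40,
                                                n_datasets = 1, seed = 1,
                                                refit_niche = FALSE))
  expect_true(any(grepl("replacement", w)))
})

test_that("niche refits on subsampled datasets overlap the full-data interval", {
  co <- simulate_cohort(3, seed = 71)
  ck <- pseudoreplication_check(co, per_plate = 30, n_datasets = 2, seed = 5,
                                bayes_args = list(iterations = 2000,
                                                  burn_in = 200, seed = 9))
  expect_equal(nrow(ck$sea_b), 4)                 # 2 datasets x 2 species
  expect_true(all(ck$sea_b$overlaps_full))
})

test_that("region contrast is a two-group Kruskal-Wallis", {
  x <- rnorm(40)
  same <- region_contrast(c(x, x), rep(c("in", "out"), each = 40))
  expect_equal(same$df, 1)
  expect_lt(same$statistic, 0.1)
  expect_gt(same$p_value, 0.7)

  set.seed(83)
  a <- rnorm(50); b <- rnorm(50, 2)
  shifted <- region_contrast(c(a, b), rep(c("in", "out"), each = 50))
  expect_lt(shifted$p_value, 0.01)
  expect_error(region_contrast(a, rep("in", 50)), "two non-empty")
})
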
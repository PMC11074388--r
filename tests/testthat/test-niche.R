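test_that("SEA and SEAc follow their closed forms", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  f <- ellipse_from_moments(c(0, 0), S, n = 10)
  expect_equal(f$SEA, pi * sqrt(0.75), tolerance = 1e-12)
  expect_equal(f$SEA, 2.7207, tolerance = 1e-4)
  expect_equal(f$SEA_C, f$SEA * 9 / 8, tolerance = 1e-12)
  expect_equal(f$SEA_C, 3.0608, tolerance = 1e-4)

  set.seed(5)
  big <- fit_ellipse(draw_mvn(1e5, c(0, 0), diag(2)))
  expect_equal(big$SEA, pi, tolerance = 0.02 * pi)
  expect_equal(big$SEA_C / big$SEA, (1e5 - 1) / (1e5 - 2))

  line <- cbind(1:5, 2 * (1:5))
  expect_error(fit_ellipse(line), "degenerate")
  expect_error(fit_ellipse(cbind(1:2, 1:2)), "at least 3")
})

test_that("SEAc over SEA equals (n-1)/(n-2) for arbitrary fits", {
  set.seed(8)
  for (n in c(4, 7, 23, 100)) {
    f <- fit_ellipse(draw_mvn(n, c(-24, 6.6), matrix(c(1, .3, .3, .5), 2)))
    expect_equal(f$SEA_C / f$SEA, (n - 1) / (n - 2), tolerance = 1e-12)
    expect_gt(f$SEA_C, f$SEA)
  }
})

test_that("Bayesian SEAb is reproducible and consistent with the truth at large n", {
  set.seed(12)
  Sigma <- matrix(c(0.9, 0.3, 0.3, 1.4), 2)
  pts <- draw_mvn(5000, c(-23, 7), Sigma)
  f1 <- fit_ellipse_bayes(pts, iterations = 5000, burn_in = 500, seed = 77)
  f2 <- fit_ellipse_bayes(pts, iterations = 5000, burn_in = 500, seed = 77)
  expect_identical(f1$SEA_B_draws, f2$SEA_B_draws)
  expect_equal(f1$SEA_B_mean, pi * sqrt(det(Sigma)), tolerance = 0.05)
  expect_true(f1$ci95[1] <= f1$SEA_B_mode && f1$SEA_B_mode <= f1$ci95[2])
  expect_equal(length(f1$SEA_B_draws), 2 * length(seq(501, 5000, by = 10)))
})

test_that("posterior mean SEAb matches the conjugate closed form at small n", {
  # for p = 2 the inverse-Wishart IW(nu, Psi) has E[sqrt(det(Sigma))] =
  # sqrt(det(Psi)) / (nu - 2); check both the reference-prior default
  # (nu = n - 1) and an explicit proper NIW prior (nu = nu0 + n)
  set.seed(40)
  pts <- draw_mvn(5, c(0, 0), diag(2))
  S <- 4 * cov(pts)
  f <- fit_ellipse_bayes(pts, iterations = 200000, burn_in = 1000, seed = 3)
  expect_equal(f$SEA_B_mean, pi * sqrt(det(S)) / (5 - 3), tolerance = 0.03)
  # reference-prior small-sample inflation: E[SEAb] = SEA * (n-1)/(n-3)
  base <- fit_ellipse(pts)
  expect_equal(f$SEA_B_mean / base$SEA, (5 - 1) / (5 - 3), tolerance = 0.03)
  expect_gt(f$SEA_B_mean, base$SEA)

  fp <- fit_ellipse_bayes(pts, iterations = 200000, burn_in = 1000, seed = 3,
                          prior = list(nu0 = 3, psi0_scale = 1e-3))
  Psi_n <- 1e-3 * diag(2) + S
  expect_equal(fp$SEA_B_mean, pi * sqrt(det(Psi_n)) / (3 + 5 - 2),
               tolerance = 0.03)
  expect_error(fit_ellipse_bayes(pts[1:3, ]), "at least 4")
})

test_that("coverage contours carry chi-squared scaling and Monte-Carlo mass", {
  f <- ellipse_from_moments(c(0, 0), diag(2), n = 100)
  c95 <- ellipse_contour(f, 0.95)
  expect_equal(c95$scale2, qchisq(0.95, 2), tolerance = 1e-12)
  expect_equal(c95$area, pi * 5.9915, tolerance = 1e-3)
  c40 <- ellipse_contour(f, 0.40)
  expect_equal(c40$scale2, -2 * log(0.60), tolerance = 1e-12)
  expect_equal(c40$area, 3.21, tolerance = 1e-2)
  expect_equal(ellipse_contour(f, "standard")$area, f$SEA)
  expect_error(ellipse_contour(f, 1.2), "coverage")

  set.seed(14)
  draws <- draw_mvn(1e5, c(0, 0), diag(2))
  expect_equal(mean(contour_contains(c40, draws)), 0.40, tolerance = 0.01)
  expect_equal(mean(contour_contains(c95, draws)), 0.95, tolerance = 0.01)

  # area strictly increases with coverage
  areas <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.95),
                  function(p) ellipse_contour(f, p)$area, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("ellipse overlap reproduces the circle-lens closed form and is symmetric", {
  circ <- function(cx) ellipse_contour(
    ellipse_from_moments(c(cx, 0), diag(2), 10), "standard")
  a <- circ(0); b <- circ(1)
  lens <- 2 * acos(0.5) - 0.5 * sqrt(3)           # 1.2284
  o <- ellipse_overlap(a, b)
  expect_equal(o$area_overlap, lens, tolerance = 0.005 * lens)
  expect_equal(ellipse_overlap(b, a)$area_overlap, o$area_overlap,
               tolerance = 0.01 * lens)

  same <- ellipse_overlap(a, circ(0))
  expect_equal(same$proportion, 1, tolerance = 0.02)
  expect_equal(same$area_overlap, a$area, tolerance = 0.02 * a$area)

  far <- ellipse_overlap(a, circ(50))
  expect_identical(far$area_overlap, 0)
  expect_identical(unname(far$proportions["union"]), 0)

  # proportion conventions are consistent with one another
  expect_equal(unname(o$proportions["mean_area"]),
               2 * o$area_overlap / (o$area_a + o$area_b), tolerance = 1e-9)
  expect_lte(o$proportions[["union"]], o$proportions[["min_area"]])
})

test_that("SEAb credible intervals are calibrated (exact area pivot)", {
  # under the reference prior, det(S)/det(Sigma) is a pivot, so the 95%
  # credible interval for the area has exactly 95% frequentist coverage
  Sigma <- matrix(c(1, 0.4, 0.4, 0.8), 2)
  truth <- pi * sqrt(det(Sigma))
  covered <- vapply(1:60, function(i) {
    set.seed(2000 + i)
    pts <- draw_mvn(50, c(0, 0), Sigma)
    f <- fit_ellipse_bayes(pts, iterations = 4000, burn_in = 400, seed = i)
    f$ci95[1] <= truth && truth <= f$ci95[2]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})
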
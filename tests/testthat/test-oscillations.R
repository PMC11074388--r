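sine_series <- function(n = 64, lam = 16, amp = 1, base = -24, phase = 0,
                        n_amp = 0.5, n_base = 6.6) {
  make_series(n = n,
              f13 = function(t) base + amp * sin(2 * pi * (t - phase) / lam),
              f15 = function(t) n_base + n_amp * sin(2 * pi * t / lam))
}

test_that("a noiseless sine yields one peak and one valley group per cycle", {
  b <- sine_series(n = 64, lam = 16)
  g <- extract_extrema(b, cycle_length_cm = 16)
  expect_equal(sum(g$kind == "peak"), 4)
  expect_equal(sum(g$kind == "valley"), 4)
  # 3-member group means sit just below the crest: mean of sin at peak +/- 1 cm
  attn <- (1 + 2 * cos(2 * pi / 16)) / 3
  expect_equal(g$d13C_mean[g$kind == "peak"], rep(-24 + attn, 4),
               tolerance = 0.02)
  expect_true(all(g$n_members == 3))
  expect_true(all(g$d13C_mean[g$kind == "peak"] >
                    max(g$d13C_mean[g$kind == "valley"])))
})

test_that("groups truncate to two members at plate edges", {
  # valley of the carbon sine sits exactly at the distal end (t = 0)
  b <- sine_series(n = 65, lam = 16, phase = 4)   # sin(-pi/2) at t = 0
  g <- extract_extrema(b, cycle_length_cm = 16, members = 3)
  first_valley <- g[g$kind == "valley" & g$cycle_index == 1, ]
  expect_equal(first_valley$n_members, 2)
  expect_true(all(g$n_members %in% 2:3))
})

test_that("constant carbon series cannot be segmented", {
  b <- make_series(n = 40, f13 = function(t) rep(-24, length(t)))
  expect_error(extract_extrema(b, cycle_length_cm = 15), "no oscillation")
  expect_error(extract_extrema(sine_series(), members = 5), "2 or 3")
  expect_error(extract_extrema(sine_series()), "no cycle-length estimate")
})

test_that("amplitude is the mean peak-minus-valley and doubles the half-excursion", {
  b <- sine_series(n = 64, lam = 16, amp = 0.9)
  g <- extract_extrema(b, cycle_length_cm = 16)
  a <- oscillation_amplitude(g)
  attn <- (1 + 2 * cos(2 * pi / 16)) / 3
  expect_equal(a$mean_amplitude, 2 * 0.9 * attn, tolerance = 0.05)
  expect_equal(nrow(a$per_cycle), 4)

  single <- oscillation_amplitude(g[g$cycle_index == 2, ])
  expect_equal(single$mean_amplitude, single$per_cycle$amplitude[1])

  # invariant under a constant shift of the whole series
  b2 <- sine_series(n = 64, lam = 16, amp = 0.9, base = -20)
  a2 <- oscillation_amplitude(extract_extrema(b2, cycle_length_cm = 16))
  expect_equal(a2$mean_amplitude, a$mean_amplitude, tolerance = 1e-9)
})

test_that("the fin preset reproduces its configured peak-to-valley amplitude", {
  cfg <- species_preset("fin", noise_sd_C = 0, noise_sd_N = 0, seed = 1)
  b <- simulate_series(cfg, species = "fin")
  g <- extract_extrema(b, cycle_length_cm = 16.52)
  a <- oscillation_amplitude(g)
  expect_equal(a$mean_amplitude, 3.7, tolerance = 0.07 * 3.7)
})

test_that("peak/valley group counts track the number of cycles", {
  set.seed(31)
  for (i in 1:5) {
    lam <- runif(1, 12, 20)
    cfg <- synthetic_config(lam, 90, noise_sd_C = 0.15, noise_sd_N = 0.15,
                            seed = 100 + i)
    b <- simulate_series(cfg)
    g <- extract_extrema(b, cycle_length_cm = lam)
    ncyc <- floor(89 / lam)
    expect_equal(sum(g$kind == "peak"), sum(g$kind == "valley"))
    expect_true(abs(sum(g$kind == "peak") - ncyc) <= 1)
    expect_true(all(g$d13C_mean[g$kind == "peak"] >=
                      g$d13C_mean[g$kind == "valley"][
                        order(g$cycle_index[g$kind == "valley"])] - 1e-9))
  }
})

test_that("seasonal tables aggregate groups and expose configured species contrasts", {
  mk <- function(pid, sp, base) {
    b <- sine_series(n = 64, lam = 16, base = base)
    b$plate_id <- pid; b$species <- sp
    extract_extrema(b, cycle_length_cm = 16)
  }
  ex <- list(mk("B1", "blue", -24.6), mk("B2", "blue", -24.6),
             mk("F1", "fin", -22.6), mk("F2", "fin", -22.6))
  st <- seasonal_table(ex)
  expect_equal(nrow(st$table), 4 * 8)
  expect_equal(nrow(st$summary), 4)
  pk <- st$summary[st$summary$kind == "peak", ]
  expect_equal(pk$d13C_mean[pk$species == "fin"] -
                 pk$d13C_mean[pk$species == "blue"], 2.0, tolerance = 1e-6)

  pm <- plate_extremum_means(st$table)
  expect_equal(nrow(pm), 8)                       # 4 plates x 2 kinds
  expect_equal(sort(unique(pm$plate_id)), c("B1", "B2", "F1", "F2"))

  empty <- seasonal_table(list())
  expect_equal(nrow(empty$table), 0)
})
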
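#' Mann-Whitney rank test between two groups
#'
#' Two-sided Mann-Whitney U test with the W convention of the first group's
#' rank sum minus its minimum (the U statistic of the first group, computed
#' with midranks for ties): 0 <= W <= n_a * n_b. The p-value uses exact
#' enumeration for small samples without ties and the normal approximation
#' with tie correction (and continuity correction) otherwise, as implemented
#' by \code{stats::wilcox.test}. Identical values across both groups give
#' W = n_a * n_b / 2 and p = 1 with a warning.
#'
#' @param a,b numeric samples.
#' @param labels length-2 character group labels.
#' @return object of class \code{rank_test_result}: \code{statistic_W},
#'   \code{p_value}, \code{groups} (labels and sizes), \code{exact}.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # W = 0, exact p = 1/3
#' @export
mann_whitney <- function(a, b, labels = c("a", "b")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop_bi("mann_whitney: both groups must be non-empty")
  res <- list(groups = list(label_a = labels[1L], n_a = length(a),
                            label_b = labels[2L], n_b = length(b)))
  if (length(unique(c(a, b))) == 1L) {
    warning("mann_whitney: all values identical across both groups")
    res$statistic_W <- length(a) * length(b) / 2
    res$p_value <- 1
    res$exact <- FALSE
  } else {
    has_ties <- any(duplicated(c(a, b)))
    exact <- !has_ties && (length(a) + length(b)) <= 40L
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE))
    res$statistic_W <- unname(wt$statistic)
    res$p_value <- wt$p.value
    res$exact <- exact
  }
  structure(res, class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("<rank_test_result> %s (n=%d) vs %s (n=%d): W = %g, p = %.4g%s\n",
              x$groups$label_a, x$groups$n_a, x$groups$label_b, x$groups$n_b,
              x$statistic_W, x$p_value, if (x$exact) " (exact)" else ""))
  invisible(x)
}

#' Distribution screening: normality and variance homogeneity
#'
#' Shapiro-Wilk normality per group and Levene's test of homogeneity of
#' variance across groups (via \code{car::leveneTest}), with a routing
#' decision: if any group departs from normality or variances are
#' heterogeneous at \code{alpha}, rank-based tests are recommended,
#' otherwise parametric ones. Groups with fewer than 3 values or constant
#' values are skipped with a note.
#'
#' @param values numeric vector.
#' @param group parallel grouping vector.
#' @param alpha screening level (default 0.05).
#' @return object of class \code{distribution_screen}: \code{per_group}
#'   (Shapiro-Wilk W and p, or skip note), \code{levene} (F, df, p),
#'   \code{routing} ("rank" or "parametric").
#' @export
screen_distributions <- function(values, group, alpha = 0.05) {
  stopifnot(length(values) == length(group))
  group <- factor(group)
  per <- do.call(rbind, lapply(levels(group), function(g) {
    x <- values[group == g & !is.na(values)]
    if (length(x) < 3L)
      return(data.frame(group = g, n = length(x), shapiro_W = NA_real_,
                        shapiro_p = NA_real_, note = "skipped: n < 3",
                        stringsAsFactors = FALSE))
    if (length(unique(x)) == 1L)
      return(data.frame(group = g, n = length(x), shapiro_W = NA_real_,
                        shapiro_p = NA_real_, note = "skipped: constant values",
                        stringsAsFactors = FALSE))
    sw <- stats::shapiro.test(x)
    data.frame(group = g, n = length(x), shapiro_W = unname(sw$statistic),
               shapiro_p = sw$p.value, note = "", stringsAsFactors = FALSE)
  }))
  lev <- tryCatch({
    lt <- car::leveneTest(values ~ group)
    list(statistic = lt[1, "F value"], df = unname(lt[["Df"]]),
         p_value = lt[1, "Pr(>F)"])
  }, error = function(e) list(statistic = NA_real_, df = NA, p_value = NA_real_))
  reject_norm <- any(per$shapiro_p < alpha, na.rm = TRUE)
  reject_var <- !is.na(lev$p_value) && lev$p_value < alpha
  structure(list(per_group = per, levene = lev,
                 routing = if (reject_norm || reject_var) "rank" else "parametric",
                 alpha = alpha),
            class = "distribution_screen")
}

#' @export
print.distribution_screen <- function(x, ...) {
  print(x$per_group, row.names = FALSE)
  cat(sprintf("Levene F = %.3f, p = %.4g; routing: %s tests\n",
              x$levene$statistic, x$levene$p_value, x$routing))
  invisible(x)
}

#' Cross-correlation of two detrended isotope series
#'
#' Pearson correlation between time-ordered series at integer-sample lags:
#' the value at lag k correlates \code{x[t]} with \code{y[t + k]}, so a
#' positive peak lag means y lags behind x by that many cm. The peak is the
#' largest absolute correlation; it is classified positive or negative only
#' when it exceeds the large-sample 95 percent white-noise band
#' \code{1.96 / sqrt(n)}, else "none". Swapping the inputs negates the peak
#' lag.
#'
#' @param x,y equal-length numeric series (time-ordered, e.g. residuals from
#'   \code{\link{detrend_gaussian}}); length must exceed \code{2 * max_lag}.
#' @param max_lag maximum lag in samples (default 20).
#' @return object of class \code{ccf_result}: \code{lags},
#'   \code{correlations}, \code{peak_lag}, \code{peak_r},
#'   \code{classification}, \code{band}.
#' @export
ccf_series <- function(x, y, max_lag = 20L) {
  n <- length(x)
  if (length(y) != n) stop_bi("ccf_series: series lengths differ")
  if (n <= 2L * max_lag)
    stop_bi("ccf_series: series length must exceed 2 * max_lag")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_bi("ccf_series: zero-variance input")
  lags <- seq(-max_lag, max_lag)
  cors <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(x[seq_len(n - k)], y[seq_len(n - k) + k])
    else stats::cor(x[seq_len(n + k) - k], y[seq_len(n + k)])
  }, numeric(1))
  # ties in |r| (periodic signals match again half a cycle away, with the
  # sign flipped): take the smallest absolute lag, preferring the
  # positive-correlation match when both signs peak at the same |lag|
  cand <- which(abs(cors) >= max(abs(cors)) - 1e-12)
  cand <- cand[abs(lags[cand]) == min(abs(lags[cand]))]
  pk <- cand[which.max(cors[cand])]
  band <- 1.96 / sqrt(n)
  classification <- if (abs(cors[pk]) > band) {
    if (cors[pk] > 0) "positive" else "negative"
  } else "none"
  structure(list(lags = lags, correlations = cors,
                 peak_lag = lags[pk], peak_r = cors[pk],
                 classification = classification, band = band, n = n),
            class = "ccf_result")
}

#' @export
print.ccf_result <- function(x, ...) {
  cat(sprintf("<ccf_result> peak r = %.3f at lag %d (band +/- %.3f): %s\n",
              x$peak_r, x$peak_lag, x$band, x$classification))
  invisible(x)
}

#' Breusch-Godfrey test for first-order serial correlation, plate-aware
#'
#' LM test of first-order autocorrelation in the residuals of a restricted
#' model, with lagged residuals that never cross a plate boundary (the first
#' observation of each plate gets a zero lag, the usual fill convention).
#' The auxiliary regression adds the one-step lag to the restricted model's
#' design; the statistic is n times the auxiliary R-squared, referred to a
#' chi-squared distribution with 1 df.
#'
#' The default restricted model is the overall mean (\code{demean =
#' "overall"}): that is the model whose independence assumption the pooled
#' niche fits actually make, and it keeps the test at its nominal size.
#' \code{demean = "plate"} removes each plate's own mean first; note that
#' per-plate demeaning biases the lag-1 residual autocorrelation by about
#' -1/n_plate under the null, which oversizes the pooled chi-squared test
#' when plates are short. With a single plate and \code{"overall"} the
#' statistic reduces exactly to the textbook Breusch-Godfrey test on an
#' intercept-only model.
#'
#' @param values numeric vector, ordered by position within plate.
#' @param plate_ids parallel plate identifiers.
#' @param demean restricted model: \code{"overall"} (grand mean, default) or
#'   \code{"plate"} (plate indicators).
#' @return list: \code{lm_stat}, \code{df}, \code{p_value}, \code{order}.
#' @export
bg_test_panel <- function(values, plate_ids,
                          demean = c("overall", "plate")) {
  demean <- match.arg(demean)
  ok <- !is.na(values)
  values <- values[ok]
  plate <- factor(plate_ids[ok])
  n <- length(values)
  if (n < 3L) stop_bi("bg_test_panel: too few observations")
  X <- if (demean == "plate") {
    # indicator matrix built directly (model.matrix rejects 1-level factors)
    vapply(levels(plate), function(l) as.numeric(plate == l), numeric(n))
  } else {
    matrix(1, n, 1)
  }
  e <- stats::lm.fit(X, values)$residuals
  # lag within plate: split() orders by factor level, so align everything
  ord <- order(plate)
  elag <- unlist(lapply(split(e, plate), function(v) c(0, v[-length(v)])),
                 use.names = FALSE)
  aux <- stats::lm.fit(cbind(X[ord, , drop = FALSE], elag), e[ord])
  lm_stat <- n * sum(aux$fitted.values^2) / sum(e^2)
  list(lm_stat = lm_stat, df = 1L,
       p_value = stats::pchisq(lm_stat, df = 1L, lower.tail = FALSE),
       order = 1L)
}

#' Plate-level subsampling check against pseudoreplication
#'
#' Repeated samples along one plate are not independent. This draws
#' \code{per_plate} samples without replacement from every plate (with
#' replacement, with a warning, when a plate is shorter), \code{n_datasets}
#' times, then (i) tests each subsampled dataset for residual first-order
#' autocorrelation with the plate-aware Breusch-Godfrey test and (ii)
#' optionally refits the Bayesian niche ellipses per species on each dataset
#' and flags whether their 95 percent SEAb credible intervals overlap the
#' full-data intervals.
#'
#' @param plates list of \code{\link{baleen_series}} (>= 2).
#' @param per_plate samples drawn from each plate (default 40).
#' @param n_datasets number of resampled datasets (default 5).
#' @param seed integer seed for reproducible draws.
#' @param isotopes which value columns to test for autocorrelation.
#' @param refit_niche refit SEAb per dataset and compare credible intervals.
#' @param bayes_args list of overrides for \code{\link{fit_ellipse_bayes}}.
#' @return object of class \code{resample_diagnostics}: \code{n_datasets},
#'   \code{per_plate}, \code{dataset_size}, \code{autocorr} (data frame of
#'   BG results per dataset and isotope), \code{sea_b} (per dataset and
#'   species credible intervals plus overlap flags, when refitted),
#'   \code{full_ci}, and \code{datasets} (the resampled data frames).
#' @export
pseudoreplication_check <- function(plates, per_plate = 40L, n_datasets = 5L,
                                    seed = NULL, isotopes = c("d13C", "d15N"),
                                    refit_niche = TRUE, bayes_args = list()) {
  if (inherits(plates, "baleen_series")) plates <- list(plates)
  if (length(plates) < 2L)
    stop_bi("pseudoreplication_check: need at least 2 plates")
  if (!is.null(seed)) set.seed(seed)
  draw_one <- function() {
    df <- do.call(rbind, lapply(plates, function(b) {
      s <- b$samples
      if (nrow(s) < per_plate) {
        warning(sprintf("plate '%s' has %d < %d samples; sampling with replacement",
                        b$plate_id, nrow(s), per_plate))
        take <- sample.int(nrow(s), per_plate, replace = TRUE)
      } else {
        take <- sample.int(nrow(s), per_plate)
      }
      cbind(data.frame(plate_id = b$plate_id, species = b$species,
                       stringsAsFactors = FALSE),
            s[sort(take), c("position_cm", "d13C", "d15N")])
    }))
    rownames(df) <- NULL
    df
  }
  datasets <- replicate(n_datasets, draw_one(), simplify = FALSE)
  autocorr <- do.call(rbind, lapply(seq_len(n_datasets), function(i) {
    do.call(rbind, lapply(isotopes, function(iso) {
      bg <- bg_test_panel(datasets[[i]][[iso]], datasets[[i]]$plate_id)
      data.frame(dataset = i, isotope = iso, lm_stat = bg$lm_stat,
                 p_value = bg$p_value, stringsAsFactors = FALSE)
    }))
  }))
  rownames(autocorr) <- NULL
  sea_b <- NULL
  full_ci <- NULL
  if (refit_niche) {
    full <- do.call(rbind, lapply(plates, function(b)
      data.frame(species = b$species, d13C = b$samples$d13C,
                 d15N = b$samples$d15N, stringsAsFactors = FALSE)))
    fit_by_species <- function(df, tag) {
      do.call(rbind, lapply(unique(df$species), function(sp) {
        pts <- df[df$species == sp, c("d13C", "d15N")]
        fb <- do.call(fit_ellipse_bayes,
                      c(list(points = pts, group_label = sp), bayes_args))
        data.frame(dataset = tag, species = sp, ci_low = fb$ci95[1],
                   ci_high = fb$ci95[2], sea_b_mode = fb$SEA_B_mode,
                   stringsAsFactors = FALSE)
      }))
    }
    full_ci <- fit_by_species(full, 0L)
    sea_b <- do.call(rbind, lapply(seq_len(n_datasets), function(i)
      fit_by_species(datasets[[i]], i)))
    sea_b$overlaps_full <- vapply(seq_len(nrow(sea_b)), function(i) {
      fc <- full_ci[full_ci$species == sea_b$species[i], ]
      sea_b$ci_low[i] <= fc$ci_high && sea_b$ci_high[i] >= fc$ci_low
    }, logical(1))
    rownames(sea_b) <- NULL
  }
  structure(list(n_datasets = n_datasets, per_plate = per_plate,
                 dataset_size = per_plate * length(plates),
                 autocorr = autocorr, sea_b = sea_b, full_ci = full_ci,
                 datasets = datasets),
            class = "resample_diagnostics")
}

#' @export
print.resample_diagnostics <- function(x, ...) {
  cat(sprintf("<resample_diagnostics> %d datasets of %d (= %d plates x %d draws)\n",
              x$n_datasets, x$dataset_size, x$dataset_size / x$per_plate,
              x$per_plate))
  cat(sprintf("  Breusch-Godfrey p-values: %s\n",
              paste(sprintf("%.3f", x$autocorr$p_value), collapse = ", ")))
  if (!is.null(x$sea_b))
    cat(sprintf("  SEAb 95%% CIs overlap full data in %d/%d refits\n",
                sum(x$sea_b$overlaps_full), nrow(x$sea_b)))
  invisible(x)
}

#' Contrast a continuous variable between two regions
#'
#' Kruskal-Wallis rank test between two labelled groups; with two groups the
#' statistic is chi-squared distributed with 1 df. Used e.g. to compare d13C
#' between animals captured inside and outside a sea sector.
#'
#' @param values numeric vector.
#' @param region parallel two-level grouping.
#' @return list: \code{statistic}, \code{df}, \code{p_value}, \code{method}.
#' @export
region_contrast <- function(values, region) {
  region <- factor(region)
  if (nlevels(droplevels(region[!is.na(values)])) < 2L)
    stop_bi("region_contrast: need two non-empty groups")
  kt <- stats::kruskal.test(values ~ region)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, method = "Kruskal-Wallis")
}
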
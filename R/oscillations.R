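#' Extract peak and valley groups of each carbon oscillation
#'
#' The carbon record defines the seasonal oscillation: the detrended d13C
#' series is segmented into consecutive windows one cycle length wide
#' (starting at the oldest sample), and within each window the most extreme
#' detrended sample anchors a peak (maximum) and a valley (minimum) group.
#' Each group is extended to \code{members} adjacent grid samples centred on
#' the anchor (truncated to 2 where the anchor sits at a plate edge), and
#' carries the raw - not detrended - d13C and d15N means of its members, so
#' groups are bivariate and usable for seasonal niche fits. Ties between
#' equal extremal values break toward the earliest position.
#'
#' @param series a \code{\link{baleen_series}} with d13C present.
#' @param est a \code{spectral_estimate} supplying the cycle length, or
#'   \code{NULL} if \code{cycle_length_cm} is given directly.
#' @param cycle_length_cm cycle length in cm (overrides \code{est}).
#' @param members target group size (2 or 3; default 3).
#' @param sigma_cm Gaussian filter SD for the anchoring detrend (cm).
#' @param min_window_frac trailing windows spanning less than this fraction
#'   of a cycle are dropped (default 0.75): a fragment that cannot contain a
#'   full oscillation would report spurious, attenuated extrema.
#' @return data frame of class \code{extremum_groups}: one row per group with
#'   \code{plate_id}, \code{species}, \code{kind} (peak/valley),
#'   \code{cycle_index}, \code{anchor_time_cm}, \code{anchor_position_cm},
#'   \code{n_members}, \code{member_positions} (comma-joined cm),
#'   \code{d13C_mean}, \code{d15N_mean}.
#' @export
extract_extrema <- function(series, est = NULL, cycle_length_cm = NULL,
                            members = 3L, sigma_cm = 8,
                            min_window_frac = 0.75) {
  stopifnot(inherits(series, "baleen_series"))
  if (!members %in% 2:3)
    stop_bi("extract_extrema: 'members' must be 2 or 3")
  lam <- cycle_length_cm %||% est$cycle_length_cm
  if (is.null(lam) || is.na(lam))
    stop_bi(sprintf("plate '%s': no cycle-length estimate for extremum extraction",
                    series$plate_id))
  to <- time_order(series)
  d <- detrend_gaussian(to$d13C, sigma_cm = sigma_cm,
                        spacing_cm = stats::median(diff(to$time_cm)),
                        positions = to$time_cm)
  if (max(abs(d$residuals)) < 1e-12)
    stop_bi(sprintf("plate '%s': no oscillation in d13C (flat residuals)",
                    series$plate_id))
  n <- nrow(to)
  window <- floor(to$time_cm / lam)
  rows <- list()
  for (wi in sort(unique(window))) {
    idx <- which(window == wi)
    spacing <- stats::median(diff(to$time_cm))
    if (length(idx) < 2L ||
        diff(range(to$time_cm[idx])) + spacing < min_window_frac * lam)
      next                                         # partial tail window
    if (all(is.na(to$d13C[idx]))) {
      warning(sprintf("plate '%s': window %d has no d13C values, skipped",
                      series$plate_id, wi + 1L))
      next
    }
    for (kind in c("peak", "valley")) {
      res <- d$residuals[idx]
      anchor <- idx[if (kind == "peak") which.max(res) else which.min(res)]
      half <- (members - 1L) %/% 2L
      lo <- anchor - half
      hi <- anchor + (members - 1L - half)
      if (lo < 1L) { lo <- 1L; hi <- min(n, lo + members - 1L) }
      if (hi > n) { hi <- n; lo <- max(1L, hi - members + 1L) }
      g <- lo:hi
      # at a plate edge the group truncates to 2 members
      if (anchor %in% c(1L, n)) g <- if (anchor == 1L) 1:2 else (n - 1L):n
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = series$plate_id, species = series$species, kind = kind,
        cycle_index = wi + 1L,
        anchor_time_cm = to$time_cm[anchor],
        anchor_position_cm = to$position_cm[anchor],
        n_members = length(g),
        member_positions = paste(sort(to$position_cm[g]), collapse = ","),
        d13C_mean = mean(to$d13C[g], na.rm = TRUE),
        d15N_mean = mean(to$d15N[g], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("extremum_groups", class(out))
  out
}

#' Carbon oscillation amplitude (peak minus valley, per cycle)
#'
#' Pairs each cycle's peak group with its valley group and reports the d13C
#' difference of their means; the summary amplitude is the mean over cycles.
#' This matches the field convention of quoting amplitude as the full
#' peak-to-valley excursion. Extrema without a same-cycle partner are paired
#' with the nearest cycle index, with a warning.
#'
#' @param groups an \code{\link{extract_extrema}} result (possibly several
#'   plates; amplitudes are computed within plate).
#' @return object of class \code{amplitude_summary}: \code{per_cycle} data
#'   frame (\code{plate_id}, \code{cycle_index}, \code{amplitude}) and
#'   \code{mean_amplitude}.
#' @export
oscillation_amplitude <- function(groups) {
  stopifnot(is.data.frame(groups))
  if (!nrow(groups)) stop_bi("oscillation_amplitude: no extremum groups")
  per <- list()
  for (pid in unique(groups$plate_id)) {
    g <- groups[groups$plate_id == pid, ]
    pk <- g[g$kind == "peak", ]
    vl <- g[g$kind == "valley", ]
    if (!nrow(pk) || !nrow(vl))
      stop_bi(sprintf("plate '%s': need at least one peak-valley pair", pid))
    used <- logical(nrow(vl))
    for (i in seq_len(nrow(pk))) {
      j <- which(vl$cycle_index == pk$cycle_index[i] & !used)
      if (!length(j)) {
        j <- which(!used)
        if (!length(j)) break
        j <- j[which.min(abs(vl$cycle_index[j] - pk$cycle_index[i]))]
        warning(sprintf("plate '%s': cycle %d peak paired with cycle %d valley",
                        pid, pk$cycle_index[i], vl$cycle_index[j]))
      } else j <- j[1L]
      used[j] <- TRUE
      per[[length(per) + 1L]] <- data.frame(
        plate_id = pid, cycle_index = pk$cycle_index[i],
        amplitude = pk$d13C_mean[i] - vl$d13C_mean[j],
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  structure(list(per_cycle = per, mean_amplitude = mean(per$amplitude)),
            class = "amplitude_summary")
}

#' @export
print.amplitude_summary <- function(x, ...) {
  cat(sprintf("<amplitude_summary> mean d13C peak-to-valley %.2f per mil over %d cycles\n",
              x$mean_amplitude, nrow(x$per_cycle)))
  invisible(x)
}

#' Seasonal peak/valley table across plates
#'
#' Stacks extremum groups from several plates into one long table and adds a
#' species-level summary (mean and SD of the group means, per species and
#' kind). The long table feeds the niche and comparison stages.
#'
#' @param extrema_list list of \code{\link{extract_extrema}} results (or one
#'   combined data frame).
#' @return list with \code{table} (long per-group rows) and \code{summary}
#'   (species x kind means and SDs, with plate counts).
#' @export
seasonal_table <- function(extrema_list) {
  if (is.data.frame(extrema_list)) extrema_list <- list(extrema_list)
  tab <- do.call(rbind, extrema_list)
  if (is.null(tab) || !nrow(tab))
    return(list(table = data.frame(), summary = data.frame()))
  rownames(tab) <- NULL
  groups <- unique(tab[, c("species", "kind")])
  summ <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- tab[tab$species == groups$species[i] & tab$kind == groups$kind[i], ]
    data.frame(species = groups$species[i], kind = groups$kind[i],
               n_groups = nrow(g), n_plates = length(unique(g$plate_id)),
               d13C_mean = mean(g$d13C_mean), d13C_sd = stats::sd(g$d13C_mean),
               d15N_mean = mean(g$d15N_mean), d15N_sd = stats::sd(g$d15N_mean),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(table = tab, summary = summ)
}

#' Plate-level seasonal means
#'
#' Collapses extremum groups to one bivariate point per plate and kind (the
#' mean over that plate's peak or valley groups). Seasonal niche ellipses are
#' fitted to these plate-level means - one point per animal - rather than to
#' all member samples, avoiding pseudoreplication at the seasonal level.
#'
#' @param extrema an \code{\link{extract_extrema}} result or combined table.
#' @return data frame: \code{plate_id}, \code{species}, \code{kind},
#'   \code{d13C}, \code{d15N}, \code{n_groups}.
#' @export
plate_extremum_means <- function(extrema) {
  stopifnot(is.data.frame(extrema))
  keys <- unique(extrema[, c("plate_id", "species", "kind")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    g <- extrema[extrema$plate_id == keys$plate_id[i] &
                 extrema$kind == keys$kind[i], ]
    data.frame(plate_id = keys$plate_id[i], species = keys$species[i],
               kind = keys$kind[i],
               d13C = mean(g$d13C_mean), d15N = mean(g$d15N_mean),
               n_groups = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
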
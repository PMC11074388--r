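#' Construct a baleen plate isotope series
#'
#' A \code{baleen_series} holds the ordered bulk stable-isotope record sampled
#' along one baleen plate together with the whale's metadata. Positions are
#' measured in cm from the proximal base of the plate, so position 0 is the
#' newest tissue and the largest position the oldest; use
#' \code{\link{time_order}} to obtain the record in chronological order.
#'
#' @param plate_id character identifier of the plate.
#' @param species one of \code{"blue"} or \code{"fin"}.
#' @param samples data frame with columns \code{position_cm}, \code{d13C},
#'   \code{d15N} and optionally \code{pctC}, \code{pctN} (percent by mass).
#'   Rows are sorted by position; duplicated positions are an error.
#' @param sex one of \code{"M"}, \code{"F"}, \code{"unknown"}.
#' @param pregnant one of \code{"yes"}, \code{"no"}, \code{"na"}.
#' @param capture_date ISO date string (or \code{NA}).
#' @param latitude,longitude decimal degrees (or \code{NA}).
#'
#' @return an object of class \code{baleen_series}: a list with the metadata
#'   fields and a \code{samples} data frame (with C:N ratio columns added when
#'   the elemental percentages are present).
#' @seealso \code{\link{read_baleen_series}}, \code{\link{compute_ratios}}
#' @export
baleen_series <- function(plate_id, species, samples,
                          sex = "unknown", pregnant = "na",
                          capture_date = NA_character_,
                          latitude = NA_real_, longitude = NA_real_) {
  species <- as.character(species)
  if (!species %in% c("blue", "fin"))
    stop_bi(sprintf("plate '%s': unknown species label '%s' (expected 'blue' or 'fin')",
                    plate_id, species))
  if (!sex %in% c("M", "F", "unknown"))
    stop_bi(sprintf("plate '%s': sex must be 'M', 'F' or 'unknown'", plate_id))
  if (!pregnant %in% c("yes", "no", "na"))
    stop_bi(sprintf("plate '%s': pregnant must be 'yes', 'no' or 'na'", plate_id))
  samples <- as.data.frame(samples)
  req <- c("position_cm", "d13C", "d15N")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop_bi(sprintf("plate '%s': samples lack column(s) %s",
                    plate_id, paste(miss, collapse = ", ")))
  if (nrow(samples) < 1L)
    stop_bi(sprintf("plate '%s': empty sample table", plate_id))
  if (any(!is.finite(samples$position_cm)) || any(samples$position_cm < 0))
    stop_bi(sprintf("plate '%s': position_cm must be finite and >= 0", plate_id))
  dup <- samples$position_cm[duplicated(samples$position_cm)]
  if (length(dup))
    stop_bi(sprintf("plate '%s': duplicate position_cm %s",
                    plate_id, paste(unique(dup), collapse = ", ")))
  samples <- samples[order(samples$position_cm), , drop = FALSE]
  rownames(samples) <- NULL
  if (all(c("pctC", "pctN") %in% names(samples)))
    samples <- compute_ratios(samples)
  structure(
    list(plate_id = as.character(plate_id), species = species, sex = sex,
         pregnant = pregnant, capture_date = capture_date,
         latitude = latitude, longitude = longitude, samples = samples),
    class = "baleen_series")
}

#' @export
print.baleen_series <- function(x, ...) {
  n <- nrow(x$samples)
  span <- diff(range(x$samples$position_cm))
  cat(sprintf("<baleen_series> plate %s (%s whale, sex %s)\n",
              x$plate_id, x$species, x$sex))
  cat(sprintf("  %d samples spanning %.1f cm (0 cm = proximal base, newest tissue)\n",
              n, span))
  invisible(x)
}

#' Derive mass and atomic C:N ratios from elemental percentages
#'
#' The mass ratio is \code{pctC / pctN}; the atomic ratio multiplies the mass
#' ratio by the ratio of atomic masses 14.007/12.011 (about 1.1662), so a mass
#' C:N of 3.4 corresponds to an atomic C:N of about 4.0. Keratin typically
#' shows mass C:N near 3.4.
#'
#' @param x a data frame with numeric columns \code{pctC} and \code{pctN}
#'   (percent by mass, both > 0), or a \code{baleen_series}.
#' @return the input with \code{mass_CN} and \code{atomic_CN} columns filled.
#' @examples
#' compute_ratios(data.frame(pctC = 45, pctN = 13.24))
#' @export
compute_ratios <- function(x) UseMethod("compute_ratios")

#' @export
compute_ratios.data.frame <- function(x) {
  if (!all(c("pctC", "pctN") %in% names(x)))
    stop_bi("compute_ratios: need 'pctC' and 'pctN' columns")
  ok <- !is.na(x$pctC) & !is.na(x$pctN)
  if (any(ok & (x$pctC <= 0 | x$pctN <= 0)))
    stop_bi("compute_ratios: pctC and pctN must be positive")
  x$mass_CN <- ifelse(ok, x$pctC / x$pctN, NA_real_)
  x$atomic_CN <- x$mass_CN * CN_ATOMIC_FACTOR
  x
}

#' @export
compute_ratios.baleen_series <- function(x) {
  x$samples <- compute_ratios(x$samples)
  x
}

#' Time-ordered view of a baleen series
#'
#' Baleen grows from the proximal base, so the largest position along the
#' plate is the oldest tissue. This returns the sample arrays reversed into
#' chronological order: index 1 (time coordinate 0 cm) is the most distal,
#' oldest sample. Applying the reversal to an already time-ordered record
#' restores the original order.
#'
#' @param series a \code{baleen_series} with at least 2 samples.
#' @return data frame with \code{time_cm} (cm of growth since the oldest
#'   retained tissue), the original \code{position_cm}, and the isotope
#'   columns, ordered oldest first.
#' @export
time_order <- function(series) {
  stopifnot(inherits(series, "baleen_series"))
  s <- series$samples
  if (nrow(s) < 2L)
    stop_bi(sprintf("plate '%s': time_order needs at least 2 samples", series$plate_id))
  out <- s[rev(seq_len(nrow(s))), , drop = FALSE]
  out <- cbind(time_cm = max(s$position_cm) - out$position_cm, out)
  rownames(out) <- NULL
  out
}

#' Trophic discrimination factors
#'
#' Systematic isotopic offsets between a reference pool and baleen keratin.
#' The carbon POM-to-baleen factor is the sum of the POM-to-skin (1.7 per mil)
#' and skin-to-baleen (0.98 per mil) steps, i.e. 2.68 per mil. The nitrogen
#' krill-to-baleen factor defaults to 2.77 per mil (sd 0.22). No default is
#' shipped for the carbon krill-to-baleen factor; supply one when comparing
#' against prey ranges on the carbon axis.
#'
#' @param d13C_pom_to_skin,d13C_skin_to_baleen per-mil carbon offsets whose
#'   sum is the POM-to-baleen correction.
#' @param d15N_krill_to_baleen,d15N_krill_to_baleen_sd per-mil nitrogen
#'   offset (and its uncertainty) from krill to baleen.
#' @param d13C_krill_to_baleen per-mil carbon offset from krill to baleen,
#'   or \code{NULL} if unknown.
#' @return list of class \code{discrimination_factors}; the element
#'   \code{d13C_pom_to_baleen} is always the exact sum of its two components.
#' @export
discrimination_factors <- function(d13C_pom_to_skin = 1.7,
                                   d13C_skin_to_baleen = 0.98,
                                   d15N_krill_to_baleen = 2.77,
                                   d15N_krill_to_baleen_sd = 0.22,
                                   d13C_krill_to_baleen = NULL) {
  assert_scalar_num(d13C_pom_to_skin, "d13C_pom_to_skin")
  assert_scalar_num(d13C_skin_to_baleen, "d13C_skin_to_baleen")
  assert_scalar_num(d15N_krill_to_baleen, "d15N_krill_to_baleen")
  if (!is.null(d13C_krill_to_baleen))
    assert_scalar_num(d13C_krill_to_baleen, "d13C_krill_to_baleen")
  structure(list(
    d13C_pom_to_skin = d13C_pom_to_skin,
    d13C_skin_to_baleen = d13C_skin_to_baleen,
    d13C_pom_to_baleen = d13C_pom_to_skin + d13C_skin_to_baleen,
    d15N_krill_to_baleen = d15N_krill_to_baleen,
    d15N_krill_to_baleen_sd = d15N_krill_to_baleen_sd,
    d13C_krill_to_baleen = d13C_krill_to_baleen),
    class = "discrimination_factors")
}

#' Optional Suess-effect adjustment of d13C values
#'
#' Applies a linear correction for the secular depletion of oceanic d13C from
#' fossil-fuel CO2. Southern Ocean change over the relevant interval is tiny
#' (about -0.005 per mil per year), so this is off by default throughout the
#' package and provided only for sensitivity analyses.
#'
#' @param d13C per-mil values.
#' @param years_before_reference years elapsed between tissue growth and the
#'   reference date (positive = older tissue).
#' @param slope_per_yr per-mil change per year (default -0.005).
#' @return adjusted d13C values: \code{d13C - slope_per_yr * years_before_reference}.
#' @export
suess_adjust <- function(d13C, years_before_reference, slope_per_yr = -0.005) {
  d13C - slope_per_yr * years_before_reference
}

SERIES_META_COLS <- c("plate_id", "species", "sex", "pregnant",
                      "capture_date", "latitude", "longitude")
SERIES_VALUE_COLS <- c("position_cm", "d13C", "d15N", "pctC", "pctN")

#' Read baleen series from a long-format CSV
#'
#' One row per (plate, position) with the metadata columns repeated on every
#' row: \code{plate_id, species, sex, pregnant, capture_date, latitude,
#' longitude, position_cm, d13C, d15N, pctC, pctN}. Missing isotope values are
#' kept as explicit \code{NA} gaps. Duplicate positions within a plate or an
#' unknown species label are hard errors.
#'
#' @param path CSV file path.
#' @return named list of \code{\link{baleen_series}}, one per plate.
#' @export
read_baleen_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "species", "position_cm", "d13C", "d15N")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_bi(sprintf("'%s': missing column(s) %s", path, paste(miss, collapse = ", ")))
  out <- lapply(split(df, df$plate_id), function(p) {
    cols <- intersect(SERIES_VALUE_COLS, names(p))
    baleen_series(
      plate_id = p$plate_id[1L], species = p$species[1L],
      sex = if ("sex" %in% names(p)) as.character(p$sex[1L]) else "unknown",
      pregnant = if ("pregnant" %in% names(p)) as.character(p$pregnant[1L]) else "na",
      capture_date = if ("capture_date" %in% names(p)) as.character(p$capture_date[1L]) else NA_character_,
      latitude = if ("latitude" %in% names(p)) p$latitude[1L] else NA_real_,
      longitude = if ("longitude" %in% names(p)) p$longitude[1L] else NA_real_,
      samples = p[, cols, drop = FALSE])
  })
  out[order(names(out))]
}

#' Write baleen series to a long-format CSV
#'
#' Inverse of \code{\link{read_baleen_series}}; numeric values round-trip
#' to at least 1e-9. Derived ratio columns are included when present.
#'
#' @param series a \code{baleen_series} or list of them.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_baleen_series <- function(series, path) {
  if (inherits(series, "baleen_series")) series <- list(series)
  rows <- lapply(series, function(b) {
    s <- b$samples
    meta <- data.frame(plate_id = b$plate_id, species = b$species, sex = b$sex,
                       pregnant = b$pregnant, capture_date = b$capture_date,
                       latitude = b$latitude, longitude = b$longitude,
                       stringsAsFactors = FALSE)
    cbind(meta[rep(1L, nrow(s)), , drop = FALSE], s)
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
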
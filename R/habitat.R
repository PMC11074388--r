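#' Water-mass zone thresholds in baleen-corrected d13C space
#'
#' Thresholds derived from Southern Ocean particulate organic matter (POM)
#' isoscapes, already shifted into baleen space by the POM-to-baleen
#' discrimination correction (+2.68 per mil): baleen d13C below
#' \code{southern_ocean_max} indicates the Southern Ocean / North Antarctic
#' Zone, values above \code{subantarctic_min} the Subantarctic Front, and a
#' \code{seasonal_variation} band of 1.1 per mil just below the subantarctic
#' threshold counts as "near" subantarctic. The defaults (-21.32, -20.22)
#' are the exact arithmetic consequence of applying the 2.68 correction to
#' the POM thresholds; the rounded one-decimal forms can be supplied instead.
#'
#' @param southern_ocean_max upper d13C bound of the Southern Ocean class.
#' @param subantarctic_min lower d13C bound of the Subantarctic class.
#' @param seasonal_variation width (per mil) of the "near subantarctic" band.
#' @return list of class \code{iso_zones}.
#' @export
iso_zones <- function(southern_ocean_max = -21.32, subantarctic_min = -20.22,
                      seasonal_variation = 1.1) {
  assert_scalar_num(southern_ocean_max, "southern_ocean_max")
  assert_scalar_num(subantarctic_min, "subantarctic_min")
  if (southern_ocean_max >= subantarctic_min)
    stop_bi("iso_zones: southern_ocean_max must be < subantarctic_min")
  if (seasonal_variation < 0)
    stop_bi("iso_zones: seasonal_variation must be >= 0")
  structure(list(southern_ocean_max = southern_ocean_max,
                 subantarctic_min = subantarctic_min,
                 seasonal_variation = seasonal_variation,
                 space = "baleen_corrected"),
            class = "iso_zones")
}

#' Shift POM d13C values into baleen space
#'
#' Adds the combined POM-to-baleen discrimination factor (POM to skin plus
#' skin to baleen, 1.7 + 0.98 = 2.68 per mil by default), making POM isoscape
#' values directly comparable to measured baleen d13C.
#'
#' @param pom_d13C per-mil POM values.
#' @param f a \code{\link{discrimination_factors}} object.
#' @return baleen-equivalent d13C values.
#' @examples
#' pom_to_baleen(c(-22.90, -24.00))  # -20.22, -21.32
#' @export
pom_to_baleen <- function(pom_d13C, f = discrimination_factors()) {
  stopifnot(inherits(f, "discrimination_factors"))
  pom_d13C + f$d13C_pom_to_baleen
}

ZONE_LEVELS <- c("southern_ocean", "intermediate", "near_subantarctic",
                 "subantarctic")

#' Classify baleen d13C values into water-mass zones
#'
#' Strictly below the Southern Ocean threshold is \code{southern_ocean};
#' strictly above the subantarctic threshold is \code{subantarctic}; within
#' \code{seasonal_variation} below the subantarctic threshold (inclusive on
#' both ends) is \code{near_subantarctic}; anything else is
#' \code{intermediate}. Values equal to a threshold therefore resolve to the
#' non-extreme class. The mapping is monotone in d13C.
#'
#' @param d13C per-mil baleen values.
#' @param zones an \code{\link{iso_zones}} object.
#' @return factor with levels southern_ocean < intermediate <
#'   near_subantarctic < subantarctic; \code{NA} values stay \code{NA}.
#' @export
classify_zone <- function(d13C, zones = iso_zones()) {
  stopifnot(inherits(zones, "iso_zones"))
  out <- rep(NA_character_, length(d13C))
  ok <- !is.na(d13C)
  x <- d13C[ok]
  z <- rep("intermediate", length(x))
  z[x >= zones$subantarctic_min - zones$seasonal_variation &
      x <= zones$subantarctic_min] <- "near_subantarctic"
  z[x > zones$subantarctic_min] <- "subantarctic"
  z[x < zones$southern_ocean_max] <- "southern_ocean"
  out[ok] <- z
  factor(out, levels = ZONE_LEVELS, ordered = TRUE)
}

#' Per-sample habitat calls for a set of plates
#'
#' @param plates a \code{baleen_series} or list of them.
#' @param zones an \code{\link{iso_zones}} object.
#' @return data frame: \code{plate_id}, \code{species}, \code{position_cm},
#'   \code{d13C}, \code{zone}.
#' @export
habitat_calls <- function(plates, zones = iso_zones()) {
  if (inherits(plates, "baleen_series")) plates <- list(plates)
  out <- do.call(rbind, lapply(plates, function(b) {
    data.frame(plate_id = b$plate_id, species = b$species,
               position_cm = b$samples$position_cm, d13C = b$samples$d13C,
               stringsAsFactors = FALSE)
  }))
  out$zone <- classify_zone(out$d13C, zones)
  rownames(out) <- NULL
  out
}

#' Zone occupancy fractions per species
#'
#' Fractions of non-missing samples in each zone, per species, plus the
#' composite "within or near subantarctic" fraction (subantarctic plus
#' near_subantarctic) used to summarise approaches to the Subantarctic
#' Front. Fractions sum to 1 across the four zones.
#'
#' @param calls a \code{\link{habitat_calls}} data frame.
#' @param by grouping column (default \code{"species"}).
#' @return data frame with one row per group: \code{n} plus one column per
#'   zone and \code{within_or_near_subantarctic}.
#' @export
zone_fractions <- function(calls, by = "species") {
  stopifnot(is.data.frame(calls), "zone" %in% names(calls))
  groups <- unique(as.character(calls[[by]]))
  out <- do.call(rbind, lapply(groups, function(g) {
    z <- calls$zone[calls[[by]] == g & !is.na(calls$zone)]
    n <- length(z)
    if (n == 0L) {
      warning(sprintf("zone_fractions: group '%s' has no classified samples", g))
      fr <- setNames(rep(NA_real_, length(ZONE_LEVELS)), ZONE_LEVELS)
    } else {
      fr <- table(factor(z, levels = ZONE_LEVELS)) / n
      fr <- setNames(as.numeric(fr), ZONE_LEVELS)
    }
    df <- data.frame(group = g, n = n, stringsAsFactors = FALSE)
    df[names(fr)] <- as.list(fr)
    df$within_or_near_subantarctic <- fr[["subantarctic"]] + fr[["near_subantarctic"]]
    df
  }))
  names(out)[1L] <- by
  rownames(out) <- NULL
  out
}

#' Fraction of samples consistent with literature prey ranges
#'
#' Prey isotope ranges (axis-aligned boxes in d13C x d15N space, from the
#' literature) are shifted into baleen space by adding the krill-to-baleen
#' discrimination factors, then the fraction of baleen samples falling inside
#' each box is reported. If a discrimination factor for an axis is missing
#' (the carbon krill-to-baleen factor has no shipped default), that axis is
#' treated as unconstrained, with a warning.
#'
#' A worked example box set lives at
#' \code{system.file("extdata", "prey_boxes_synthetic.csv", package =
#' "baleniso")}; its numbers are illustrative placeholders, not literature
#' values.
#'
#' @param points two-column matrix/data frame of baleen (d13C, d15N).
#' @param prey_boxes data frame with columns \code{name}, \code{d13C_min},
#'   \code{d13C_max}, \code{d15N_min}, \code{d15N_max} (prey space).
#' @param f a \code{\link{discrimination_factors}} object.
#' @return data frame: \code{name}, \code{n}, \code{fraction}.
#' @export
prey_consistency <- function(points, prey_boxes, f = discrimination_factors()) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2L, is.data.frame(prey_boxes))
  need <- c("name", "d13C_min", "d13C_max", "d15N_min", "d15N_max")
  miss <- setdiff(need, names(prey_boxes))
  if (length(miss))
    stop_bi(sprintf("prey_consistency: prey_boxes lack column(s) %s",
                    paste(miss, collapse = ", ")))
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  n <- nrow(pts)
  dC <- f$d13C_krill_to_baleen
  if (is.null(dC) || is.na(dC)) {
    warning("prey_consistency: no d13C krill-to-baleen factor; carbon axis unconstrained")
    dC <- NA_real_
  }
  dN <- f$d15N_krill_to_baleen
  out <- do.call(rbind, lapply(seq_len(nrow(prey_boxes)), function(i) {
    b <- prey_boxes[i, ]
    inC <- if (is.na(dC)) rep(TRUE, n) else
      pts[, 1] >= b$d13C_min + dC & pts[, 1] <= b$d13C_max + dC
    inN <- if (is.na(dN)) rep(TRUE, n) else
      pts[, 2] >= b$d15N_min + dN & pts[, 2] <= b$d15N_max + dN
    data.frame(name = b$name, n = n,
               fraction = if (n) mean(inC & inN) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
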
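#' Build a pipeline run configuration
#'
#' Collects every stage default into one serializable list: a run is
#' reproducible from the configuration plus its inputs alone. All randomness
#' flows from the single master \code{seed}; stage seeds are derived from it
#' deterministically.
#'
#' @param input path to a long-format series CSV, or \code{NULL} to simulate.
#' @param out_dir output directory for tables, stats and the run log.
#' @param seed master integer seed.
#' @param n_per_species plates per species when simulating.
#' @param sigma_cm Gaussian detrending SD (cm).
#' @param band_cm wavelength search window (cm).
#' @param min_cycles minimum annual cycles for growth-rate averaging.
#' @param members extremum group size.
#' @param coverages ellipse coverage levels.
#' @param mcmc list: \code{iterations}, \code{burn_in}, \code{thin},
#'   \code{chains}.
#' @param zones an \code{\link{iso_zones}} object.
#' @param factors a \code{\link{discrimination_factors}} object.
#' @param prey_boxes optional prey-box data frame or CSV path.
#' @param resample list: \code{per_plate}, \code{n_datasets}, or \code{NULL}
#'   to skip the pseudoreplication stage.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, out_dir = tempfile("baleniso_run_"),
                            seed = 1L, n_per_species = 5L,
                            sigma_cm = 8, band_cm = c(8, 30), min_cycles = 3L,
                            members = 3L, coverages = c(0.40, 0.95),
                            mcmc = list(iterations = 20000L, burn_in = 1000L,
                                        thin = 0.10, chains = 2L),
                            zones = iso_zones(),
                            factors = discrimination_factors(),
                            prey_boxes = NULL,
                            resample = list(per_plate = 40L, n_datasets = 5L)) {
  structure(list(input = input, out_dir = out_dir, seed = as.integer(seed),
                 n_per_species = n_per_species, sigma_cm = sigma_cm,
                 band_cm = band_cm, min_cycles = min_cycles, members = members,
                 coverages = coverages, mcmc = mcmc, zones = zones,
                 factors = factors, prey_boxes = prey_boxes,
                 resample = resample),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Only keys present in the file override the \code{\link{pipeline_config}}
#' defaults; \code{zones} and \code{factors} sub-maps are passed to their
#' constructors so their invariants are enforced.
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  plain <- intersect(names(y), c("input", "out_dir", "seed", "n_per_species",
                                 "sigma_cm", "band_cm", "min_cycles",
                                 "members", "coverages", "mcmc", "resample"))
  args[plain] <- y[plain]
  if (!is.null(y$zones)) args$zones <- do.call(iso_zones, y$zones)
  if (!is.null(y$factors)) args$factors <- do.call(discrimination_factors, y$factors)
  if (!is.null(y$prey_boxes)) args$prey_boxes <- y$prey_boxes
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  fnv1a32(paste(deparse(config[setdiff(names(config), "out_dir")]),
                collapse = "\n"))
}

#' Run the full baleen isotope analysis pipeline
#'
#' Executes, in order: input (or simulation) -> chronology -> oscillations ->
#' niche -> habitat -> comparisons, writing a per-individual summary table
#' (subsample counts, C:N ratios, cycle counts, growth rates with species
#' averages), a niche summary table (group sizes, SEAc, SEAb with credible
#' intervals, overlaps under all three proportion conventions), habitat zone
#' fractions, a JSON stats bundle, and a plain-text log with one line per
#' plate per stage. Reruns with the same configuration are numerically
#' identical.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return (invisibly) a report bundle: \code{plates}, \code{rates},
#'   \code{table1}, \code{extrema}, \code{niche}, \code{habitat},
#'   \code{comparisons}, \code{resample}, \code{config_hash}, \code{files}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logln <- function(...) writeLines(sprintf(...), log_con)
  logln("baleniso pipeline; config hash %s; master seed %d", hash, config$seed)

  stage <- "input"
  bundle <- tryCatch({
    # --- input / simulate -------------------------------------------------
    plates <- if (is.null(config$input)) {
      logln("stage input: simulating %d plates per species (seed %d)",
            config$n_per_species, config$seed)
      simulate_cohort(config$n_per_species, seed = config$seed)
    } else {
      logln("stage input: reading %s", config$input)
      read_baleen_series(config$input)
    }
    for (b in plates)
      logln("  plate %s: %s, %d samples", b$plate_id, b$species, nrow(b$samples))

    # --- chronology -------------------------------------------------------
    stage <- "chronology"
    rates <- cohort_growth_rates(plates, sigma_cm = config$sigma_cm,
                                 band_cm = config$band_cm)
    for (i in seq_len(nrow(rates)))
      logln("  plate %s: cycle %.2f cm (%d cycles, %s)", rates$plate_id[i],
            rates$cycle_length_cm[i], rates$n_cycles[i], rates$isotope_used[i])
    table1 <- table1_aggregate(plates, rates, min_cycles = config$min_cycles)

    # --- oscillations -----------------------------------------------------
    stage <- "oscillations"
    extrema <- do.call(rbind, lapply(seq_along(plates), function(i) {
      extract_extrema(plates[[i]],
                      cycle_length_cm = rates$cycle_length_cm[i],
                      members = config$members, sigma_cm = config$sigma_cm)
    }))
    seasonal <- seasonal_table(extrema)
    amps <- lapply(split(extrema, extrema$species), oscillation_amplitude)

    # --- niche ------------------------------------------------------------
    stage <- "niche"
    all_pts <- do.call(rbind, lapply(plates, function(b)
      data.frame(species = b$species, d13C = b$samples$d13C,
                 d15N = b$samples$d15N, stringsAsFactors = FALSE)))
    seas_pts <- plate_extremum_means(extrema)
    mcmc <- config$mcmc
    seed_niche <- config$seed + 1000L
    fits <- list()
    for (sp in unique(all_pts$species)) {
      fits[[paste0(sp, "_overall")]] <- fit_ellipse_bayes(
        all_pts[all_pts$species == sp, c("d13C", "d15N")],
        iterations = mcmc$iterations, burn_in = mcmc$burn_in,
        thin = mcmc$thin, chains = mcmc$chains,
        seed = seed_niche, group_label = paste0(sp, "_overall"))
      for (kd in unique(seas_pts$kind)) {
        pts <- seas_pts[seas_pts$species == sp & seas_pts$kind == kd,
                        c("d13C", "d15N")]
        lbl <- paste0(sp, "_", kd)
        if (nrow(pts) >= 4L)
          fits[[lbl]] <- fit_ellipse_bayes(
            pts, iterations = mcmc$iterations, burn_in = mcmc$burn_in,
            thin = mcmc$thin, chains = mcmc$chains,
            seed = seed_niche, group_label = lbl)
        else logln("  niche group %s skipped (n=%d < 4)", lbl, nrow(pts))
      }
    }
    for (f in fits)
      logln("  niche %s: n=%d SEAc=%.2f SEAb=[%.2f,%.2f]", f$group_label,
            f$n, f$SEA_C, f$ci95[1], f$ci95[2])
    pairs <- list(c("blue_overall", "fin_overall"),
                  c("blue_peak", "fin_peak"), c("blue_valley", "fin_valley"))
    overlaps <- list()
    for (pr in pairs) {
      if (!all(pr %in% names(fits))) next
      for (cv in config$coverages) {
        key <- sprintf("%s|%s|%.2f", pr[1], pr[2], cv)
        overlaps[[key]] <- ellipse_overlap(
          ellipse_contour(fits[[pr[1]]], cv),
          ellipse_contour(fits[[pr[2]]], cv))
      }
    }
    table2 <- niche_summary_table(fits, overlaps)

    # --- habitat ----------------------------------------------------------
    stage <- "habitat"
    calls <- habitat_calls(plates, config$zones)
    fractions <- zone_fractions(calls)
    prey <- NULL
    if (!is.null(config$prey_boxes)) {
      boxes <- config$prey_boxes
      if (is.character(boxes)) boxes <- utils::read.csv(boxes)
      prey <- do.call(rbind, lapply(unique(all_pts$species), function(sp) {
        cbind(species = sp,
              prey_consistency(all_pts[all_pts$species == sp,
                                       c("d13C", "d15N")],
                               boxes, config$factors))
      }))
    }

    # --- comparisons ------------------------------------------------------
    stage <- "comparisons"
    screen <- list(
      d13C = screen_distributions(all_pts$d13C, all_pts$species),
      d15N = screen_distributions(all_pts$d15N, all_pts$species))
    mw <- list(
      d13C = mann_whitney(all_pts$d13C[all_pts$species == "blue"],
                          all_pts$d13C[all_pts$species == "fin"],
                          labels = c("blue", "fin")),
      d15N = mann_whitney(all_pts$d15N[all_pts$species == "blue"],
                          all_pts$d15N[all_pts$species == "fin"],
                          labels = c("blue", "fin")))
    ccfs <- lapply(plates, function(b) {
      to <- time_order(b)
      dc <- detrend_gaussian(to$d13C, config$sigma_cm, positions = to$time_cm)
      dn <- detrend_gaussian(to$d15N, config$sigma_cm, positions = to$time_cm)
      ccf_series(dn$residuals, dc$residuals, max_lag = 20L)
    })
    resample <- NULL
    if (!is.null(config$resample)) {
      resample <- pseudoreplication_check(
        plates, per_plate = config$resample$per_plate,
        n_datasets = config$resample$n_datasets,
        seed = config$seed + 2000L,
        bayes_args = list(iterations = mcmc$iterations,
                          burn_in = mcmc$burn_in, thin = mcmc$thin,
                          chains = mcmc$chains, seed = seed_niche))
      logln("  resample: %d datasets of %d; min BG p = %.3f",
            resample$n_datasets, resample$dataset_size,
            min(resample$autocorr$p_value))
    }

    list(plates = plates, rates = rates, table1 = table1, extrema = extrema,
         seasonal = seasonal, amplitudes = amps,
         niche = list(fits = fits, overlaps = overlaps, table2 = table2),
         habitat = list(calls = calls, fractions = fractions, prey = prey),
         comparisons = list(screen = screen, mann_whitney = mw, ccf = ccfs),
         resample = resample, config_hash = hash)
  }, error = function(e) {
    stop_bi(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })

  # --- write artifacts ----------------------------------------------------
  files <- c(
    table1 = file.path(config$out_dir, "table1_individuals.csv"),
    table1_species = file.path(config$out_dir, "table1_species.csv"),
    table2 = file.path(config$out_dir, "table2_niche.csv"),
    fractions = file.path(config$out_dir, "zone_fractions.csv"),
    stats = file.path(config$out_dir, "stats.json"))
  w <- function(df, path) {
    df$config_hash <- hash
    utils::write.csv(df, path, row.names = FALSE)
  }
  w(bundle$table1$individuals, files["table1"])
  w(bundle$table1$species, files["table1_species"])
  w(bundle$niche$table2, files["table2"])
  w(bundle$habitat$fractions, files["fractions"])
  stats <- list(
    config_hash = hash, seed = config$seed,
    mann_whitney = lapply(bundle$comparisons$mann_whitney, function(m)
      list(W = m$statistic_W, p = m$p_value)),
    amplitudes = lapply(bundle$amplitudes, function(a) a$mean_amplitude),
    overlaps = lapply(bundle$niche$overlaps, function(o)
      as.list(o$proportions)),
    zone_fractions = bundle$habitat$fractions,
    bg_p_values = if (!is.null(bundle$resample))
      bundle$resample$autocorr$p_value else NULL)
  jsonlite::write_json(stats, files["stats"], auto_unbox = TRUE, digits = NA)
  bundle$files <- c(files, log = log_path)
  writeLines(sprintf("pipeline complete; %d plates", length(bundle$plates)),
             log_con)
  invisible(bundle)
}

#' Per-individual and species summary table
#'
#' One row per plate (subsample count, mass and atomic C:N mean and SD,
#' cycle count, growth rate - blank unless the plate has at least
#' \code{min_cycles} cycles) plus one species-average row per species (mean
#' cycle count over qualifying individuals; growth rate mean and SD).
#'
#' @param plates list of \code{\link{baleen_series}}.
#' @param rates a \code{\link{cohort_growth_rates}} data frame.
#' @param min_cycles qualification threshold (default 3).
#' @return list of class \code{table1_summary}: \code{individuals} and
#'   \code{species} data frames.
#' @export
table1_aggregate <- function(plates, rates, min_cycles = 3L) {
  msd <- function(x, f) if (is.null(x)) NA_real_ else f(x, na.rm = TRUE)
  individuals <- do.call(rbind, lapply(plates, function(b) {
    s <- b$samples
    r <- rates[rates$plate_id == b$plate_id, ]
    qual <- nrow(r) == 1L && !is.na(r$n_cycles) && r$n_cycles >= min_cycles
    data.frame(plate_id = b$plate_id, species = b$species, sex = b$sex,
               n_subsamples = nrow(s),
               mass_CN_mean = msd(s$mass_CN, mean),
               mass_CN_sd = msd(s$mass_CN, stats::sd),
               atomic_CN_mean = msd(s$atomic_CN, mean),
               atomic_CN_sd = msd(s$atomic_CN, stats::sd),
               n_cycles = if (nrow(r)) r$n_cycles else NA_integer_,
               growth_rate = if (qual) r$cycle_length_cm else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(individuals) <- NULL
  species <- do.call(rbind, lapply(unique(individuals$species), function(sp) {
    g <- individuals[individuals$species == sp, ]
    q <- g[!is.na(g$growth_rate), ]
    data.frame(species = sp, n_plates = nrow(g),
               n_subsamples_total = sum(g$n_subsamples),
               mass_CN_mean = mean(g$mass_CN_mean),
               atomic_CN_mean = mean(g$atomic_CN_mean),
               mean_cycles = if (nrow(q)) mean(q$n_cycles) else NA_real_,
               growth_rate_mean = if (nrow(q)) mean(q$growth_rate) else NA_real_,
               growth_rate_sd = if (nrow(q) > 1L) stats::sd(q$growth_rate) else NA_real_,
               n_qualifying = nrow(q), stringsAsFactors = FALSE)
  }))
  rownames(species) <- NULL
  structure(list(individuals = individuals, species = species,
                 min_cycles = min_cycles),
            class = "table1_summary")
}

#' @export
print.table1_summary <- function(x, ...) {
  print(x$individuals, row.names = FALSE, digits = 4)
  cat("--- species averages (individuals with >=", x$min_cycles, "cycles) ---\n")
  print(x$species, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Overall sample sizes per species
#'
#' Sums per-plate subsample counts by species; these totals are the group
#' sizes of the species-level niche fits.
#'
#' @param individuals data frame with \code{species} and \code{n_subsamples}
#'   columns (e.g. \code{table1_aggregate(...)$individuals}).
#' @return named integer vector of totals per species.
#' @export
species_sample_sizes <- function(individuals) {
  stopifnot(all(c("species", "n_subsamples") %in% names(individuals)))
  tapply(individuals$n_subsamples, individuals$species, sum)
}

#' Niche summary table
#'
#' One row per fitted group with sample size, SEA, SEAc, SEAb mode and 95
#' percent credible interval, followed by overlap proportions (all three
#' conventions) per compared pair and coverage.
#'
#' @param fits named list of \code{\link{fit_ellipse_bayes}} results.
#' @param overlaps named list of \code{\link{ellipse_overlap}} results
#'   (names \code{"a|b|coverage"}).
#' @return data frame.
#' @export
niche_summary_table <- function(fits, overlaps = list()) {
  rows <- do.call(rbind, lapply(fits, function(f) {
    data.frame(group = f$group_label, n = f$n, SEA = f$SEA, SEA_c = f$SEA_C,
               SEA_b_mode = f$SEA_B_mode %||% NA_real_,
               SEA_b_low = if (is.null(f$ci95)) NA_real_ else f$ci95[1],
               SEA_b_high = if (is.null(f$ci95)) NA_real_ else f$ci95[2],
               overlap_pair = NA_character_, coverage = NA_real_,
               prop_union = NA_real_, prop_mean_area = NA_real_,
               prop_min_area = NA_real_, stringsAsFactors = FALSE)
  }))
  orows <- do.call(rbind, lapply(names(overlaps), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    o <- overlaps[[key]]
    data.frame(group = NA_character_, n = NA_integer_, SEA = NA_real_,
               SEA_c = NA_real_, SEA_b_mode = NA_real_, SEA_b_low = NA_real_,
               SEA_b_high = NA_real_,
               overlap_pair = paste(parts[1], parts[2], sep = " vs "),
               coverage = as.numeric(parts[3]),
               prop_union = o$proportions[["union"]],
               prop_mean_area = o$proportions[["mean_area"]],
               prop_min_area = o$proportions[["min_area"]],
               stringsAsFactors = FALSE)
  }))
  out <- rbind(rows, orows)
  rownames(out) <- NULL
  out
}
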
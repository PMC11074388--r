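# baleniso

Analysis of bulk stable-isotope series (δ¹³C, δ¹⁵N) sampled along baleen
plates of blue and fin whales. Baleen grows continuously, so a transect of
measurements at ~1 cm increments is a multi-year record of diet and
location: carbon tracks the source of primary production (and hence water
mass and latitude), nitrogen tracks trophic level. The package turns a set
of per-plate series into:

* **Growth chronology** — each plate's annual isotope oscillation is
  isolated with a Gaussian low-pass detrend and its wavelength estimated
  from the FFT periodogram peak (cm/cycle = cm/yr); individuals with ≥ 3
  annual cycles average into a species growth rate (mean ± SD).
* **Seasonal extremes** — peaks and valleys of each carbon oscillation
  (groups of 2–3 adjacent samples), read as the subantarctic and Southern
  Ocean ends of the migratory cycle, with peak-to-valley amplitudes.
* **Isotopic niche** — standard ellipse areas of the bivariate
  (δ¹³C, δ¹⁵N) cloud: SEA = π√det(Σ̂), the small-sample corrected
  SEAc = SEA·(n−1)/(n−2), and a Bayesian SEAb posterior whose 95% credible
  interval is exactly calibrated (the area posterior under the reference
  prior is pivotal), plus 40%/95% coverage contours (χ²₂ scaling) and
  ellipse overlap under three proportion conventions.
* **Habitat classification** — POM-isoscape thresholds shifted into baleen
  space by the diet–tissue discrimination Δ¹³C = 1.7 + 0.98 = 2.68‰
  (Southern Ocean < −21.32‰, Subantarctic Front > −20.22‰, with a ±1.1‰
  "near" band), zone occupancy fractions, and prey-range consistency via
  krill→baleen discrimination factors.
* **Comparative statistics** — Shapiro–Wilk/Levene screening with test
  routing, Mann–Whitney U, cross-correlation of detrended carbon and
  nitrogen signals, a plate-subsampling check against pseudoreplication
  (40 draws per plate × 5 datasets) with plate-aware Breusch–Godfrey
  autocorrelation tests, and two-group Kruskal–Wallis region contrasts.

A synthetic baleen-series generator with species presets (blue: 14.35
cm/yr, 2.0‰ carbon peak-to-valley; fin: 16.52 cm/yr, 3.7‰, carbon lagging
nitrogen by a quarter cycle) makes the full pipeline testable without
archival plate material. Per-individual summaries of the ten 1940s
Antarctic plates that calibrate the presets ship in
`inst/extdata/whale_plate_summaries.csv`.

## Worked example

```r
library(baleniso)

cohort <- simulate_cohort(n_per_species = 5, seed = 42)
rates  <- cohort_growth_rates(cohort)
species_growth_rate(rates[rates$species == "blue", ])
#> <growth_rate_summary> 14.76 +/- 1.81 cm/yr over 5 individuals (>= 3 cycles)
species_growth_rate(rates[rates$species == "fin", ])
#> <growth_rate_summary> 15.26 +/- 3.31 cm/yr over 5 individuals (>= 3 cycles)
```

Each plate's wavelength is recovered from its nitrogen periodogram; the
species means land near the generating presets (14.35 and 16.52 cm/yr)
with the spread coming from the cohort's per-individual jitter.

```r
extrema <- do.call(rbind, lapply(seq_along(cohort), function(i)
  extract_extrema(cohort[[i]], cycle_length_cm = rates$cycle_length_cm[i])))
oscillation_amplitude(extrema[extrema$species == "fin", ])
#> <amplitude_summary> mean d13C peak-to-valley 3.44 per mil over 24 cycles

pts <- do.call(rbind, lapply(cohort, function(b)
  data.frame(species = b$species, d13C = b$samples$d13C, d15N = b$samples$d15N)))
fit_blue <- fit_ellipse_bayes(pts[pts$species == "blue", -1], seed = 7, group_label = "blue")
fit_fin  <- fit_ellipse_bayes(pts[pts$species == "fin",  -1], seed = 7, group_label = "fin")
fit_fin
#> <niche_ellipse> fin: n=360, SEA=2.506, SEAc=2.513 per mil^2
#>   SEAb mode 2.517, 95% CI [2.270, 2.792] (3800 draws)

ellipse_overlap(ellipse_contour(fit_blue, 0.95), ellipse_contour(fit_fin, 0.95))
#> <overlap_result> area 4.8760 (A=5.3194, B=15.0149); proportion 0.315 [union]
#>   conventions: union 0.315, mean_area 0.480, min_area 0.917

zone_fractions(habitat_calls(cohort))
#>   species   n southern_ocean intermediate near_subantarctic subantarctic
#> 1    blue 430          1.000            0             0.000            0
#> 2     fin 360          0.831            0             0.169            0
#>   within_or_near_subantarctic
#> 1                       0.000
#> 2                       0.169
```

The fin niche is larger than the blue (its migration spans more
isotopically distinct water), every simulated blue sample classifies as
Southern Ocean, and a sixth of fin samples fall within or near the
Subantarctic Front band — the qualitative pattern the presets encode.
`run_pipeline(pipeline_config(seed = 1))` chains all stages and writes the
per-individual and niche summary tables, zone fractions, a JSON stats
bundle and a per-plate log to its output directory.

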
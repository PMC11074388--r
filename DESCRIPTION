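Package: baleniso
Title: Baleen Stable-Isotope Chronology, Niche and Habitat Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing bulk stable-isotope series (delta-13C,
    delta-15N) sampled along baleen plates of mysticete whales. Estimates
    per-individual baleen growth rates from annual isotope oscillations
    (Gaussian low-pass detrending followed by FFT periodogram peak
    detection), extracts peak/valley extremum groups of the carbon
    oscillations, quantifies bivariate isotopic niches with standard
    ellipse areas (maximum-likelihood SEA, small-sample corrected SEAc and
    Bayesian SEAb with credible intervals) and ellipse overlap, classifies
    samples into Southern Ocean / Subantarctic water-mass zones via
    discrimination-corrected particulate organic matter isoscape
    thresholds, and provides species-level inferential statistics
    (rank tests, cross-correlation of detrended signals, plate-level
    subsampling with Breusch-Godfrey autocorrelation checks). A synthetic
    baleen-series generator with species presets supports testing and
    power analysis without access to archival plate data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    yaml
Suggests:
    lmtest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
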
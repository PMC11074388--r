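---
title: "Methods: baleen isotope chronology, niche and habitat analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: baleen isotope chronology, niche and habitat analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baleniso)
```

## The measurement and its time axis

Baleen is keratin that grows continuously from the gum, so a transect of
bulk stable-isotope measurements taken at ~1 cm increments along a plate is
a time series of the whale's diet and location: carbon (δ¹³C, ‰ vs VPDB)
tracks the source of primary production and hence latitude and water mass,
nitrogen (δ¹⁵N, ‰ vs air) tracks trophic level and physiology. Position is
measured from the proximal base, so 0 cm is the *newest* tissue; every
spectral and cross-correlation computation in this package first flips the
record into chronological order (`time_order()`), which makes "lag"
directly interpretable as elapsed growth.

Elemental ratios are carried along as a tissue-quality control: the mass
C:N ratio is %C/%N, and the atomic ratio multiplies it by the ratio of
atomic masses 14.007/12.011 (≈1.1662). Keratin sits near a mass C:N of
3.4, equivalently an atomic C:N near 4.0; values far from this flag
contamination or degradation. No Suess-effect correction is applied by
default — the secular δ¹³C decline in the Southern Ocean is of order
−0.005‰ yr⁻¹, negligible over a single plate — but `suess_adjust()`
exposes the linear correction for sensitivity analyses.

## Growth chronology: detrend, then find the annual cycle

Annual migration imprints a roughly annual oscillation on the isotope
record, so the cycle length in cm *is* the annual growth rate in cm/yr.
The chronology stage:

1. **Detrends** with a Gaussian low-pass filter (`detrend_gaussian()`).
   The kernel SD defaults to 8 cm — roughly half the expected annual
   wavelength — so multi-year drift is absorbed into the trend while the
   annual cycle passes into the residuals essentially intact (the filter's
   gain at a 15 cm wavelength is below 1%). Edges are handled by
   reflection; interior gaps are linearly interpolated (and flagged) only
   for this spectral path, never for the niche or habitat stages, which use
   raw values.
2. **Locates the periodogram peak** (`estimate_cycle_length()`): the
   zero-mean residuals are zero-padded to at least 4× their length (next
   power of two), the FFT periodogram is searched inside a wavelength band
   of 8–30 cm (bracketing plausible growth rates for both species and
   excluding leftover trend leakage at low frequency), and the peak
   frequency is converted to cm/cycle as 1/frequency. A parabolic
   interpolation over the peak bin and its neighbours refines the estimate
   below bin resolution; ties break toward the longer cycle.
3. **Flags weak peaks.** The confidence statistic is peak power over the
   *median* in-band power: a genuine oscillation concentrates power in one
   lobe and leaves the median at the sidelobe floor, while a white-noise
   periodogram rarely exceeds ~10× its median. The default threshold of 10
   was calibrated on simulations (white noise is flagged in >95% of runs;
   sinusoids at the noise levels the generator produces are never flagged).
   Nitrogen is the default detection isotope — its annual cycles are
   usually the better resolved in baleen — with an automatic fallback to
   carbon when the nitrogen peak is weak (`plate_chronology()`).

Per-individual rates average into a species growth rate
(`species_growth_rate()`) using only individuals with at least three
annual cycles, with the sample (n−1) standard deviation. The cycle count
defaults to plate span divided by the estimated cycle length, but a
manually (visually) counted peak-to-peak number can be supplied, since
published cycle counts are often visual.

## Seasonal extremes of the carbon oscillation

Carbon defines the seasonal segmentation (`extract_extrema()`): the
detrended δ¹³C series is cut into consecutive windows one cycle long, and
in each window the most extreme detrended sample anchors a peak and a
valley group of 3 adjacent samples (2 at a plate edge; ties break to the
earliest position). Groups report the **raw** δ¹³C and δ¹⁵N means of their
members — detrended values decide *where* the season is, raw values say
*what* it looked like — so each group is a bivariate seasonal point.
Trailing window fragments shorter than 75% of a cycle are dropped: a
fragment cannot contain a full oscillation and would report attenuated
extrema. Note that averaging 3 samples around a sinusoidal crest
attenuates the reported amplitude by a factor (1 + 2cos(2π/λ))/3 ≈ 0.95,
so peak-to-valley amplitudes recovered from the generator's presets run a
few percent below the configured excursion; this is a property of the
grouped estimator, not a bug.

Peaks are read downstream as the subantarctic (winter/breeding) end of the
migration and valleys as the Southern Ocean (summer/feeding) end; that
interpretation lives in reporting, not in the data model.

## Isotopic niche: standard ellipses

For a bivariate cloud of (δ¹³C, δ¹⁵N) points the **standard ellipse area**
is SEA = π·√det(Σ̂) with Σ̂ the sample covariance — the area of the 1-SD
ellipse. The small-sample correction SEAc = SEA·(n−1)/(n−2) is applied
exactly. Coverage contours scale the ellipse by the χ²₂ quantile: 1.0217
at 40% (core niche) and 5.9915 at 95% (full niche).

**Bayesian SEAb.** The posterior of Σ is sampled under the reference
(Jeffreys) prior, giving the inverse-Wishart IW(n−1, S) with S the centred
sum of squares. This choice is deliberate: for the ellipse area,
det S/det Σ is an exact pivot under this posterior, so the 95% credible
interval is also an exact 95% confidence interval — the calibration
property the package's tests verify — and the posterior mean area equals
SEA·(n−1)/(n−3), a small-sample inflation analogous to SEAc. A proper
conjugate normal–inverse-Wishart prior (df ≥ 3, scaled-identity scale
matrix) can be supplied via the `prior` argument; its posterior mean
follows the closed form π·√det(Ψ₀+S)/(ν₀+n−2), which the tests also check.
Because conjugacy allows direct sampling, the conventional MCMC controls
(20 000 iterations, 1000 burn-in, 10% thinning, two chains — 3800 retained
draws) act purely as draw-count controls; chains are compared (means
differing by more than 10% warn) and merged. Seasonal niche ellipses are
fitted to *plate-level* peak or valley means — one bivariate point per
animal — rather than to all member samples, to avoid pseudoreplication at
the seasonal level.

**Overlap.** The intersection area of two contours is integrated on a
regular grid over the intersection of their bounding boxes, doubling the
resolution until two successive refinements agree to 0.5% (the
unit-circle lens oracle reproduces the closed form 2·cos⁻¹(½) − √3/2 ≈
1.2284 to that tolerance). Published overlap percentages rarely state
their denominator, so the proportion is reported under all three common
conventions — intersection/union (default), intersection over the mean
area, and intersection over the smaller area — and tables carry all
three.

## Habitat classification

Southern Ocean particulate organic matter (POM) isoscapes put the
Subantarctic Front at distinctly higher δ¹³C than Antarctic-zone waters.
POM thresholds are shifted into baleen space by the combined diet–tissue
discrimination factor Δ¹³C = 1.7 (POM→skin) + 0.98 (skin→baleen) = 2.68‰,
which is enforced as an exact sum. The resulting defaults, −21.32‰ and
−20.22‰, are the exact arithmetic consequence of the correction; rounded
one-decimal thresholds may be configured instead. Classification is
monotone in δ¹³C: strictly below −21.32‰ → `southern_ocean`; strictly
above −20.22‰ → `subantarctic`; within the ±1.1‰ seasonal-variation band
*below* the subantarctic threshold → `near_subantarctic`; otherwise
`intermediate`. Boundary equalities resolve to the non-extreme class, and
the "near" band applies only on the Southern Ocean side, since seasonal
variation matters for the claim of approaching the front. The composite
"within or near subantarctic" fraction is reported alongside the per-zone
fractions.

Prey consistency shifts literature prey boxes into baleen space by the
krill→baleen factors (Δ¹⁵N = 2.77 ± 0.22‰; the carbon factor has **no
shipped default** because no authoritative value is bundled — supplying it
is the user's responsibility, and a missing factor leaves that axis
unconstrained with a warning). The prey boxes shipped under
`inst/extdata/` are synthetic placeholders that document the schema, not
literature values, and are named accordingly.

## Comparative statistics

* `screen_distributions()` runs Shapiro–Wilk per group and Levene across
  groups (via `car::leveneTest`) and records a routing decision: any
  failure at α = 0.05 routes to rank-based tests.
* `mann_whitney()` wraps the two-sided Mann–Whitney U with W defined as
  the first group's rank sum minus its minimum (midranks for ties), exact
  enumeration for small tie-free samples and the tie-corrected normal
  approximation otherwise. This W convention is stated explicitly because
  published W values imply a specific software convention.
* `ccf_series()` computes Pearson correlations at integer-cm lags between
  time-ordered detrended series (correlating x at time t with y at t+k),
  with a 1.96/√n white-noise band for classification. Among tied |r|
  (periodic signals re-match half a cycle away with flipped sign) the
  smallest absolute lag wins, preferring the positive-correlation match.
* `pseudoreplication_check()` draws 40 samples per plate without
  replacement, 5 times, forming datasets of 400 (for 10 plates), runs a
  plate-aware Breusch–Godfrey test on each, and refits the Bayesian niche
  per dataset, flagging whether the 95% SEAb intervals overlap the
  full-data intervals. The BG restricted model defaults to the *overall
  mean* — precisely the independence assumption the pooled niche fit
  makes. Demeaning by plate instead is available, but biases the lag-1
  residual autocorrelation by ≈ −1/n_plate under the null, which
  demonstrably oversizes the pooled n·R² ~ χ²₁ test at 40 samples per
  plate (≈10% type-I instead of 5%); the overall-mean default holds the
  nominal size (measured 5–6% over 1000 null datasets).
* `region_contrast()` is a two-group Kruskal–Wallis (χ² with 1 df),
  the natural reading of a df = 1 chi-squared contrast on continuous
  isotope values.

## The synthetic generator: what it emulates, and what it does not

`simulate_series()` builds each isotope as baseline + amplitude ·
sin(2π·t/λ) + trend·t + Gaussian noise in the time-ordered coordinate,
with the carbon cycle optionally lagging nitrogen. Amplitude means
half the peak-to-valley excursion throughout the configuration.
Species presets encode the study conditions the package is designed
around: blue whales λ = 14.35 cm/yr, carbon peak-to-valley 2.0‰,
baselines (−24.62‰, 6.60‰), 86 cm plates (~6 years); fin whales λ =
16.52 cm/yr, peak-to-valley 3.7‰, baselines (−22.77‰, 6.71‰), 72 cm
plates (~4 years), and a carbon cycle lagging nitrogen by λ/4 — the lag
magnitude is an engineering choice (the phenomenon is real, its size is
not published). Nitrogen half-amplitudes (0.5‰ blue, 0.7‰ fin) are set
from published peak/valley nitrogen contrasts; measurement noise defaults
to 0.2‰ per isotope, matching typical IRMS precision. A non-migratory
animal zeroes the carbon cycle only. Cohorts jitter per-individual λ
(SD 1.20 cm blue, 1.86 cm fin — the observed between-individual spread)
and baselines (0.3‰, an engineering choice); one master seed derives
per-plate child seeds deterministically. A sawtooth cycle shape is
available for robustness checks of the spectral stage.

The generator does **not** model fasting or pregnancy isotope effects,
within-plate growth-rate changes, baseline drift beyond a linear trend, or
non-stationary noise. Passing tests therefore demonstrate that the
*operations* behave correctly on data with the assumed structure; they do
not validate the ecological assumptions against real plates, and analyses
of archival material should treat the low-confidence flags and routing
diagnostics as first-class results.

## Numerical choices and problem sizes

Tolerances: detrend reconstruction is exact to 1e-9 by construction;
overlap integration refines to 0.5%; degenerate covariances (collinear
points) are an error rather than a silent pseudo-inverse. Tie-breaks:
periodogram ties to the longer cycle, extremum ties to the earlier
position, CCF ties to the smaller |lag| preferring positive r. The test
suite and acceptance script size their simulations to run in seconds to a
few minutes on one core: 100 plates for wavelength-recovery statistics,
10⁵ Gaussian draws for contour coverage, 100 replicates of n = 50 for
SEAb interval calibration, and 200 seeded null cohorts (1000 datasets)
for the Breusch–Godfrey size check. These sizes give Monte-Carlo standard
errors comfortably inside the asserted bands (e.g. ±2.2 percentage points
for a 95% coverage estimate at 100 replicates).

## Known limitations

Growth is assumed constant within a plate (a single λ per individual);
wavelet or change-point chronologies are out of scope, as is anchoring
cycles to calendar dates. Habitat zones are threshold classes, not a
continuous geographic assignment. The ellipse machinery is strictly
bivariate. Overlap percentages depend on the denominator convention, and
comparisons with published values should state which convention is being
matched.
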
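---
title: "Methods: flight curves, climate windows and comparative models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flight curves, climate windows and comparative models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phenowin` implements an analysis chain for long-term butterfly
monitoring data: weekly transect counts become annual flight curves,
flight curves become abundance and emergence-peak estimates, those
estimates become population and species trends, a climate-window search
attributes each species' phenology to the temperature of a *critical
period*, and phylogenetic comparative models relate species-level trends
to ecological traits and to thermal sensitivity. Because the package is
validated entirely on synthetic data, the generative model is a
first-class part of the package and every analysis stage is judged by
how well it recovers known simulation truth.

## The generative model

`simulate_dataset()` draws, in a fixed order from one seed:

* **Sites.** Per-site baseline temperatures around a regional mean
  (default 14 °C, between-site SD 2 °C, mimicking an altitude gradient),
  planar coordinates, and a three-level climate region.
* **Monthly temperatures.** For each site, year and month:
  baseline + a fixed seasonal sinusoid (amplitude 8 °C, July peak) + a
  per-month linear trend + independent Gaussian noise (default SD
  0.5 °C). The default trend vector cools February, March and May by
  0.02 °C/yr and warms the other nine months by 0.038 °C/yr, so the
  annual mean warms by about 0.59 °C over a 26-year study span —
  the mixed-sign seasonal pattern that makes critical-period timing
  matter. Temperatures start one year before the first flight season so
  that windows reaching into the previous autumn are always covered.
* **Phylogeny and traits.** A pure-birth tree; categorical traits
  (voltinism, overwintering stage, larval diet) and continuous indices
  (habitat specialization SSI, open-habitat preference TAO, host plant
  index HPI).
* **Species truth.** Baseline peak day (uniform over late spring to
  mid-summer), thermal sensitivity (days per °C; default uniform on
  [−8, 0] with a small number of atypical positive species), a critical
  window of 1–3 months weighted towards late winter, an abundance trend
  generated as trait effects plus Brownian-motion residuals on the tree,
  a residual phenology trend, flight-curve spread and expected season
  total.
* **Counts.** The expected weekly intensity is a Gaussian flight curve
  (two broods for multivoltine species, weights 0.65/0.35) centred on

  `peak = baseline_peak + sensitivity × (T_window − T_ref) + extra_trend × (year − start)`

  and renormalized so the season total follows
  `N₀ · exp(abundance_trend × (year − start))` exactly. Observed counts
  are independent Poisson draws; whole weekly visits are skipped with
  probability 0.1, shared across species.

Two generative choices deserve emphasis:

* **The temperature reference `T_ref` is regional, not site-specific.**
  A species at a persistently warmer site therefore flies persistently
  earlier, at the same days-per-degree slope that governs year-to-year
  variation. This matches the monitored system (altitudinal gradients in
  emergence date are ubiquitous) and it is what makes a mixed model with
  a site random intercept the right estimator: spatial and temporal
  temperature variation carry the same signal. Had the reference been
  site-specific, between-site temperature variation would carry no
  phenological signal at all, and pooled slopes would be attenuated
  towards zero.
* **Counts are Poisson** because the flight curves are fitted as Poisson
  generalized additive models; the generator deliberately matches the
  fitted observation family. Overdispersion, weather-dependent
  detectability, migration and spatial autocorrelation beyond shared
  trends are all absent, so passing recovery tests demonstrate
  correctness of the estimators under their own assumptions, not
  robustness to real-data violations of them.

## Flight curves and annual estimates

For each site-species-year with at least five weeks in which the species
was recorded, `fit_flight_curve()` fits
`count ~ s(julian_day, k = min(10, n_weeks − 1))` with a Poisson family
and REML smoothness selection (mgcv). The curve is predicted on a daily
grid spanning the first to last visit of that year; grid boundary points
are never accepted as peaks, which avoids edge artifacts from the spline
extrapolating towards the season limits. `detect_peaks()` keeps strict
interior local maxima whose height reaches 5 % of the curve maximum (the
prominence default; the threshold only matters for suppressing tiny
numerical wiggles and secondary shoulders). The annual phenological
estimate is the earliest retained peak; a per-species configuration hook
can select the second peak instead, for species whose first spring peak
reflects reactivated hibernated adults rather than emergence.

Annual abundance is `log(total count / recording events)`, with
recording events counted per site-year across all visits
(species-independent), so years with fewer visits remain comparable.
Natural logarithms are used throughout; a different base would only
rescale slopes.

Dataset-level inclusion rules mirror long-running monitoring practice:
sites need ≥ 10 monitored years; flagged migratory species and
multivoltine species with strongly overlapping broods are excluded (the
flags are inputs — the package does not try to detect them); species
need ≥ 3 usable populations. Every removal is logged with exactly one
primary reason, and the filter log partitions the input: each
site-species-year is either kept or carries one decision.

## Trends

Population trends are ordinary least squares of the annual estimate on
calendar year (minimum three years — the smallest n giving a p-value;
the 10-year rule applies to sites, not to each population-response
pair). Species trends use `response ~ year + (1 | site)` fitted by REML.
Fixed-effect p-values use the Wald t statistic with `n − p` residual
degrees of freedom — a deliberate, simple convention; Satterthwaite or
Kenward-Roger corrections are out of scope and would matter only at very
small group counts. Boundary (singular) random-effect fits are accepted
as valid estimates; only a nonzero optimizer return code marks
non-convergence. "Significant" everywhere means α = 0.05.

## The climate-window search

Candidate windows are every contiguous run of 1–3 months in the 13-slot
span from September of the previous year to September of the focal year
— 36 candidates. Window temperature is the unweighted mean of the
monthly means (`tmean` by default), with months Sep–Dec mapped to the
previous calendar year. For each window,
`peak_day ~ T_window + (1 | site)` is fitted by **maximum likelihood**,
because models differing in their fixed predictor are not comparable
under REML; the winning window (minimum AIC, ties broken deterministically
by shorter then earlier window) is refitted by REML to report the
sensitivity slope. Species need at least 10 phenology records across at
least 2 sites.

A caveat on post-selection inference: the p-value reported for the
selected window does not formally account for the search over 36
candidates (the winner's curse familiar from sliding-window climate
analyses). In the simulated schemes the inflation turns out to be mild —
under a true null about 8 % of species are classed as significantly
sensitive at α = 0.05 — because every candidate window shares the
dominant between-site temperature component, so the 36 tests are far
from independent. On data whose window temperatures are less correlated
the inflation could be larger; a calibrated statement about the
*existence* of a temperature effect would need a permutation or
split-sample correction, which is out of scope here.

## Comparative models

`brownian_covariance()` gives the shared-path-length matrix of the tree;
`fit_pgls()` solves the generalized least-squares problem
`β = (XᵀC⁻¹X)⁻¹XᵀC⁻¹y` by Cholesky whitening, with standard errors from
the GLS residual variance on `n − p` degrees of freedom and AICc from
the Gaussian maximum likelihood (`k = p + 1` parameters). λ is fixed at
1 (pure Brownian residuals) by default; `pagel_transform()` supports
down-weighting off-diagonals but no λ estimation is performed — the
models are deliberately the plain PGLS variant.

`trait_models()` fits one PGLS per trait for each response (sensitivity,
phenology trend, abundance trend), with HPI square-root transformed and
treatment contrasts on alphabetical reference levels, then one combined
model of the traits significant singly. `phenology_abundance_models()`
first regresses the square-root absolute phenology trend on sensitivity
— restricted to species with negative sensitivity, recording the
excluded positive-sensitivity species by id — and then regresses
abundance trends on each phenological variable alone and adjusted for
the significant traits. The two-step structure (screen traits, then
adjust) recomputes the significant set rather than hard-coding it.

## Numerical choices and degenerate inputs

* AIC ties in the window search and AICc ties in model ranking break
  deterministically (shorter/earlier window; fewer parameters).
* IDW interpolation (power 2 by default) returns the station residual
  exactly at zero distance; the two-step interpolation predicts directly
  at site coordinates rather than densifying a raster.
* Constant responses give zero slopes with undefined t statistics; the
  undefinedness is surfaced rather than masked.
* A species whose comparative-table trait has a single level is skipped
  in single-trait model loops (no contrast exists).
* All randomness flows from one configuration seed through a fixed
  execution order, so a configuration identifies a dataset byte for
  byte.

## Validation scale

The test suite validates parameter recovery end to end at 51 species ×
10 sites × 26 years (≈ 13,000 flight-curve fits and ≈ 1,900 window
models), a desk-scale counterpart of a 59-site scheme chosen to keep a
single-core run to a few minutes. At this scale the recovered
sensitivities correlate > 0.9 with truth, the selected window shares a
month with the true window for the large majority of strong-signal
species (|sensitivity| ≥ 2 days/°C), population abundance-trend slopes
have RMSE < 0.01 and near-nominal interval coverage, and PGLS recovers
simulated trait effects with ≈ 95 % coverage. What recovery at this
scale does **not** establish: robustness to overdispersed counts,
detectability trends, migratory influxes, or spatially correlated
climate anomalies — none of which the generator emulates.
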
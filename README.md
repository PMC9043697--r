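# phenowin

Butterfly populations leave a long paper trail: weekly transect counts
collected March–September, year after year, site after site. `phenowin`
turns those counts into the quantities ecologists argue about —
**when** each species flies, **how** its abundance and timing are
trending, **which part of the year's temperature** its phenology
responds to, and **whether species that track temperature well are the
ones holding their numbers** — and validates every step by recovering
known parameters from simulated monitoring schemes.

The package is aimed at ecologists analysing butterfly (or other
insect) monitoring-scheme data, and at methodologists who want a tested,
simulation-backed reference implementation of the flight-curve →
trend → climate-window → comparative-model chain.

## The analysis chain

1. **Flight curves.** For each site × species × year with the species
   recorded in ≥ 5 weeks, a penalized Poisson spline of count on Julian
   day (`mgcv`, REML smoothness) gives a daily flight curve; its first
   interior peak is the annual emergence estimate, and
   `log(total count / recording events)` the annual abundance index.
2. **Trends.** Population trends are OLS slopes on year; species trends
   come from `response ~ year + (1 | site)` mixed models. Classes
   (declining / stable / increasing) use α = 0.05.
3. **Critical periods.** For each species, 36 candidate temperature
   windows (1–3 consecutive months, September of the previous year to
   September of the focal year) are scored by the AIC of
   `peak_day ~ T_window + (1 | site)`; the best window is the species'
   *critical period* and its slope (days/°C) the species' *phenological
   sensitivity* — negative values mean earlier flight in warmer years.
4. **Comparative models.** Phylogenetic generalized least squares with
   Brownian covariance, `β = (XᵀC⁻¹X)⁻¹XᵀC⁻¹y`, relates species-level
   sensitivity, phenology trends and abundance trends to six ecological
   traits, and abundance trends to the phenological variables, with
   AICc model ranking.
5. **Synthetic data.** `simulate_dataset()` generates a full monitoring
   scheme (counts, monthly temperatures, traits, phylogeny) from a known
   ground truth, so every stage above is testable by parameter recovery.

## Worked example

```r
library(phenowin)

cfg  <- simulation_config(n_sites = 6, n_species = 12,
                          year_start = 1994, year_end = 2013, seed = 1)
ds   <- simulate_dataset(cfg)
filt <- apply_dataset_filters(ds$counts)
est  <- estimate_phenology_abundance(filt$kept)
sens <- species_sensitivities(est$phenology, ds$temperature)
head(sens[, c("species_id", "label", "sensitivity", "se", "sign_class")])
#>   species_id   label sensitivity         se sign_class
#> 1       sp01 Mar-May  -1.0458502 0.07357660    advance
#> 2       sp02     Dec  -0.9563895 0.09539975    advance
#> 3       sp03     Dec  -7.0178786 0.04800686    advance
#> 4       sp04 Mar-May  -5.3832884 0.10180051    advance
#> 5       sp05 Jul-Aug   2.5861289 0.08257958      delay
#> 6       sp06     Dec  -0.5131033 0.08034271    advance
```

`sp03` flies about 7 days earlier per extra degree in its December
critical period; `sp05` is one of the atypical species that delays.
Joining to the simulation truth, the recovered sensitivities correlate
1.00 (to 3 decimals) with the generating values on this small run. The
same objects feed the trend and comparative stages:

```r
tr <- estimate_trends(est$abundance, "log_abundance")
trend_summary(tr$species$class)
#>                  class n   percent
#> 1 significant_negative 9 75.000000
#> 2       nonsignificant 1  8.333333
#> 3 significant_positive 2 16.666667

temperature_trend_lmm(ds$temperature, "tmean", "annual", c(1994, 2013))
#>    slope     se implied_change p_value
#>   0.0212 0.0026         0.4031       0
```

Nine of twelve simulated species decline significantly while the region
warms by 0.021 °C/yr (0.40 °C over the 19-year span) — with the cooling
late-winter months that the default configuration builds in.

The numbered scripts under `analysis/` run the same chain as a
stage-by-stage workflow (`01_simulate.R` … `07_recovery.R`), writing
each stage's tables under `results/`; each stage reads only its
predecessors' CSV output.

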
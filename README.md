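# leafdemog

Demographic analysis of leaf cohorts in evergreen perennials whose
senescence control switches with the seasons.

Field protocols for leaf phenology tag the new leaves of marked plants at
biweekly censuses — all leaves that emerged since the previous census form
a **cohort**, with emergence date set to the census date — and record each
tagged leaf's fate weekly until it withers. `leafdemog` turns such census
tables (simulated or ingested) into cohort demography:

* **Survival.** Per cohort, the Kaplan–Meier estimate of leaf survival and
  a Weibull survival curve fitted to it,
  `S(x) = exp[-(x/β)^α]`, where `x` is days after emergence. The scale `β`
  (days) sets longevity; the shape `α` measures within-cohort *synchrony*
  of senescence (`α ≈ 1`: constant, age-independent mortality; large `α`:
  the cohort dies as one). Longevity is summarised as **L50**, days to 50 %
  survival, both empirically from the KM curve and as the fitted median
  `β·(ln 2)^(1/α)`.
* **Growth.** Mature leaf length (first measurement at ≥ 90 % of the
  maximum), growth period and growth rate per leaf and cohort.
* **Regimes.** k-means (silhouette-selected k) on standardised
  (L50, growth rate) separates growth-season (GS: short-lived,
  fast-growing, desynchronised) from overwintering (OW: long-lived,
  slow-growing, calendar-synchronised) cohorts, and a single-split entropy
  tree on 33-day post-emergence environmental means recovers the
  photoperiod threshold that decides a cohort's regime.
* **Age structure.** Whole-plant-population counts of extant and withered
  leaves by age class, reconstructed from the two tagged representative
  leaves per plant and cohort with exact per-cohort conservation, plus a
  multiplicative missing-plant adjustment.
* **Experiments.** Paired shading / sink-removal experiments: ΔL50 between
  arms and two-sample log-rank tests.

A full synthetic-data generator (`sim_config()`, `sim_leaves()`,
`sim_treatment()`) reproduces the statistical structure of the field
system — photoperiod-switched longevity regimes, weekly death detection,
sampling censoring, biweekly length measurement, paired treatment arms —
so the whole pipeline is testable end to end without any field data.

## Worked example

```r
library(leafdemog)

cfg <- sim_config(seed = 1)        # four years, 30 plants, defaults
cen <- sim_leaves(cfg)
cen
#> Leaf census: 3401 leaves (2803 tagged) in 104 cohorts, 30 plants
#>   cohorts 2017-10-10 .. 2021-09-21; 23.0% censored; regimes: GS=2707, OW=694

ld <- leaf_demography(cen)
ld
#> Leaf cohort demography analysis
#>   104 cohorts (104 with complete features), 3401 leaves
#>   GS: 63 cohorts, mean L50 59.9 d (range 30.1-95.5), mean alpha 1.35, mean growth 0.83 mm/d
#>   OW: 41 cohorts, mean L50 140.0 d (range 67.5-211.3), mean alpha 17.78, mean growth 0.34 mm/d
#>   silhouette-optimal k: 2
#>   Split rule: mean_photoperiod_h <= 11.37 -> OW, > 11.37 -> GS
#>   information gain 0.8553 bits; training error 2 / 104
```

GS cohorts live ~60 d with `α` near 1 (desynchronised, near-exponential
survival); OW cohorts live ~140 d with very large `α` — their deaths are
synchronised on the calendar, around flowering onset, not by leaf age. The
silhouette method confirms two groups, and the entropy split recovers the
planted 11.4 h photoperiod rule at 11.37 h (the midpoint between the two
cohorts bracketing the rule). `plot(ld)` draws the diagnostic panels;
`ld$cohorts` is the per-cohort table.

A paired sink-removal experiment on an overwintering cohort, with the
treated arm's lifespans shifted +27.1 d:

```r
ex <- sim_treatment(cfg, regime = "OW", delta_d = 27.1, n_per_arm = 70,
                    design = "between_plant", seed = 2)
compare_treatments(ex)
#> Treatment comparison (delta = treated - control, fitted medians)
#>       arm n_control n_treated L50_control_d L50_treated_d delta_L50_d
#> 1 treated        70        70          87.8         113.9       26.04
#>   delta_L50_empirical_d chisq  p_value
#> 1                 25.61  76.3 2.43e-18
```

The planted 27.1 d extension is recovered (26.0 d) and the arms separate
decisively under the log-rank test.

The core estimator is also usable directly:

```r
km  <- km_curve(c(7, 14, 21, 28, 35, 42), c(1, 1, 0, 1, 1, 1))
fit <- fit_weibull_km(km)
fit
#> Weibull fit to Kaplan-Meier survival curve
#>   shape (alpha, synchrony): 1.579
#>   scale (beta, days):       26.4
#>   fitted median L50: 20.93 d;  SSE 0.0312 over 5 event times
```

`coef()`, `predict()`, `residuals()`, `plot()`, `summary()` and
`simulate()` methods are available on the fit.

## Package layout

| | |
|---|---|
| `R/environment.R`, `R/sim-*.R` | day length, environment series, generative model |
| `R/survival.R` | `km_curve()`, `fit_weibull_km()` + methods, L50 conventions, log-rank, per-cohort summaries |
| `R/growth.R` | leaf and cohort growth descriptors |
| `R/classify.R` | environmental windows, k-means, silhouette, entropy split |
| `R/age-structure.R` | reconstruction, missing-plant adjustment, turnover |
| `R/pipeline.R` | `leaf_demography()` + methods, `compare_treatments()` |
| `R/io.R` | CSV interchange with seed provenance headers |
| `vignettes/leaf-cohort-demography.Rmd` | models, conventions and design choices |
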
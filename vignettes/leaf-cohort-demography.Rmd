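---
title: "Leaf cohort demography: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf cohort demography: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(leafdemog)
```

## The scientific problem

Evergreen rosette perennials at temperate latitudes keep leaves year-round,
but the leaves themselves are short-lived and turn over continuously. Field
protocols for studying this tag the new leaves of marked plants at regular
censuses: all leaves that emerged since the previous biweekly census form a
*cohort*, with their emergence date set to the census date, and the fate of
each tagged leaf (alive or withered) is recorded weekly. Two quantities
summarise a cohort's demography:

* **L50** — days from emergence until half the cohort's leaves have
  withered (median longevity);
* **synchrony** — whether leaves die independently of one another at a
  roughly constant rate, or all at once.

The striking empirical pattern this package is built around is a *seasonal
switch* between two senescence regimes. Cohorts emerging under long
photoperiods (the growth season, **GS**) live briefly, grow fast, and die
desynchronised — their survival curves decay roughly exponentially. Cohorts
emerging under short photoperiods (overwintering, **OW**) live much longer,
grow slowly, and die together in spring, synchronised in *calendar* time
with the onset of flowering rather than with their own age. The switch is
predicted almost perfectly by the photoperiod a cohort experiences just
after emergence, with a threshold near 11.4 h.

## The survival model

For each cohort we estimate the Kaplan–Meier survival curve of leaf age at
death, right-censoring leaves that were sampled or lost, and then fit the
two-parameter Weibull survival function

$$S(x) = \exp\!\left[-\left(\frac{x}{\beta}\right)^{\alpha}\right],$$

where $x$ is days after emergence, $\beta$ (days) is the scale, and the
dimensionless shape $\alpha$ measures within-cohort synchrony: $\alpha = 1$
is age-independent (exponential) mortality, large $\alpha$ means the cohort
dies as one. The fit minimises the unweighted sum of squared differences
between $S(x)$ and the Kaplan–Meier estimate at the event times — i.e. the
curve is fitted to the survival *plot*, not by maximum likelihood. Maximum
likelihood on the raw longevities is retained in the test suite as an
independent oracle; the two estimators agree to within a few percent on
clean Weibull samples, which is one of the package's acceptance checks.

Numerical conventions of `fit_weibull_km()`:

* initial values from the linearised regression of $\log(-\log S)$ on
  $\log x$, excluding points with $S \in \{0, 1\}$ (log-undefined), which
  are nevertheless retained in the least-squares objective;
* Nelder–Mead on $(\log\alpha, \log\beta)$, relative tolerance $10^{-10}$,
  restarted once from its own solution; bounds $\alpha \in (0.05, 50]$,
  $\beta \in (0, 10 \cdot \max x]$ enforced by penalty;
* cohorts with fewer than two distinct event times are unfittable and are
  reported flagged, never dropped silently.

Two L50 conventions are exposed, and both are reported per cohort:

* **empirical** (`l50_empirical()`, the primary per-cohort value): the
  Kaplan–Meier crossing of 0.5, with the midpoint of the flat interval when
  the estimate hits 0.5 exactly, and linear interpolation between the
  bracketing step points when it jumps across;
* **fitted** (`l50_weibull()`): the closed form
  $\beta (\ln 2)^{1/\alpha}$.

For *treatment-arm comparisons* the headline effect reported by
`compare_treatments()` is the difference of **fitted** medians. This is a
deliberate choice: deaths are only observed at weekly fate censuses, so the
empirical median moves on a 7-day lattice, and the difference of two
lattice-valued medians has several-fold higher variance than the difference
of the smooth fitted medians (we measured standard deviations of roughly
1.9 d versus 0.5 d for a typical shaded-cohort comparison, with negligible
bias for either). The empirical difference is reported alongside.

Arms are compared with the standard two-sample log-rank test
(`logrank_test()`, delegated to `survival::survdiff`), and its nominal size
is verified by simulation in the acceptance suite.

## The synthetic world

`sim_config()` + `sim_leaves()` generate census tables with the statistical
structure the analysis assumes, so that every downstream stage is testable
without any field data. The generative model, and what each default means:

| parameter | default | meaning |
|---|---|---|
| `latitude_deg` | 35.1 | temperate site; sets the photoperiod curve |
| `start_date`–`end_date` | 2017-10-10 – 2021-09-21 | four years of biweekly tagging censuses |
| `n_plants` | 30 | monitored plants |
| `census_interval_tag_d` / `census_interval_fate_d` | 14 / 7 | tagging (and length) vs fate censuses |
| `emergence_rate_fn` | summer-peaked sinusoid, mean ≈ 1.1 | new leaves per plant per biweek (Poisson) |
| `regime_threshold_h` | 11.4 | photoperiod rule deciding a leaf's regime |
| `window_d` | 33 | post-emergence window for environmental means |
| `gs_alpha`, `gs_beta` | 1, 86.3 | GS longevity Weibull; median 59.8 d |
| `flowering_onset_doy`, `flowering_sd_d` | 110, 10 | OW deaths: Gaussian around the next flowering onset |
| `min_survival_d` | 14 | floor on any drawn longevity |
| `growth_rate_gs` / `growth_rate_ow` | 0.9 / 0.35 mm/d | regime mean linear growth rates |
| `growth_rate_cohort_sd` / `growth_rate_leaf_sd` | 0.12 / 0.18 | lognormal growth-rate scatter (see below) |
| `mature_length_mean_mm` ± sd | 40 ± 8 | plateau of the linear growth curve |
| `censor_prob_per_census` | 0.02 | leaf sampled/removed at a fate census |
| `experiment_alpha` | 3.5 | within-experiment Weibull shape for GS arms |

Key structural choices:

* **Photoperiod** comes from the standard solar-declination day-length
  formula with a geometric (sun-centre) horizon and no refraction; the test
  suite checks it against an independent implementation of the NOAA sunrise
  equation and against `geosphere::daylength`, with 0.2–0.3 h agreement.
  Temperature is a sinusoid lagging photoperiod by 45 d; radiation a
  nonnegative sinusoid.
* **OW death is calendar-anchored, not an age-domain Weibull.** Each OW
  leaf's death date is drawn as Gaussian around the next flowering onset
  (at least 30 d after emergence). A high fitted $\alpha$ for OW cohorts is
  then an *emergent* property — exactly the property the synchrony analysis
  is supposed to detect — rather than something planted in the age domain.
  `ow_alpha` in the configuration records the nominal shape such cohorts
  exhibit but is never sampled from.
* **Census discretisation.** True death dates are detected at the next
  weekly fate census, so every observed longevity is a multiple of 7 d and
  never shorter than the true lifespan (by at most one census interval).
  Sampling censoring is applied per intermediate census with a geometric
  first-removal draw.
* **Growth-rate scatter.** Cohort mean growth rates vary within a regime in
  real data; the generator therefore multiplies the regime rate by mean-one
  lognormal factors at the cohort level (sd 0.12) and leaf level (sd 0.18).
  These values keep the two regimes' rate distributions separated by about
  three standard deviations even for small winter cohorts, reproducing the
  clean two-cluster structure and error-free photoperiod split that the
  regime dichotomy implies, while avoiding the degenerate zero-scatter
  world in which the silhouette method prefers splitting the elongated OW
  cluster along L50 into three groups.
* **Emergence rates** (magnitudes per plant per biweek) are free
  parameters of the field system; the default sinusoid peaks in summer and
  yields cohorts of a few dozen leaves at 30 plants, matching the scale of
  the field protocol.

### Treatment experiments

`sim_treatment()` generates paired manipulation experiments: a control arm
and treated arms drawn from the same cohort regime, with the treated
lifespans shifted additively by `delta_d` days *before* census
discretisation. Two choices deserve explanation:

* **Arms are matched.** Every treated leaf shares its baseline longevity
  draw with its control partner (shading arms sit on the same plant, sink
  arms on paired neighbouring plants). This mirrors the paired field
  designs and removes between-leaf variance from the effect estimate.
* **GS arms use `experiment_alpha` = 3.5, not the regime-average shape 1.**
  The GS regime's $\alpha \approx 1$ describes a whole cohort in the
  canopy. The same-aged, same-sized tagged leaves of a manipulation
  experiment senesce far more synchronously, and their survival curves drop
  steeply. The distinction matters statistically, not just cosmetically:
  an additive shift of an exponential ($\alpha = 1$) distribution leaves
  the hazard unchanged beyond the shift, so the log-rank test has
  essentially no power against it at any realistic sample size — we
  measured rejection rates near the nominal level for a 11.7 d shift at 60
  leaves/arm. A synchronised arm ($\alpha = 3.5$) with the same median
  makes the planted shift detectable with near-certain power at field
  sample sizes, which is what the corresponding field experiments report.

## Growth metrics

Per leaf, from the biweekly length series: the maximum length over all
measurements; the *mature length* as the first measurement reaching 90% of
that maximum (inclusive — with real-valued lengths the strict/non-strict
distinction only matters on exact ties, and inclusive is deterministic on
the simulator's grid); the *growth period* as days from the cohort census
date to that measurement; and the *growth rate* as mature length divided by
growth period. Leaves with maximum length under 10 mm, or mature at the
emergence census itself (period 0), are excluded from cohort means but kept
flagged. Because measurements are biweekly, a recovered rate is bounded
between `mature/(t_cross)` and `mature/(t_cross + 14)` where `t_cross` is
the true crossing time — a discretisation bound the tests verify against
the analytic crossing of a linear growth model.

## Classification and the decision threshold

Cohorts with complete features are clustered by k-means (Lloyd's algorithm,
20 restarts, best within-cluster sum of squares kept) on z-standardised
(L50, growth rate). Standardisation is essential: L50 spans tens to
hundreds of days while growth rates are below 2 mm/d, so unscaled
clustering would be longevity-only. The number of clusters is selected by
the mean silhouette width over k = 2…6; regime *names* always come from the
two-cluster solution, the cluster with smaller mean L50 being GS.

The environmental determinant is recovered by a depth-one entropy tree
(`entropy_split()`): every midpoint between consecutive distinct values of
each candidate feature (photoperiod, temperature, radiation averaged over
the 33 d after emergence) is scored by information gain, ties broken in
that feature order. A single split suffices because the published structure
is a single zero-error photoperiod threshold; the midpoint convention
places the recovered threshold strictly between the bordering cohorts, so
its distance from the planted rule is bounded by the photoperiod spacing of
adjacent cohorts.

## Age-structure reconstruction

Only two leaves per plant and cohort are tagged, but all new leaves are
counted at tagging. The whole-population age structure is reconstructed per
cohort and census by representative scaling: the fraction of that cohort's
tagged leaves still alive (tagged leaves censored by sampling drop out of
the denominator) times the cohort's initial total. Cumulative withered
counts are the complement, so *extant + cumulative withered = initial
total* holds exactly at every census — the estimator's conservation
property, which the tests assert to machine precision. The scaling phrase
"ratio of extant to withered tagged leaves" admits two readings
(extant/withered vs extant/total); only extant/total satisfies
conservation, so that reading is used. When a census finds no tagged leaf
of a cohort under observation the last available ratio is carried forward
and the row is flagged as untracked. Counts are kept fractional until final
reporting; censuses with missing plants are adjusted multiplicatively
(`adjust_missing_plants()`: observed × reference/present). Age classes are
30-day bins by default.

## What the simulations do and do not establish

The generator reproduces the statistical skeleton of the field system:
photoperiod-switched regimes, calendar-synchronised OW death, weekly
detection, sampling censoring, biweekly growth measurements, paired
experiments. Passing tests therefore establish that the estimators recover
*planted* structure through the full observation model. They do not
establish anything about features the generator lacks: herbivory and flood
losses beyond generic censoring, within-plant correlation of leaf fates,
temperature-dependent growth suppression in summer, year-to-year variation
in flowering onset, or measurement error in lengths (available via
`length_noise_sd_mm` but off by default). Real censuses also start tagging
leaves mid-protocol (the earliest field cohorts lack length data); the
pipeline handles such cohorts by flagging them out of classification rather
than imputing.

## Problem sizes and runtime choices

The default four-year, 30-plant census (≈ 3,400 leaves, ≈ 104 cohorts)
drives the classification and synchrony analyses; parameter-recovery
properties use 200 cohorts of 50 leaves; the log-rank size check uses 2,000
null replicates at 30 leaves/arm; treatment recovery uses 60–70 leaves/arm,
the scale of the corresponding field experiments. These sizes make the full
suite run in about a minute and a half while leaving Monte-Carlo margins
far from the asserted bounds.

## Known limitations

* The Weibull-to-KM fit treats the KM step values as homoskedastic
  observations; no weighting by at-risk numbers is applied (none is
  standard for this estimator, and the unweighted fit is what the analysis
  is defined as).
* `l50_empirical()` is undefined (NA) for cohorts whose survival never
  reaches 0.5; downstream stages flag rather than impute such cohorts.
* The entropy tree is depth one by design; it recovers a single threshold,
  not interactions between environmental drivers.
* OW longevity inherits its variance from the calendar-anchored death
  model, so simulated OW L50 ranges are slightly wider than field ranges
  when emergence spans the full October–February window.
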
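Package: leafdemog
Title: Leaf Cohort Demography, Survival Synchrony and Seasonal Senescence Regimes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demographic analysis of leaf cohorts in evergreen perennials that
    switch seasonally between senescence regimes. Simulates or ingests
    long-format leaf census records, estimates Kaplan-Meier survival per
    biweekly emergence cohort, fits Weibull survival curves to the
    product-limit estimates to extract cohort longevity (L50) and senescence
    synchrony (the Weibull shape), classifies cohorts into growth-season and
    overwintering regimes by k-means with silhouette-selected k, recovers the
    photoperiod decision threshold with a single-split entropy tree,
    reconstructs whole-plant leaf age structures from tagged representative
    leaves, and quantifies treatment effects (shading, sink removal) on leaf
    longevity with log-rank comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    cluster
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    geosphere,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
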
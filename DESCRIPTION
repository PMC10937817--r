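Package: hbrnorm
Title: Hierarchical Bayesian Normative Modeling of Regional Cortical Thickness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Normative modeling of regional cortical thickness over the
    148-region Destrieux parcellation. Fits a per-region hierarchical
    Bayesian regression of thickness on age and sex with site-level random
    intercepts and heteroscedastic site noise, transfers the fitted model to
    a new acquisition site from a small local control sample, and converts
    clinical scans into posterior-predictive deviation z-scores. Downstream
    tooling derives outlier flags (z < -1.96), per-subject total outlier
    counts, regional prevalence maps, superior-temporal-sulcus status,
    Hamming-distance heterogeneity summaries, and the accompanying group
    statistics (ANCOVA, region-wise Welch t-tests with FDR, Mann-Whitney,
    two-way location-by-phenotype ANOVA, SUVR regressions). A seeded
    multi-site cohort simulator generates reference, adaptation and clinical
    cohorts with known ground truth so the whole pipeline is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
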
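Package: vaxsafety
Title: Propensity-Matched Comparative Vaccine Safety Analysis with Empirical Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for comparative observational vaccine
    safety studies of the active-comparator new-user cohort design: brand- and
    dose-specific vaccination cohorts with eligibility rules and 28-day risk
    windows, thromboembolic outcome ascertainment including the thrombosis
    with thrombocytopenia syndrome (TTS) phenotype, large-scale L1-regularised
    propensity-score models with greedy variable-ratio caliper matching and
    covariate-balance diagnostics, Poisson incidence rate ratios with exact
    rate confidence intervals, minimum detectable rate ratio power
    diagnostics, negative-control-outcome empirical calibration of p-values
    and confidence intervals, and DerSimonian-Laird random-effects
    meta-analysis across databases. A synthetic data generator with known
    confounding, known true rate ratios, and injectable systematic error
    makes every stage testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    glmnet,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
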
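Package: caseseries
Title: Case-Series Analysis of Neuropsychological Test Batteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for case-series neuropsychology: probabilistic principal
    components analysis (PPCA) imputation of missing battery scores with
    cross-validated selection of the component count, varimax-rotated group
    PCA with projection of control norms and impairment cutoffs into the
    factor space, domain composite scores, Bayesian single-case tests for a
    deficit and for a standardised difference allowing for covariates, and
    classification of per-patient deficit patterns and pairwise
    dissociations. Includes a synthetic cohort generator with ground-truth
    labels for recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    MASS,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
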
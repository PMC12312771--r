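Package: ipdmasem
Title: Individual Participant Data Meta-Analytic Structural Equation Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and estimation tools for meta-analytic structural
    equation modeling (MASEM) with individual participant data (IPD).
    Generates two-level multivariate normal IPD collections from
    path-model population matrices, and fits five estimators to them:
    the naive-pooling and cluster-robust single-level path model
    (sandwich standard errors and a mean-scaled chi-square), the
    partially saturated and structured two-level path models by direct
    full-information maximum likelihood on unbalanced clusters,
    fixed-effects multivariate meta-analysis of path coefficients, and
    fixed-effects one-stage MASEM on study correlation vectors.
    Includes a Monte Carlo study runner with the usual evaluation
    criteria (RMSE, relative standard-error bias, exact-fit and
    RMSEA close-fit rejection rates).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
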
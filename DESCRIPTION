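Package: gbdcm
Title: Generalized Bayesian Estimation for Diagnostic Classification Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Loss-function-based (Gibbs posterior) Bayesian inference for
    attribute mastery patterns in diagnostic classification models (DCMs).
    Implements the generalized Bayesian counterparts of the nonparametric
    classification method (Hamming loss on DINA ideal responses) and of the
    generalized nonparametric classification method (squared-Euclidean loss
    on weighted DINA/DINO ideal responses), sampled by Metropolis-Hastings
    within Gibbs; the corresponding NPC and GNPC point estimators; a MAP
    estimator by coordinate descent under the Q-matrix constraint; a
    synthetic-data generator for factorial recovery studies (correlated
    attributes from a thresholded compound-symmetry normal, DINA or general
    monotone DCM item response probabilities); and recovery metrics
    (attribute- and pattern-level agreement, half-split MCMC stability,
    pattern tabulations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
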
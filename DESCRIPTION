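Package: pcspanel
Title: Stability-Driven Biomarker Panel Selection for qPCR Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for developing simplified gene-expression risk panels
    from qPCR cycle-threshold (Ct) data using a stability-driven ranking
    procedure. Candidate genes are ranked by model-based importance across a
    perturbation grid of preprocessing pipelines, prediction-checked learner
    ensembles, and repeated development/test splits; genes that are both
    highly ranked and highly stable across the grid are selected into a
    compact panel. Includes delta-Ct preprocessing with censoring-aware
    imputation, a tunable model zoo (penalized logistic regression, random
    forests, gradient boosting), internal panel-size validation, final ridge
    risk-model fitting with logistic recalibration, sensitivity-anchored
    operating-point metrics, and a minimum-test-tradeoff analysis. A
    synthetic-cohort simulator with planted signal genes makes every stage
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
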
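Package: passr
Title: Prior Adaptive Semi-Supervised Estimation for High-Dimensional
    Phenotyping Models
Version: 0.1.0
Authors@R: person("EHR Methods", "Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semi-supervised estimation of high-dimensional logistic
    phenotype models that borrow strength from a large unlabeled cohort
    through a surrogate outcome (e.g. billing-code counts).  Implements the
    prior adaptive semi-supervised (PASS) estimator, which shrinks the
    feature coefficients toward a scalar multiple of the surrogate's
    single-index direction with separate penalty levels on and off the
    surrogate support, together with the supervised LASSO/ALASSO,
    prior-informed and unsupervised benchmark estimators, a simulation
    engine for the main and mis-specification scenarios, and evaluation
    metrics (AUC, excess risk, MSE of predicted probabilities, Brier skill
    score).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    data.table,
    jsonlite,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
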
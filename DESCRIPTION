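Package: hsiclasso
Title: Nonlinear Metabolite Feature Selection and Kernel Prediction of
    Depressive Symptoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metabolome-based prediction of depressive symptom scores with
    nonlinear feature selection. Implements the Hilbert-Schmidt independence
    criterion (HSIC) Lasso screen -- a nonnegative L1-penalized fit of the
    outcome Gram matrix by feature Gram matrices -- combined with kernel ridge
    regression for quantitative scores and RBF support-vector classification
    for binary traits, evaluated in a three-level nested five-fold
    cross-validation shared across a registry of baseline models (lasso,
    partial least squares, sparse partial least squares, p-value screening,
    random forest, covariates-only and all-variable regressions). Also
    provides exact two-sided Fisher tests for r x 2 contingency tables by
    hypergeometric enumeration, pooled two-sample t tests, selection-frequency
    marker summaries, covariate-adjusted per-metabolite regressions, pairwise
    HSIC dependency tables, and a seed-reproducible synthetic cohort generator
    with planted sparse nonlinear signal, redundant feature blocks and mixed
    covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    glmnet,
    kernlab,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
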
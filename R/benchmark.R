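#' Fixed simulation studies shipped with the package
#'
#' Two study designs are fixed here, once, so that every consumer (tests,
#' scripts, vignettes) evaluates the method under identical conditions.
#'
#' * The *recovery study*: cohorts of 400 subjects and 100 metabolites with
#'   5 planted causal features (links cycling quadratic, sine, threshold,
#'   linear -- so a purely even quadratic link, invisible to linear screens,
#'   is always present) and no covariate effects; the question is how often
#'   a 10-feature screen recovers the planted signal.
#' * The *prediction study*: full default cohort structure at a reduced
#'   scale (300 subjects, 60 metabolites plus the 8 covariates) with
#'   compact tuning grids, comparing HSIC Lasso + kernel ridge against the
#'   lasso under the shared nested cross-validation.
#'
#' These sizes keep a 20-seed replication within a desktop compute budget
#' while preserving the qualitative structure of the full-scale design.
#'
#' @name benchmark
#' @keywords internal
NULL

#' Configuration of the recovery study
#'
#' @param seed cohort seed.
#' @return a [cohort_config()].
#' @export
recovery_config <- function(seed) {
  cohort_config(n_subjects = 400, n_metabolites = 100, n_causal = 5,
                effect_functions = c("quadratic", "sine", "threshold",
                                     "linear", "linear"),
                covariate_effects = c(sex = 0), seed = seed)
}

#' Lasso screen retaining a fixed number of features
#'
#' The linear counterpart of [path_select_k()]: fits the glmnet lasso path
#' and returns the `k` features with the largest absolute coefficients at
#' the first path point whose active set reaches size `k` (or the largest
#' active set if `k` is never reached).
#'
#' @param X feature matrix.
#' @param y outcome.
#' @param k number of features to retain.
#' @param binary logistic loss?
#' @return character vector of feature names.
#' @export
lasso_select_k <- function(X, y, k, binary = FALSE) {
  fam <- if (binary) "binomial" else "gaussian"
  fit <- glmnet::glmnet(as.matrix(X), y, family = fam, standardize = TRUE,
                        nlambda = 200)
  B <- as.matrix(fit$beta)
  nnz <- colSums(B != 0)
  j <- which(nnz >= k)[1]
  if (is.na(j)) j <- which.max(nnz)
  cf <- B[, j]
  names(sort(abs(cf[cf != 0]), decreasing = TRUE))[seq_len(min(k, sum(cf != 0)))]
}

#' Configuration and models of the prediction study
#'
#' @param seed cohort seed.
#' @return list with `config` (a [cohort_config()]) and `models` (the
#'   HSIC Lasso + KR and lasso `model_spec`s with the study's compact grids).
#' @export
prediction_study <- function(seed) {
  list(config = cohort_config(n_subjects = 300, n_metabolites = 60, seed = seed),
       models = list(
         hsic_kr = model_spec("HSIC Lasso + KR", "hsic_lasso", "kernel_ridge",
                              selector_grid = list(k = c(5, 10)),
                              predictor_grid = list(sigma_mult = c(0.5, 1, 2),
                                                    lambda = c(0.01, 1))),
         lasso = model_spec("Lasso", "none", "lasso_linear",
                            predictor_grid = list(lambda = 10^seq(-3, 0.5,
                                                                  length.out = 10)))))
}
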
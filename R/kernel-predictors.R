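#' Kernel predictors paired with the HSIC Lasso screen
#'
#' Quantitative scores are predicted by kernel ridge regression (KR) with an
#' RBF kernel, fitted natively by an n x n linear solve in the dual:
#' \deqn{\beta = (K + \lambda m I)^{-1} (y - \bar y), \qquad
#'       f(x) = \bar y + \sum_i \beta_i \exp(-\|x - x_i\|^2 / (2\sigma^2)).}
#' Binary traits are predicted by a soft-margin RBF support-vector machine
#' delegated to \pkg{kernlab}, wrapped so that real-valued decision scores
#' (needed for AUC) are exposed. Features are standardized with
#' training-fold statistics only.
#'
#' @name kernel_predictors
#' @keywords internal
NULL

standardize_train <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv, X = sweep(sweep(X, 2, mu), 2, sdv, "/"))
}

standardize_apply <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

rbf_kernel <- function(A, B, sigma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Median-heuristic length scale of a feature matrix
#'
#' Median pairwise Euclidean distance between (standardized) rows; the base
#' unit of the bandwidth grid.
#'
#' @param X numeric matrix.
#' @param max_n cap on rows entering the pairwise computation; larger inputs
#'   are thinned deterministically (evenly spaced rows).
#' @return positive scalar.
#' @export
median_heuristic <- function(X, max_n = 500) {
  X <- as.matrix(X)
  if (nrow(X) > max_n)
    X <- X[unique(round(seq(1, nrow(X), length.out = max_n))), , drop = FALSE]
  d <- stats::dist(X)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Fit kernel ridge regression
#'
#' @param X m x d training matrix (raw scale; standardized internally).
#' @param y numeric outcome.
#' @param sigma RBF bandwidth on the standardized scale.
#' @param lambda ridge penalty; the system solved is `(K + lambda*m*I) beta = y - mean(y)`.
#' @param standardize rescale each feature by training mean/SD (the default;
#'   disable when inputs are already on a common scale).
#' @return `kernel_ridge` model object.
#' @export
fit_kernel_ridge <- function(X, y, sigma, lambda, standardize = TRUE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, ncol(X) >= 1, length(y) == nrow(X),
            sigma > 0, lambda >= 0)
  st <- if (standardize) standardize_train(X)
        else list(mu = rep(0, ncol(X)), sd = rep(1, ncol(X)), X = X)
  K <- rbf_kernel(st$X, st$X, sigma)
  m <- nrow(X)
  A <- K + diag(lambda * m, m)
  beta <- tryCatch(solve(A, y - mean(y)),
                   error = function(e)
                     stop("fit_kernel_ridge: singular system; use lambda > 0"))
  structure(list(Xs = st$X, mu = st$mu, sd = st$sd, beta = drop(beta),
                 y_mean = mean(y), sigma = sigma, lambda = lambda),
            class = "kernel_ridge")
}

#' Predict from a kernel ridge model
#'
#' @param object a `kernel_ridge` model.
#' @param newdata matrix on the raw feature scale.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.kernel_ridge <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$Xs))
    stop("predict.kernel_ridge: dimension mismatch")
  Kn <- rbf_kernel(standardize_apply(newdata, object), object$Xs, object$sigma)
  drop(Kn %*% object$beta) + object$y_mean
}

#' Fit a soft-margin RBF support-vector classifier
#'
#' Wraps `kernlab::ksvm` (RBF kernel, cost `C`), exposing real decision
#' values oriented so that larger values indicate the positive class
#' (orientation fixed on training data only).
#'
#' @param X m x d training matrix.
#' @param labels 0/1 vector or 2-level factor; both classes must be present.
#' @param sigma RBF bandwidth on the standardized scale.
#' @param C soft-margin cost.
#' @return `svm_rbf` model object.
#' @export
fit_svm_rbf <- function(X, labels, sigma, C) {
  X <- as.matrix(X)
  f <- as.factor(labels)
  if (nlevels(droplevels(f)) < 2)
    stop("fit_svm_rbf: single-class training fold; re-draw stratified folds")
  stopifnot(sigma > 0, C > 0)
  st <- standardize_train(X)
  fit <- kernlab::ksvm(st$X, f, type = "C-svc", C = C, scaled = FALSE,
                       kernel = "rbfdot", kpar = list(sigma = 1 / (2 * sigma^2)))
  dec <- kernlab::predict(fit, st$X, type = "decision")[, 1]
  pos <- levels(f)[2]
  flip <- mean(dec[f == pos]) < mean(dec[f != pos])
  structure(list(fit = fit, mu = st$mu, sd = st$sd, flip = flip,
                 positive = pos, sigma = sigma, C = C),
            class = "svm_rbf")
}

#' Decision values of an RBF-SVM on new data
#'
#' @param model an `svm_rbf` model.
#' @param newdata matrix on the raw feature scale.
#' @return numeric decision values (larger = more likely positive class).
#' @export
decision_function <- function(model, newdata) {
  stopifnot(inherits(model, "svm_rbf"))
  Xs <- standardize_apply(as.matrix(newdata), model)
  dec <- kernlab::predict(model$fit, Xs, type = "decision")[, 1]
  if (model$flip) -dec else dec
}
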
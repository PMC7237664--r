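#' Gram matrices and the empirical HSIC statistic
#'
#' The Hilbert-Schmidt independence criterion (HSIC) is a kernel-based
#' dependency measure: it is nonnegative and, in population, zero exactly
#' when the two variables are independent. The empirical estimator used
#' throughout this package is
#' \deqn{\widehat{HSIC}(u, v) = (n-1)^{-2}\,\mathrm{tr}(\bar K \bar L),}
#' where \eqn{\bar K = \Gamma K \Gamma} is the doubly centered Gram matrix of
#' \eqn{u} (\eqn{\Gamma = I - n^{-1}\mathbf{1}\mathbf{1}^\top}) and
#' \eqn{\bar L} that of \eqn{v}. Continuous variables use a Gaussian kernel
#' on standardized values; categorical variables use a class-frequency
#' normalized delta kernel.
#'
#' @name kernels
#' @keywords internal
NULL

new_gram <- function(values, kind, centered = FALSE, normalized = FALSE) {
  structure(list(values = values, kind = kind, centered = centered,
                 frobenius_normalized = normalized),
            class = "gram_matrix")
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat(sprintf("<gram_matrix> %s kernel, n = %d, centered = %s, normalized = %s\n",
              x$kind, nrow(x$values), x$centered, x$frobenius_normalized))
  invisible(x)
}

#' Gaussian (RBF) Gram matrix of a single variable
#'
#' Computes \eqn{K_{ij} = \exp(-(x_i - x_j)^2 / (2\sigma^2))}, optionally on
#' the zero-mean, unit-SD rescaling of `x`. Standardizing and fixing the
#' bandwidth at 1 is the convention used by the selector, so that penalty
#' scales are comparable across features.
#'
#' @param x numeric vector, length >= 2.
#' @param bandwidth kernel bandwidth \eqn{\sigma > 0}.
#' @param standardize rescale `x` to zero mean, unit SD first?
#' @return A `gram_matrix` object (uncentered).
#' @export
gaussian_gram <- function(x, bandwidth = 1, standardize = TRUE) {
  stopifnot(is.numeric(x), length(x) >= 2, bandwidth > 0)
  if (anyNA(x)) stop("gaussian_gram: input contains missing values")
  if (standardize) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("gaussian_gram: zero-variance input cannot be standardized (degenerate feature)")
    x <- (x - mean(x)) / s
  }
  d <- outer(x, x, "-")
  K <- exp(-(d * d) / (2 * bandwidth^2))
  new_gram(K, "gaussian")
}

#' Class-frequency normalized delta kernel Gram matrix
#'
#' \eqn{K_{ij} = 1/n_c} when subjects i and j share class c, else 0. The
#' 1/n_c normalization gives every class equal total kernel mass, which keeps
#' rare categories (e.g. antidepressant use) from being swamped.
#'
#' @param labels vector coercible to factor.
#' @return A `gram_matrix` object (uncentered).
#' @export
delta_gram <- function(labels) {
  f <- as.factor(labels)
  stopifnot(length(f) >= 2, nlevels(f) >= 1)
  if (anyNA(f)) stop("delta_gram: input contains missing values")
  counts <- tabulate(f, nbins = nlevels(f))
  same <- outer(f, f, "==")
  K <- ifelse(same, 1 / counts[as.integer(f)][row(same)], 0)
  new_gram(K, "delta")
}

#' Double-center a Gram matrix
#'
#' Returns \eqn{\Gamma K \Gamma} with \eqn{\Gamma = I - n^{-1} 1 1^\top};
#' idempotent, and every row/column sum of the result is 0.
#'
#' @param K a `gram_matrix` or plain symmetric matrix.
#' @return centered `gram_matrix`.
#' @export
center_gram <- function(K) {
  g <- if (inherits(K, "gram_matrix")) K else new_gram(as.matrix(K), "custom")
  M <- g$values
  rm_ <- rowMeans(M)
  gm <- mean(M)
  M <- M - outer(rm_, rep(1, ncol(M))) - outer(rep(1, nrow(M)), colMeans(M)) + gm
  new_gram(M, g$kind, centered = TRUE, normalized = g$frobenius_normalized)
}

#' Frobenius-normalize a Gram matrix
#'
#' Divides by the Frobenius norm so that \eqn{\|K\|_F = 1}. Applied after
#' centering inside the selector, this makes the self-dependency of every
#' non-degenerate feature identical, so penalties act on comparable scales.
#'
#' @param K a `gram_matrix`.
#' @return normalized `gram_matrix`.
#' @export
frobenius_normalize <- function(K) {
  g <- if (inherits(K, "gram_matrix")) K else new_gram(as.matrix(K), "custom")
  nf <- sqrt(sum(g$values^2))
  if (nf == 0) stop("frobenius_normalize: zero matrix (degenerate feature)")
  new_gram(g$values / nf, g$kind, centered = g$centered, normalized = TRUE)
}

#' Kernelize one variable according to its kind
#'
#' Dispatches to [gaussian_gram()] for continuous variables and
#' [delta_gram()] for categorical ones, then centers (and optionally
#' Frobenius-normalizes) the result.
#'
#' @param x the variable.
#' @param kind `"continuous"` or `"categorical"`.
#' @param bandwidth Gaussian bandwidth (continuous only).
#' @param normalize Frobenius-normalize after centering?
#' @return centered `gram_matrix`.
#' @export
feature_gram <- function(x, kind = c("continuous", "categorical"),
                         bandwidth = 1, normalize = FALSE) {
  kind <- match.arg(kind)
  K <- if (kind == "continuous") gaussian_gram(x, bandwidth = bandwidth, standardize = TRUE)
       else delta_gram(x)
  K <- center_gram(K)
  if (normalize) K <- frobenius_normalize(K)
  K
}

#' Empirical HSIC statistic between two variables
#'
#' \eqn{(n-1)^{-2}\,\mathrm{tr}(\bar K \bar L)} with kind-appropriate
#' kernels; symmetric in its arguments and nonnegative up to numerical
#' round-off. With `normalized = TRUE` the centered Grams are
#' Frobenius-normalized first, giving a scale-free dependency score with
#' self-dependency \eqn{(n-1)^{-2}} for every non-degenerate variable.
#'
#' @param u,v equal-length variables.
#' @param kind_u,kind_v `"continuous"` or `"categorical"`.
#' @param bandwidth Gaussian bandwidth for continuous variables.
#' @param normalized use Frobenius-normalized centered Grams?
#' @return nonnegative scalar.
#' @export
hsic_statistic <- function(u, v,
                           kind_u = "continuous", kind_v = "continuous",
                           bandwidth = 1, normalized = FALSE) {
  if (length(u) != length(v)) stop("hsic_statistic: length mismatch")
  n <- length(u)
  # a constant variable has a constant Gram, which centering annihilates:
  # its HSIC with anything is exactly 0
  if (is_degenerate(u, kind_u) || is_degenerate(v, kind_v)) return(0)
  Ku <- feature_gram(u, kind_u, bandwidth = bandwidth, normalize = normalized)
  Kv <- feature_gram(v, kind_v, bandwidth = bandwidth, normalize = normalized)
  sum(Ku$values * Kv$values) / (n - 1)^2
}

is_degenerate <- function(x, kind) {
  if (kind == "categorical") length(unique(x)) < 2 else isTRUE(stats::sd(x) == 0)
}
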
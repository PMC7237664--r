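#' HSIC Lasso feature screening
#'
#' HSIC Lasso selects features that are strongly dependent on the outcome
#' while mutually non-redundant. Writing \eqn{\bar K^{(k)}} for the centered,
#' Frobenius-normalized Gram matrix of candidate feature k and \eqn{\bar L}
#' for that of the outcome, it solves the nonnegative lasso
#' \deqn{\min_{\alpha \ge 0} \tfrac12 \|\bar L - \textstyle\sum_k \alpha_k
#'   \bar K^{(k)}\|_F^2 + \lambda \|\alpha\|_1,}
#' equivalently \eqn{\tfrac12 \alpha^\top Q \alpha - c^\top \alpha +
#' \lambda \sum_k \alpha_k} with
#' \eqn{Q_{kl} = \langle \bar K^{(k)}, \bar K^{(l)} \rangle_F} and
#' \eqn{c_k = \langle \bar K^{(k)}, \bar L \rangle_F} (an unnormalized HSIC
#' between feature k and the outcome). Features with \eqn{\alpha_k > 0} are
#' selected; the feature-feature term \eqn{Q} penalizes redundant features
#' so that typically only one of a block of mutually dependent metabolites
#' becomes active.
#'
#' @name hsic_lasso
#' @keywords internal
NULL

#' Build an HSIC Lasso problem from a feature matrix and an outcome
#'
#' Computes the quadratic form `Q` (feature-feature Frobenius inner
#' products) and linear term `c` (feature-outcome HSICs) over centered,
#' Frobenius-normalized Gram matrices. The outcome uses a Gaussian kernel on
#' the standardized scores when quantitative, and a class-frequency
#' normalized delta kernel when binary. Gram matrices are processed in
#' feature blocks so that at most `2 * block_size` of them are held in
#' memory at once.
#'
#' @param X numeric matrix, subjects x candidate features (named columns).
#' @param kinds character vector per column, `"continuous"`/`"categorical"`.
#' @param y outcome vector.
#' @param outcome_kind `"quantitative"` or `"binary"`.
#' @param bandwidth Gaussian bandwidth for continuous variables.
#' @param block_size features per Gram block.
#' @return An object of class `hsic_problem` with elements `Q`, `c`,
#'   `feature_ids`, `outcome_kind`, `n`, and `dropped` (zero-variance
#'   columns excluded, with a warning).
#' @export
build_hsic_problem <- function(X, kinds = NULL, y,
                               outcome_kind = c("quantitative", "binary"),
                               bandwidth = 1, block_size = 64) {
  outcome_kind <- match.arg(outcome_kind)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3, length(y) == n)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (is.null(kinds)) kinds <- rep("continuous", ncol(X))
  stopifnot(length(kinds) == ncol(X))

  degen <- vapply(seq_len(ncol(X)), function(j) is_degenerate(X[, j], kinds[j]), logical(1))
  dropped <- colnames(X)[degen]
  if (length(dropped)) {
    warning("build_hsic_problem: excluding zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, !degen, drop = FALSE]
    kinds <- kinds[!degen]
  }
  p <- ncol(X)
  if (p == 0) stop("build_hsic_problem: no non-degenerate features left")

  L <- if (outcome_kind == "quantitative") {
    feature_gram(y, "continuous", bandwidth = bandwidth, normalize = TRUE)
  } else {
    feature_gram(y, "categorical", normalize = TRUE)
  }
  lvec <- as.vector(L$values)

  gram_block <- function(cols) {
    G <- matrix(0, n * n, length(cols))
    for (i in seq_along(cols)) {
      g <- feature_gram(X[, cols[i]], kinds[cols[i]],
                        bandwidth = bandwidth, normalize = TRUE)
      G[, i] <- as.vector(g$values)
    }
    G
  }

  blocks <- split(seq_len(p), ceiling(seq_len(p) / block_size))
  Q <- matrix(0, p, p)
  cc <- numeric(p)
  for (bi in seq_along(blocks)) {
    Gi <- gram_block(blocks[[bi]])
    cc[blocks[[bi]]] <- drop(crossprod(Gi, lvec))
    Q[blocks[[bi]], blocks[[bi]]] <- crossprod(Gi)
    if (bi < length(blocks)) {
      for (bj in seq(bi + 1, length(blocks))) {
        Gj <- gram_block(blocks[[bj]])
        B <- crossprod(Gi, Gj)
        Q[blocks[[bi]], blocks[[bj]]] <- B
        Q[blocks[[bj]], blocks[[bi]]] <- t(B)
      }
    }
  }
  dimnames(Q) <- list(colnames(X), colnames(X))
  names(cc) <- colnames(X)

  structure(list(Q = Q, c = cc, feature_ids = colnames(X),
                 outcome_kind = outcome_kind, n = n, dropped = dropped),
            class = "hsic_problem")
}

#' @export
print.hsic_problem <- function(x, ...) {
  cat(sprintf("<hsic_problem> %d candidate features, n = %d, %s outcome\n",
              length(x$feature_ids), x$n, x$outcome_kind))
  invisible(x)
}

#' Solve the nonnegative lasso by cyclic coordinate descent
#'
#' Minimizes \eqn{\tfrac12 \alpha^\top Q \alpha - c^\top \alpha + \lambda
#' \sum_k \alpha_k} over \eqn{\alpha \ge 0} with the closed-form coordinate
#' update \eqn{\alpha_k \leftarrow \max\{0, (c_k - \sum_{l \ne k} Q_{kl}
#' \alpha_l - \lambda) / Q_{kk}\}}. Convergence is certified by the KKT
#' residual: for active k, \eqn{|(Q\alpha)_k - c_k + \lambda| \le tol}; for
#' inactive k, \eqn{(Q\alpha)_k - c_k + \lambda \ge -tol}.
#'
#' @param problem an `hsic_problem`.
#' @param penalty \eqn{\lambda \ge 0}.
#' @param tol KKT residual tolerance.
#' @param max_iter maximum full coordinate sweeps.
#' @param alpha0 optional warm start.
#' @return `hsic_selection`: `alpha` (named, >= 0), `active_set` (ids sorted
#'   by descending alpha; ties by larger `c` then column order), `penalty`,
#'   `converged`, `kkt_residual`.
#' @export
solve_nonneg_lasso <- function(problem, penalty, tol = 1e-8, max_iter = 1e4,
                               alpha0 = NULL) {
  stopifnot(inherits(problem, "hsic_problem"), penalty >= 0)
  Q <- problem$Q
  cc <- problem$c
  p <- length(cc)
  alpha <- if (is.null(alpha0)) numeric(p) else as.numeric(alpha0)
  stopifnot(length(alpha) == p, all(alpha >= 0))
  qa <- drop(Q %*% alpha)
  dq <- diag(Q)
  if (any(dq <= 0)) stop("solve_nonneg_lasso: non-positive diagonal in Q (degenerate feature)")

  kkt <- function() {
    g <- qa - cc + penalty
    max(c(abs(g[alpha > 0]), pmax(0, -g[alpha == 0]), 0))
  }

  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (k in seq_len(p)) {
      new_k <- max(0, (cc[k] - (qa[k] - dq[k] * alpha[k]) - penalty) / dq[k])
      d <- new_k - alpha[k]
      if (d != 0) {
        qa <- qa + Q[, k] * d
        alpha[k] <- new_k
      }
    }
    if (kkt() <= tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("solve_nonneg_lasso: not converged in ", max_iter, " sweeps (KKT residual ",
            format(kkt(), digits = 3), ")")

  # round-off dust (e.g. the loser of a duplicated-feature pair) is not a
  # selection: clear coordinates below tol relative to the largest weight
  if (any(alpha > 0)) alpha[alpha < tol * max(alpha)] <- 0

  active <- which(alpha > 0)
  ord <- active[order(-alpha[active], -cc[active], active)]
  structure(list(alpha = stats::setNames(alpha, problem$feature_ids),
                 active_set = problem$feature_ids[ord],
                 penalty = penalty, requested_k = NA_integer_,
                 converged = converged, kkt_residual = kkt()),
            class = "hsic_selection")
}

#' @export
print.hsic_selection <- function(x, ...) {
  cat(sprintf("<hsic_selection> %d active features at lambda = %.4g (converged: %s)\n",
              length(x$active_set), x$penalty, x$converged))
  if (length(x$active_set))
    cat("  ", paste(utils::head(x$active_set, 10), collapse = ", "),
        if (length(x$active_set) > 10) "..." else "", "\n")
  invisible(x)
}

#' Select a requested number of features along the penalty path
#'
#' Bisects on \eqn{\lambda \in (0, \max_k c_k]} (with warm starts) until the
#' active set has exactly `k` members, or returns the largest active set of
#' size at most `k` if `k` is skipped on the path. Deterministic.
#'
#' @param problem an `hsic_problem`.
#' @param k requested number of features, `1 <= k <= p`.
#' @param tol,max_iter passed to [solve_nonneg_lasso()].
#' @param max_bisect bisection steps.
#' @return `hsic_selection` with `requested_k = k`.
#' @export
path_select_k <- function(problem, k, tol = 1e-8, max_iter = 1e4, max_bisect = 60) {
  p <- length(problem$c)
  stopifnot(k >= 1, k <= p)
  lam_hi <- max(problem$c)
  if (lam_hi <= 0) stop("path_select_k: no feature has positive dependency on the outcome")
  lam_lo <- lam_hi * 1e-8
  best <- NULL

  consider <- function(sol) {
    na <- length(sol$active_set)
    if (na <= k && (is.null(best) || na > length(best$active_set))) best <<- sol
  }

  sol <- solve_nonneg_lasso(problem, lam_lo, tol, max_iter)
  if (length(sol$active_set) <= k) {
    # even the near-unpenalized solution has <= k active features
    sol$requested_k <- k
    if (length(sol$active_set) < k)
      warning("path_select_k: only ", length(sol$active_set),
              " features reachable (requested ", k, ")")
    return(sol)
  }
  warm <- sol$alpha
  for (i in seq_len(max_bisect)) {
    lam <- sqrt(lam_lo * lam_hi)
    sol <- solve_nonneg_lasso(problem, lam, tol, max_iter, alpha0 = warm)
    na <- length(sol$active_set)
    consider(sol)
    if (na == k) break
    if (na > k) lam_lo <- lam else lam_hi <- lam
    warm <- sol$alpha
  }
  if (is.null(best)) {
    warning("path_select_k: requested size ", k, " not reachable; returning nearest")
    best <- solve_nonneg_lasso(problem, lam_hi, tol, max_iter)
  } else if (length(best$active_set) < k) {
    warning("path_select_k: size ", k, " skipped on the path; returning ",
            length(best$active_set), " features")
  }
  best$requested_k <- k
  best
}

#' Serialize a selection result to JSON
#'
#' @param sel an `hsic_selection`.
#' @param path optional file; if `NULL`, returns the JSON string.
#' @export
write_selection_json <- function(sel, path = NULL) {
  stopifnot(inherits(sel, "hsic_selection"))
  x <- list(feature_ids = names(sel$alpha), alpha = unname(sel$alpha),
            active_set = sel$active_set, penalty = sel$penalty,
            requested_k = sel$requested_k, converged = sel$converged)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
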
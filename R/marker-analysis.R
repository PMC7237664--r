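#' Post-hoc marker characterization
#'
#' After the nested cross-validation, feature-selecting models yield one
#' selected feature set per outer fold. Metabolites selected in at least 4
#' of 5 folds by *both* a quantitative-outcome model and a binary-outcome
#' model are reported as consistent markers; each is characterized by a
#' covariate-adjusted regression (coefficient per metabolite SD and
#' two-sided p), and dependencies among the outcome, covariates and chosen
#' metabolites are summarized in a pairwise HSIC table.
#'
#' @name marker_analysis
#' @keywords internal
NULL

#' Per-feature selection frequency across outer folds
#'
#' @param per_fold_selections list of feature-id character vectors, one per
#'   outer fold (normally 5).
#' @param universe optional feature universe; defaults to the union.
#' @return data.frame `feature`, `count`, `label` (formatted `"n/5"`),
#'   sorted by decreasing count.
#' @export
selection_frequency <- function(per_fold_selections, universe = NULL) {
  stopifnot(is.list(per_fold_selections), length(per_fold_selections) >= 1)
  k <- length(per_fold_selections)
  if (is.null(universe)) universe <- sort(unique(unlist(per_fold_selections)))
  counts <- vapply(universe, function(f)
    sum(vapply(per_fold_selections, function(s) f %in% s, logical(1))), numeric(1))
  out <- data.frame(feature = universe, count = as.integer(counts),
                    label = sprintf("%d/%d", counts, k),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$feature), , drop = FALSE]
}

#' Markers consistently selected in both outcome branches
#'
#' Features whose selection count reaches `threshold` in both the
#' quantitative-outcome and the binary-outcome frequency tables. The default
#' threshold of 4 of 5 folds matches the convention of flagging features
#' selected in at least four replications.
#'
#' @param freq_quant,freq_binary [selection_frequency()] tables over the
#'   same feature universe.
#' @param threshold minimal count in each branch.
#' @return character vector of feature ids.
#' @export
consistent_markers <- function(freq_quant, freq_binary, threshold = 4) {
  cq <- stats::setNames(freq_quant$count, freq_quant$feature)
  cb <- stats::setNames(freq_binary$count, freq_binary$feature)
  feats <- union(names(cq), names(cb))
  get0n <- function(v, f) ifelse(f %in% names(v), v[f], 0L)
  feats[get0n(cq, feats) >= threshold & get0n(cb, feats) >= threshold]
}

#' Covariate-adjusted single-metabolite regression
#'
#' Linear (scores) or logistic (binary traits) regression of the outcome on
#' one standardized metabolite plus all covariates; returns the metabolite
#' coefficient (per metabolite SD) and its two-sided p. Collinear fits are
#' flagged with an `NA` coefficient.
#'
#' @param metabolite numeric vector.
#' @param covariates data.frame or matrix of covariates.
#' @param outcome outcome vector.
#' @param outcome_kind `"quantitative"` or `"binary"`.
#' @return list with `coefficient`, `p`, `ok`.
#' @export
adjusted_regression_stats <- function(metabolite, covariates, outcome,
                                      outcome_kind = c("quantitative", "binary")) {
  outcome_kind <- match.arg(outcome_kind)
  n <- length(outcome)
  covariates <- as.data.frame(covariates)
  stopifnot(length(metabolite) == n, nrow(covariates) == n,
            n > ncol(covariates) + 2)
  s <- stats::sd(metabolite)
  if (!is.finite(s) || s == 0)
    return(list(coefficient = NA_real_, p = NA_real_, ok = FALSE))
  df <- cbind(data.frame(.y = outcome, .m = (metabolite - mean(metabolite)) / s),
              covariates)
  fit <- if (outcome_kind == "quantitative") stats::lm(.y ~ ., data = df)
         else suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  cf <- stats::coef(summary(fit))
  if (!".m" %in% rownames(cf) || anyNA(stats::coef(fit)))
    return(list(coefficient = NA_real_, p = NA_real_, ok = FALSE))
  list(coefficient = unname(cf[".m", 1]), p = unname(cf[".m", 4]), ok = TRUE)
}

#' Pairwise HSIC dependency table
#'
#' Empirical HSIC between every pair of the supplied variables with
#' kind-appropriate kernels (Gaussian on standardized values for continuous
#' variables, class-normalized delta for categorical ones), scaled by
#' `scale` for readability (default 1e3). The diagonal is `NA`. When
#' `covariate_names` are given, a `covariate_sum` component holds, for each
#' non-covariate variable, the sum of its HSIC over the covariates.
#'
#' @param variables named list of equal-length vectors.
#' @param kinds named character vector of `"continuous"`/`"categorical"`.
#' @param covariate_names subset of `names(variables)`.
#' @param scale multiplicative reporting constant.
#' @param bandwidth Gaussian kernel bandwidth.
#' @return object of class `dependency_table`: `values` (symmetric matrix),
#'   `covariate_sum`, `scale`.
#' @export
pairwise_hsic_table <- function(variables, kinds, covariate_names = character(0),
                                scale = 1e3, bandwidth = 1) {
  stopifnot(is.list(variables), length(variables) >= 2,
            !is.null(names(variables)), all(names(variables) %in% names(kinds)))
  vn <- names(variables)
  q <- length(vn)
  M <- matrix(NA_real_, q, q, dimnames = list(vn, vn))
  for (i in seq_len(q - 1)) {
    for (j in seq(i + 1, q)) {
      h <- scale * hsic_statistic(variables[[i]], variables[[j]],
                                  kinds[[vn[i]]], kinds[[vn[j]]],
                                  bandwidth = bandwidth)
      M[i, j] <- h
      M[j, i] <- h
    }
  }
  cov_sum <- NULL
  if (length(covariate_names)) {
    others <- setdiff(vn, covariate_names)
    cov_sum <- vapply(others, function(v)
      sum(M[v, covariate_names]), numeric(1))
  }
  structure(list(values = M, covariate_sum = cov_sum, scale = scale),
            class = "dependency_table")
}

#' @export
print.dependency_table <- function(x, ...) {
  cat(sprintf("<dependency_table> %d variables, HSIC x %g\n", nrow(x$values), x$scale))
  print(round(x$values, 2))
  if (!is.null(x$covariate_sum)) {
    cat("covariate sums:\n")
    print(round(x$covariate_sum, 2))
  }
  invisible(x)
}

#' Marker summary table across models
#'
#' Assembles the marker report: per-feature selection frequencies for each
#' supplied model (quantitative and binary branches), the consistency flag,
#' and the covariate-adjusted regression coefficient and p-value for each
#' consistent metabolite in both branches.
#'
#' @param results_quant,results_binary named lists of `cv_result`s from
#'   feature-selecting models (same outer folds).
#' @param cohort the `cohort` the results were computed on.
#' @param cutoff cutoff used for the binary branch.
#' @param threshold consistency threshold per branch (default 4).
#' @return list with `frequencies` (data.frame feature x model counts),
#'   `consistent` (per consistent metabolite: frequencies, adjusted
#'   coefficient and p for both branches).
#' @export
marker_report <- function(results_quant, results_binary, cohort,
                          cutoff = 16, threshold = 4) {
  stopifnot(length(results_quant) >= 1, length(results_binary) >= 1)
  freq_of <- function(res) selection_frequency(res$selected)
  fq <- lapply(results_quant, freq_of)
  fb <- lapply(results_binary, freq_of)
  cons <- consistent_markers(fq[[1]], fb[[1]], threshold = threshold)
  cons <- setdiff(cons, cohort$covariate_names)

  universe <- sort(unique(c(unlist(lapply(fq, `[[`, "feature")),
                            unlist(lapply(fb, `[[`, "feature")))))
  tab <- data.frame(feature = universe, stringsAsFactors = FALSE)
  for (nm in names(fq))
    tab[[paste0(nm, "_quant")]] <- fq[[nm]]$label[match(universe, fq[[nm]]$feature)]
  for (nm in names(fb))
    tab[[paste0(nm, "_binary")]] <- fb[[nm]]$label[match(universe, fb[[nm]]$feature)]

  cov_df <- as.data.frame(cohort$features[, cohort$covariate_names, drop = FALSE])
  ybin <- binarize_outcome(cohort$outcome, cutoff)
  cons_stats <- lapply(cons, function(m) {
    rq <- adjusted_regression_stats(cohort$features[, m], cov_df,
                                    cohort$outcome, "quantitative")
    rb <- adjusted_regression_stats(cohort$features[, m], cov_df, ybin, "binary")
    data.frame(feature = m,
               coef_quant = rq$coefficient, p_quant = rq$p,
               coef_binary = rb$coefficient, p_binary = rb$p,
               stringsAsFactors = FALSE)
  })
  list(frequencies = tab,
       consistent = if (length(cons_stats)) do.call(rbind, cons_stats)
                    else data.frame())
}
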
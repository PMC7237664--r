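#' Cohort-comparison statistics
#'
#' Group comparisons between the high and low depressive-symptom groups:
#' pooled-variance two-sample Student's t tests for continuous variables
#' and exact two-sided Fisher tests for categorical ones. The Fisher tests
#' are computed by full hypergeometric enumeration over all tables with the
#' observed margins (r x 2, r <= 6); the two-sided p-value follows the
#' probability-mass rule, summing the point probabilities of every table no
#' more probable than the observed one (relative tolerance 1e-7 on the
#' comparison, the dominant statistical-software convention).
#'
#' @name cohort_stats
#' @keywords internal
NULL

#' Pooled-variance two-sample Student's t test
#'
#' Accepts either raw vectors (`x`, `y`) or group summaries
#' (`mean`, `sd`, `n` pairs). Two-sided p with `df = n1 + n2 - 2`.
#'
#' @param x,y raw group vectors (alternative interface).
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return list with `t`, `df`, `p`.
#' @export
student_t_pooled <- function(x = NULL, y = NULL,
                             mean1 = NULL, sd1 = NULL, n1 = NULL,
                             mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x)) {
    stopifnot(!is.null(y), length(x) >= 2, length(y) >= 2)
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 <= 0) stop("student_t_pooled: zero pooled variance")
  tt <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Exact two-sided Fisher test for a 2 x 2 table
#'
#' Hypergeometric enumeration in log space (log-factorials); the two-sided
#' p sums point probabilities `<= (1 + 1e-7) *` the observed table's. A
#' table with an empty margin admits a single configuration and returns
#' p = 1 (with a message).
#'
#' @param table 2 x 2 nonnegative integer matrix.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0), all(tab == round(tab)))
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); N <- sum(tab)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) {
    message("fisher_exact_2x2: empty margin, p = 1 by convention")
    return(1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(N, c1)
  lp_obs <- lchoose(r1, tab[1, 1]) + lchoose(r2, tab[2, 1]) - lchoose(N, c1)
  min(1, sum(exp(logp[logp <= lp_obs + log1p(1e-7)])))
}

#' Exact two-sided Fisher test for an r x 2 table
#'
#' Full enumeration of all tables with the observed margins (nested loops
#' over the r - 1 free cells of the first column with feasibility pruning,
#' implemented in C++). The enumerator asserts that the point probabilities
#' sum to 1 over the support (within 1e-9). Tables beyond the enumeration
#' budget raise an error suggesting [fisher_rx2_mc()].
#'
#' @param table r x 2 nonnegative integer matrix, `2 <= r <= 6`.
#' @param budget cap on enumerated tables (default 1e9).
#' @return two-sided p-value, with attributes `tables` (support size) and
#'   `p_obs` (observed table probability).
#' @export
fisher_exact_rx2 <- function(table, budget = 1e9) {
  tab <- as.matrix(table)
  stopifnot(ncol(tab) == 2, nrow(tab) >= 2, nrow(tab) <= 6,
            all(tab >= 0), all(tab == round(tab)))
  res <- fisher_rx2_cpp(matrix(as.integer(tab), nrow(tab), 2), 1e-7, budget)
  if (abs(res$total_mass - 1) > 1e-9)
    stop("fisher_exact_rx2: enumerated probabilities sum to ",
         format(res$total_mass, digits = 12), ", not 1")
  structure(res$p, tables = res$tables, p_obs = exp(res$log_p_obs))
}

#' Monte-Carlo two-sided Fisher test for an r x 2 table
#'
#' Seeded fallback for tables whose support exceeds the enumeration budget:
#' samples tables with the observed margins via [stats::r2dtable()] and
#' estimates the probability-mass two-sided p, with a 95% CI.
#'
#' @param table r x 2 nonnegative integer matrix.
#' @param n_sim number of sampled tables.
#' @param seed RNG seed.
#' @return list with `p` (the (1 + hits)/(1 + n) estimate), `ci` (95%
#'   Clopper-Pearson interval), `n_sim`.
#' @export
fisher_rx2_mc <- function(table, n_sim = 1e5, seed = 1L) {
  tab <- as.matrix(table)
  stopifnot(ncol(tab) == 2, all(tab >= 0), all(tab == round(tab)))
  set.seed(as.integer(seed))
  rs <- rowSums(tab); cs <- colSums(tab)
  lp <- function(m) sum(lchoose(rs, m[, 1])) - lchoose(sum(rs), cs[1])
  lp_obs <- lp(tab)
  thr <- lp_obs + log1p(1e-7)
  sims <- stats::r2dtable(n_sim, rs, cs)
  hits <- sum(vapply(sims, function(m) lp(m) <= thr, logical(1)))
  ci <- stats::binom.test(hits, n_sim)$conf.int
  list(p = (1 + hits) / (1 + n_sim), ci = as.numeric(ci), n_sim = n_sim)
}

#' Group-comparison report for a cohort
#'
#' Splits the cohort at `cutoff` into high/low outcome groups and compares
#' every covariate across groups: mean (SD) and a pooled t test for
#' continuous covariates; per-level counts (percentages) and an exact
#' Fisher test for categorical ones. Percentages are recomputed from the
#' counts.
#'
#' @param cohort a `cohort`.
#' @param cutoff binarization cutoff (default 16).
#' @return data.frame with one row per covariate (continuous) or per
#'   covariate level (categorical), columns `variable`, `level`,
#'   `high`, `low` (formatted), `p` (on the variable's first row), plus
#'   group sizes as attributes `n_high`/`n_low`.
#' @export
build_cohort_report <- function(cohort, cutoff = 16) {
  stopifnot(inherits(cohort, "cohort"))
  grp <- binarize_outcome(cohort$outcome, cutoff)
  hi <- grp == 1L
  rows <- list()
  add <- function(variable, level, high, low, p)
    rows[[length(rows) + 1]] <<- data.frame(variable = variable, level = level,
                                            high = high, low = low, p = p,
                                            stringsAsFactors = FALSE)
  add("outcome score", "mean (SD)",
      sprintf("%.1f (%.1f)", mean(cohort$outcome[hi]), stats::sd(cohort$outcome[hi])),
      sprintf("%.1f (%.1f)", mean(cohort$outcome[!hi]), stats::sd(cohort$outcome[!hi])),
      student_t_pooled(cohort$outcome[hi], cohort$outcome[!hi])$p)
  for (v in cohort$covariate_names) {
    x <- cohort$features[, v]
    if (cohort$feature_kinds[[v]] == "continuous") {
      add(v, "mean (SD)",
          sprintf("%.2f (%.2f)", mean(x[hi]), stats::sd(x[hi])),
          sprintf("%.2f (%.2f)", mean(x[!hi]), stats::sd(x[!hi])),
          student_t_pooled(x[hi], x[!hi])$p)
    } else {
      lev <- sort(unique(x))
      tab <- cbind(high = vapply(lev, function(l) sum(x[hi] == l), numeric(1)),
                   low = vapply(lev, function(l) sum(x[!hi] == l), numeric(1)))
      p <- if (nrow(tab) >= 2) as.numeric(fisher_exact_rx2(tab)) else NA_real_
      for (i in seq_along(lev))
        add(v, as.character(lev[i]),
            sprintf("%d (%.2f%%)", tab[i, 1], 100 * tab[i, 1] / sum(hi)),
            sprintf("%d (%.2f%%)", tab[i, 2], 100 * tab[i, 2] / sum(!hi)),
            if (i == 1) p else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_high") <- sum(hi)
  attr(out, "n_low") <- sum(!hi)
  out
}
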
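#' Three-level nested five-fold cross-validation
#'
#' Every prediction model is evaluated on one shared partition of subjects:
#' an outer 5-fold split estimates generalization; within each outer
#' training set a first inner 5-fold split tunes feature-selection
#' parameters; within each first-inner training set a second inner 5-fold
#' split tunes predictor parameters (when the model has both stages;
#' single-stage models tune everything in the first inner loop). The grid
#' point maximizing the mean inner predictive power is retained. Predictive
#' power is the Pearson correlation between predicted and observed scores
#' (PCC) for quantitative outcomes and the area under the ROC curve (AUC)
#' for binary traits.
#'
#' @name nested_cv
#' @keywords internal
NULL

split_sizes <- function(n, k) {
  base <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1
  base
}

# partition idx into k groups with sizes differing by <= 1, optionally
# stratified (per-class counts per fold also differ by <= 1); consumes the
# current RNG stream
partition_idx <- function(idx, k, labels = NULL) {
  n <- length(idx)
  if (is.null(labels)) {
    sh <- sample(idx)
    unname(split(sh, rep(seq_len(k), times = split_sizes(n, k))))
  } else {
    stopifnot(length(labels) == n)
    folds <- vector("list", k)
    ptr <- 0L
    for (cl in levels(as.factor(labels))) {
      members <- sample(idx[labels == cl])
      for (m in members) {
        f <- (ptr %% k) + 1L
        folds[[f]] <- c(folds[[f]], m)
        ptr <- ptr + 1L
      }
    }
    folds
  }
}

#' Build the shared outer/inner/inner2 fold plan
#'
#' Deterministic given `seed`. Outer folds partition all `n` subjects into
#' 5 groups with sizes differing by at most 1 (897 subjects give sizes
#' 180, 180, 179, 179, 179); each outer training set is partitioned into 5
#' first-inner folds, and each first-inner training set into 5 second-inner
#' folds. With `stratify_labels` every split keeps per-class counts within
#' one subject per fold (used for binary traits so no training fold loses a
#' class).
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param stratify_labels optional length-`n` class labels.
#' @param n_folds folds per level (default 5).
#' @return object of class `fold_plan` with elements `outer` (list of index
#'   groups), `inner[[f]]$first` (list of groups partitioning the f-th outer
#'   training set) and `inner[[f]]$second[[j]]` (groups partitioning the
#'   (f,j)-th first-inner training set), plus `n`, `seed`, `n_folds`.
#' @export
make_fold_plan <- function(n, seed, stratify_labels = NULL, n_folds = 5) {
  if (n < n_folds^2) stop("make_fold_plan: n too small for nested ", n_folds, "-fold splits")
  if (!is.null(stratify_labels)) stopifnot(length(stratify_labels) == n)
  set.seed(as.integer(seed))
  lab <- function(idx) if (is.null(stratify_labels)) NULL else stratify_labels[idx]
  all_idx <- seq_len(n)
  outer <- partition_idx(all_idx, n_folds, lab(all_idx))
  inner <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- sort(setdiff(all_idx, outer[[f]]))
    first <- partition_idx(tr, n_folds, lab(tr))
    second <- vector("list", n_folds)
    for (j in seq_len(n_folds)) {
      itr <- sort(setdiff(tr, first[[j]]))
      second[[j]] <- partition_idx(itr, n_folds, lab(itr))
    }
    inner[[f]] <- list(first = first, second = second)
  }
  structure(list(n = n, seed = as.integer(seed), n_folds = n_folds,
                 outer = outer, inner = inner),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> n = %d, %d-fold x 3 levels, seed = %d (outer sizes: %s)\n",
              x$n, x$n_folds, x$seed,
              paste(lengths(x$outer), collapse = ", ")))
  invisible(x)
}

#' Pearson correlation between predictions and observations (PCC)
#'
#' @param predicted,observed numeric vectors of equal length >= 2.
#' @return correlation in `[-1, 1]`, or `NA` with a warning when either
#'   vector is constant (undefined metric; the fold is flagged, not zeroed).
#' @export
pcc <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 2)
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("pcc: constant vector, metric undefined for this fold")
    return(NA_real_)
  }
  stats::cor(predicted, observed)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `(concordant pairs + 0.5 * tied pairs) / (n1 * n0)`, computed via
#' midranks; invariant under strictly increasing transforms of the scores.
#'
#' @param scores real-valued decision scores.
#' @param labels 0/1 labels (1 = positive class).
#' @return AUC in `[0, 1]`, or `NA` with a warning if a class is absent.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    warning("auc: one class absent, metric undefined for this fold")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Covariate-adjusted p < threshold metabolite screen
#'
#' For each metabolite, fits one covariate-adjusted regression (linear for
#' scores, logistic for binary traits) of the outcome on that metabolite
#' plus all covariates, and retains metabolites whose coefficient has a
#' two-sided p below `threshold`. Covariates are always retained. With
#' `adjusted = FALSE` the per-metabolite models omit the covariates.
#'
#' @param X subjects x features matrix (named columns).
#' @param metabolite_names,covariate_names column subsets.
#' @param y outcome.
#' @param outcome_kind `"quantitative"` or `"binary"`.
#' @param threshold retention p-value threshold.
#' @param adjusted adjust for covariates?
#' @return character vector: covariates then retained metabolites.
#' @export
pvalue_screen <- function(X, metabolite_names, covariate_names, y,
                          outcome_kind = c("quantitative", "binary"),
                          threshold = 0.05, adjusted = TRUE) {
  outcome_kind <- match.arg(outcome_kind)
  X <- as.matrix(X)
  stopifnot(nrow(X) > length(covariate_names) + 2)
  keep <- character(0)
  Cv <- if (adjusted && length(covariate_names))
    X[, covariate_names, drop = FALSE] else NULL
  for (m in metabolite_names) {
    df <- data.frame(y = y, m = X[, m])
    if (!is.null(Cv)) df <- cbind(df, as.data.frame(Cv))
    p <- tryCatch({
      if (outcome_kind == "quantitative") {
        fit <- stats::lm(y ~ ., data = df)
        stats::summary.lm(fit)$coefficients["m", 4]
      } else {
        fit <- withCallingHandlers(
          stats::glm(y ~ ., data = df, family = stats::binomial()),
          warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
              stop("separation") else invokeRestart("muffleWarning")
          })
        stats::coef(summary(fit))["m", 4]
      }
    }, error = function(e) {
      warning("pvalue_screen: skipping ", m, " (", conditionMessage(e), ")")
      NA_real_
    })
    if (!is.na(p) && p < threshold) keep <- c(keep, m)
  }
  c(covariate_names, keep)
}

#' Describe a prediction model for the harness
#'
#' @param name display name.
#' @param selector one of `"none"`, `"hsic_lasso"`, `"lasso"`,
#'   `"pvalue_screen"`, `"covariates_only"`.
#' @param predictor one of `"kernel_ridge"`, `"svm_rbf"`, `"lasso_linear"`,
#'   `"pls"`, `"spls"`, `"random_forest"`, `"linear_regression"`,
#'   `"logistic_regression"`.
#' @param selector_grid,predictor_grid named lists of parameter vectors;
#'   grids with more than one combination are tuned in the inner loops
#'   (selector stage in the first inner loop, predictor stage in the second
#'   inner loop when both stages have grids).
#' @return a `model_spec`.
#' @export
model_spec <- function(name, selector = "none", predictor,
                       selector_grid = list(), predictor_grid = list()) {
  selector <- match.arg(selector, c("none", "hsic_lasso", "lasso",
                                    "pvalue_screen", "covariates_only"))
  predictor <- match.arg(predictor, c("kernel_ridge", "svm_rbf", "lasso_linear",
                                      "pls", "spls", "random_forest",
                                      "linear_regression", "logistic_regression"))
  grid_df <- function(g) {
    if (length(g) == 0) return(data.frame(row.names = 1))
    expand.grid(g, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  structure(list(name = name, selector = selector, predictor = predictor,
                 selector_grid = grid_df(selector_grid),
                 predictor_grid = grid_df(predictor_grid)),
            class = "model_spec")
}

metric_fn <- function(outcome_kind) {
  if (outcome_kind == "quantitative") pcc else auc
}

## ---- selector / predictor backends -------------------------------------

run_selector <- function(spec, X, y, idx, kinds, metabolite_names,
                         covariate_names, param, cache) {
  key <- paste0(spec$selector, "|", paste(idx, collapse = ","))
  all_feats <- colnames(X)
  switch(spec$selector,
    none = all_feats,
    covariates_only = covariate_names,
    hsic_lasso = {
      prob <- cache[[key]]
      if (is.null(prob)) {
        prob <- suppressWarnings(build_hsic_problem(
          X[idx, , drop = FALSE], kinds, y[idx],
          outcome_kind = if (isTRUE(param$..outcome_binary)) "binary" else "quantitative"))
        cache[[key]] <- prob
      }
      sel <- suppressWarnings(path_select_k(prob, k = param$k))
      sel$active_set
    },
    lasso = {
      fam <- if (isTRUE(param$..outcome_binary)) "binomial" else "gaussian"
      fit <- glmnet::glmnet(X[idx, , drop = FALSE], y[idx], family = fam,
                            lambda = param$lambda, standardize = TRUE)
      cf <- as.matrix(stats::coef(fit))[-1, 1]
      feats <- names(cf)[cf != 0]
      if (length(feats) == 0) covariate_names else feats
    },
    pvalue_screen = suppressWarnings(pvalue_screen(
      X[idx, , drop = FALSE], metabolite_names, covariate_names, y[idx],
      outcome_kind = if (isTRUE(param$..outcome_binary)) "binary" else "quantitative",
      threshold = if (!is.null(param$threshold)) param$threshold else 0.05))
  )
}

pls_nipals <- function(X, y, ncomp, eta = 0) {
  st <- standardize_train(X)
  Xc <- st$X
  yc <- y - mean(y)
  p <- ncol(Xc)
  ncomp <- min(ncomp, p, nrow(Xc) - 1)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  qv <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    if (eta > 0) {
      thr <- eta * max(abs(w))
      w <- sign(w) * pmax(abs(w) - thr, 0)
      if (all(w == 0)) w[which.max(abs(drop(crossprod(Xc, yc))))] <- 1
    }
    nw <- sqrt(sum(w^2))
    if (nw == 0) { ncomp <- h - 1L; break }
    w <- w / nw
    tt <- drop(Xc %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) { ncomp <- h - 1L; break }
    pl <- drop(crossprod(Xc, tt)) / tt2
    qh <- sum(yc * tt) / tt2
    Xc <- Xc - tcrossprod(tt, pl)
    yc <- yc - qh * tt
    W[, h] <- w; P[, h] <- pl; qv[h] <- qh
  }
  if (ncomp == 0) return(list(coef = numeric(p), intercept = mean(y), st = st,
                              active = character(0)))
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  qv <- qv[seq_len(ncomp)]
  B <- W %*% solve(crossprod(P, W), qv)
  active <- colnames(X)[rowSums(abs(W)) > 0]
  list(coef = drop(B), intercept = mean(y), st = st, active = active)
}

fit_predict_model <- function(spec, X, y, tr, te, feats, param, outcome_kind,
                              fit_seed) {
  Xtr <- X[tr, feats, drop = FALSE]
  Xte <- X[te, feats, drop = FALSE]
  ytr <- y[tr]
  binary <- outcome_kind == "binary"
  switch(spec$predictor,
    kernel_ridge = {
      base <- median_heuristic(standardize_train(Xtr)$X)
      fit <- fit_kernel_ridge(Xtr, ytr, sigma = param$sigma_mult * base,
                              lambda = param$lambda)
      predict(fit, Xte)
    },
    svm_rbf = {
      base <- median_heuristic(standardize_train(Xtr)$X)
      fit <- fit_svm_rbf(Xtr, ytr, sigma = param$sigma_mult * base, C = param$C)
      decision_function(fit, Xte)
    },
    lasso_linear = {
      fam <- if (binary) "binomial" else "gaussian"
      fit <- glmnet::glmnet(Xtr, ytr, family = fam, lambda = param$lambda,
                            standardize = TRUE)
      drop(stats::predict(fit, Xte, type = "link"))
    },
    pls = {
      fit <- pls_nipals(Xtr, as.numeric(ytr), ncomp = param$ncomp)
      drop(standardize_apply(Xte, fit$st) %*% fit$coef) + fit$intercept
    },
    spls = {
      fit <- pls_nipals(Xtr, as.numeric(ytr), ncomp = param$ncomp, eta = param$eta)
      drop(standardize_apply(Xte, fit$st) %*% fit$coef) + fit$intercept
    },
    random_forest = {
      set.seed(fit_seed)
      yy <- if (binary) as.factor(ytr) else as.numeric(ytr)
      mtry_grid <- unique(pmax(1, pmin(ncol(Xtr), c(
        floor(sqrt(ncol(Xtr))), floor(ncol(Xtr) / 3), floor(ncol(Xtr) / 10)))))
      oob <- vapply(mtry_grid, function(m) {
        f <- randomForest::randomForest(Xtr, yy, ntree = 200, mtry = m)
        if (binary) f$err.rate[200, "OOB"] else f$mse[200]
      }, numeric(1))
      fit <- randomForest::randomForest(Xtr, yy, ntree = 500,
                                        mtry = mtry_grid[which.min(oob)])
      if (binary) stats::predict(fit, Xte, type = "prob")[, "1"]
      else drop(stats::predict(fit, Xte))
    },
    linear_regression = {
      df <- as.data.frame(Xtr); df$..y <- ytr
      fit <- stats::lm(..y ~ ., data = df)
      drop(stats::predict(fit, as.data.frame(Xte)))
    },
    logistic_regression = {
      df <- as.data.frame(Xtr); df$..y <- ytr
      fit <- suppressWarnings(stats::glm(..y ~ ., data = df, family = stats::binomial()))
      drop(stats::predict(fit, as.data.frame(Xte), type = "link"))
    }
  )
}

## ---- the harness --------------------------------------------------------

#' Run one model through the shared nested cross-validation
#'
#' For each outer fold: tune the selector grid in the first inner loop (with
#' predictor grids tuned in the second inner loop when both stages have more
#' than one grid point), re-select features on the full outer training set
#' with the winning selector parameter, tune the predictor grid in the first
#' inner loop, refit on the outer training set and score the held-out fold.
#' All feature selection, standardization and tuning see training indices
#' only; the indices touched before prediction are recorded and checked to
#' be disjoint from the test fold.
#'
#' @param X subjects x features matrix (named columns).
#' @param y outcome vector (scores, or 0/1 for binary).
#' @param spec a [model_spec()].
#' @param plan a [make_fold_plan()] for `nrow(X)` subjects.
#' @param outcome_kind `"quantitative"` or `"binary"`.
#' @param kinds per-column `"continuous"`/`"categorical"` tags.
#' @param metabolite_names,covariate_names feature classes (selection
#'   reports distinguish them; covariates compete in selection).
#' @param verbose print per-fold progress?
#' @return object of class `cv_result`: `model`, `metric`, `scores` (one per
#'   outer fold, `NA` when undefined), `selected` (features per fold),
#'   `hyperparams` (chosen grid points per fold), `audit_ok`.
#' @export
run_nested_cv <- function(X, y, spec, plan,
                          outcome_kind = c("quantitative", "binary"),
                          kinds = NULL,
                          metabolite_names = colnames(X),
                          covariate_names = character(0),
                          verbose = FALSE) {
  outcome_kind <- match.arg(outcome_kind)
  X <- as.matrix(X)
  stopifnot(inherits(spec, "model_spec"), inherits(plan, "fold_plan"),
            nrow(X) == plan$n, length(y) == nrow(X))
  if (is.null(kinds)) kinds <- rep("continuous", ncol(X))
  metric <- metric_fn(outcome_kind)
  k_folds <- plan$n_folds
  binary <- outcome_kind == "binary"

  sel_grid <- spec$selector_grid
  pred_grid <- spec$predictor_grid
  sel_grid$..outcome_binary <- binary
  cache <- new.env(parent = emptyenv())

  scores <- rep(NA_real_, k_folds)
  selected <- vector("list", k_folds)
  hyper <- vector("list", k_folds)
  audit_ok <- TRUE

  sel_row <- function(i) as.list(sel_grid[i, , drop = FALSE])
  pred_row <- function(i) if (nrow(pred_grid)) as.list(pred_grid[i, , drop = FALSE]) else list()

  safe_score <- function(expr) tryCatch(suppressWarnings(expr),
                                        error = function(e) NA_real_)

  # tune the predictor grid by CV over the given (train, test) index pairs,
  # with features re-derived per pair by feats_for()
  tune_predictor <- function(pairs, feats_for, fit_seed) {
    if (nrow(pred_grid) <= 1) return(1L)
    sc <- matrix(NA_real_, length(pairs), nrow(pred_grid))
    for (a in seq_along(pairs)) {
      tr <- pairs[[a]]$tr; te <- pairs[[a]]$te
      feats <- feats_for(tr)
      for (b in seq_len(nrow(pred_grid)))
        sc[a, b] <- safe_score(metric(
          fit_predict_model(spec, X, y, tr, te, feats, pred_row(b),
                            outcome_kind, fit_seed), y[te]))
    }
    means <- colMeans(sc, na.rm = TRUE)
    which.max(ifelse(is.nan(means), -Inf, means))
  }

  for (f in seq_len(k_folds)) {
    test <- plan$outer[[f]]
    train <- sort(setdiff(seq_len(plan$n), test))
    touched <- integer(0)
    note <- function(idx) touched <<- union(touched, idx)
    fit_seed <- plan$seed + 1000L * f
    first <- plan$inner[[f]]$first

    # ---- stage 1: selector grid (first inner loop) ----
    best_s <- 1L
    if (nrow(sel_grid) > 1) {
      sc <- matrix(NA_real_, k_folds, nrow(sel_grid))
      for (j in seq_len(k_folds)) {
        ite <- first[[j]]
        itr <- sort(setdiff(train, ite))
        note(itr)
        second <- plan$inner[[f]]$second[[j]]
        for (s in seq_len(nrow(sel_grid))) {
          feats <- tryCatch(
            run_selector(spec, X, y, itr, kinds, metabolite_names,
                         covariate_names, sel_row(s), cache),
            error = function(e) NULL)
          if (is.null(feats) || !length(feats)) next
          pairs2 <- lapply(second, function(g) list(tr = sort(setdiff(itr, g)), te = g))
          pb <- tune_predictor(pairs2, function(tr) feats, fit_seed)
          sc[j, s] <- safe_score(metric(
            fit_predict_model(spec, X, y, itr, ite, feats, pred_row(pb),
                              outcome_kind, fit_seed), y[ite]))
        }
      }
      means <- colMeans(sc, na.rm = TRUE)
      best_s <- which.max(ifelse(is.nan(means), -Inf, means))
    }

    # ---- stage 2: predictor grid (first inner loop, winning selector) ----
    pairs1 <- lapply(first, function(g) list(tr = sort(setdiff(train, g)), te = g))
    feats_for <- function(tr) {
      note(tr)
      run_selector(spec, X, y, tr, kinds, metabolite_names, covariate_names,
                   sel_row(best_s), cache)
    }
    best_p <- tune_predictor(pairs1, feats_for, fit_seed)

    # ---- final fit on the outer training set ----
    note(train)
    feats <- run_selector(spec, X, y, train, kinds, metabolite_names,
                          covariate_names, sel_row(best_s), cache)
    audit_ok <- audit_ok && length(intersect(touched, test)) == 0
    preds <- fit_predict_model(spec, X, y, train, test, feats, pred_row(best_p),
                               outcome_kind, fit_seed)
    scores[f] <- safe_score(metric(preds, y[test]))
    selected[[f]] <- feats
    hyper[[f]] <- list(selector = sel_row(best_s)[setdiff(names(sel_row(best_s)),
                                                          "..outcome_binary")],
                       predictor = pred_row(best_p))
    if (verbose)
      message(sprintf("[%s] outer fold %d: %s = %.3f (%d features)",
                      spec$name, f, if (binary) "AUC" else "PCC",
                      scores[f], length(feats)))
  }

  structure(list(model = spec$name, metric = if (binary) "auc" else "pcc",
                 scores = scores, selected = selected, hyperparams = hyper,
                 audit_ok = audit_ok, plan_seed = plan$seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean %s = %.3f (folds: %s)\n",
              x$model, toupper(x$metric), mean(x$scores, na.rm = TRUE),
              paste(sprintf("%.3f", x$scores), collapse = ", ")))
  invisible(x)
}

#' Default model registry mirroring the benchmarked lineup
#'
#' Returns the models compared by the pipeline: the HSIC Lasso + KR/SVM
#' model and the baselines (lasso, KR/SVM without selection, KR/SVM with
#' the p < 0.05 screen, lasso-selected KR/SVM, PLS, SPLS, random forest,
#' all-variable and covariates-only regressions). Grids follow the package
#' defaults: k in {5, 10, 15, 20, 30, 50}; sigma multipliers
#' {0.25, 0.5, 1, 2, 4} of the median heuristic; ridge lambda logarithmic in
#' [1e-4, 10]; SVM cost logarithmic in [1e-2, 1e3]; grids can be overridden
#' or subset for smaller studies.
#'
#' @param outcome_kind `"quantitative"` or `"binary"`.
#' @param k_grid,sigma_grid,lambda_grid,C_grid,lasso_lambda_grid,
#'   ncomp_grid,eta_grid grid overrides.
#' @return named list of `model_spec`s.
#' @export
default_model_registry <- function(outcome_kind = c("quantitative", "binary"),
                                   k_grid = c(5, 10, 15, 20, 30, 50),
                                   sigma_grid = c(0.25, 0.5, 1, 2, 4),
                                   lambda_grid = 10^seq(-4, 1, length.out = 6),
                                   C_grid = 10^seq(-2, 3, length.out = 6),
                                   lasso_lambda_grid = 10^seq(-3, 0.5, length.out = 10),
                                   ncomp_grid = 1:5,
                                   eta_grid = c(0.3, 0.6, 0.9)) {
  outcome_kind <- match.arg(outcome_kind)
  q <- outcome_kind == "quantitative"
  kernel_pred <- if (q) "kernel_ridge" else "svm_rbf"
  kernel_grid <- if (q) list(sigma_mult = sigma_grid, lambda = lambda_grid)
                 else list(sigma_mult = sigma_grid, C = C_grid)
  reg_pred <- if (q) "linear_regression" else "logistic_regression"
  nm <- if (q) "KR" else "SVM"
  list(
    hsic_kernel = model_spec(paste0("HSIC Lasso + ", nm), "hsic_lasso", kernel_pred,
                             selector_grid = list(k = k_grid),
                             predictor_grid = kernel_grid),
    lasso = model_spec("Lasso", "none", "lasso_linear",
                       predictor_grid = list(lambda = lasso_lambda_grid)),
    kernel_all = model_spec(paste0(nm, " all"), "none", kernel_pred,
                            predictor_grid = kernel_grid),
    kernel_pscreen = model_spec(paste0(nm, " P<0.05"), "pvalue_screen", kernel_pred,
                                predictor_grid = kernel_grid),
    lasso_kernel = model_spec(paste0("Lasso + ", nm), "lasso", kernel_pred,
                              selector_grid = list(lambda = lasso_lambda_grid),
                              predictor_grid = kernel_grid),
    pls = model_spec("PLS", "none", "pls",
                     predictor_grid = list(ncomp = ncomp_grid)),
    spls = model_spec("SPLS", "none", "spls",
                      predictor_grid = list(ncomp = ncomp_grid, eta = eta_grid)),
    random_forest = model_spec("Random forest", "none", "random_forest"),
    reg_pscreen = model_spec("MLR P<0.05", "pvalue_screen", reg_pred),
    reg_all = model_spec("MLR all", "none", reg_pred),
    kernel_covariates = model_spec(paste0(nm, " covariates"), "covariates_only",
                                   kernel_pred, predictor_grid = kernel_grid),
    reg_covariates = model_spec("MLR covariates", "covariates_only", reg_pred)
  )
}
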
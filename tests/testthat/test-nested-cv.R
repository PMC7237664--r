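test_that("fold plans partition subjects into near-equal nested groups", {
  plan <- make_fold_plan(897, seed = 41)
  expect_equal(sort(lengths(plan$outer), decreasing = TRUE),
               c(180, 180, 179, 179, 179))
  expect_equal(sort(unlist(plan$outer)), 1:897)
  for (f in 1:5) {
    tr <- setdiff(1:897, plan$outer[[f]])
    expect_equal(sort(unlist(plan$inner[[f]]$first)), sort(tr))
    expect_true(max(lengths(plan$inner[[f]]$first)) -
                min(lengths(plan$inner[[f]]$first)) <= 1)
    itr1 <- setdiff(tr, plan$inner[[f]]$first[[1]])
    expect_equal(sort(unlist(plan$inner[[f]]$second[[1]])), sort(itr1))
  }
  expect_identical(make_fold_plan(897, seed = 41), plan)
  expect_false(identical(make_fold_plan(897, seed = 42)$outer, plan$outer))
  expect_error(make_fold_plan(20, 1), "too small")
})

test_that("stratified fold plans balance classes within one subject", {
  set.seed(43)
  lab <- rbinom(103, 1, 0.3)
  plan <- make_fold_plan(103, seed = 43, stratify_labels = lab)
  pos <- vapply(plan$outer, function(g) sum(lab[g]), numeric(1))
  expect_lte(max(pos) - min(pos), 1)
  expect_lte(max(lengths(plan$outer)) - min(lengths(plan$outer)), 1)
  expect_equal(sort(unlist(plan$outer)), 1:103)
})

test_that("pcc and auc reproduce hand-computed values and bounds", {
  expect_equal(pcc(1:10, 1:10), 1)
  expect_equal(pcc(1:10, -(1:10)), -1)
  expect_equal(pcc(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_warning(expect_true(is.na(pcc(rep(1, 5), rnorm(5)))), "constant")

  expect_equal(auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(auc(c(0.9, 0.4, 0.8, 0.3), c(1, 1, 0, 0)), 0.75)
  expect_warning(expect_true(is.na(auc(rnorm(4), c(1, 1, 1, 1)))), "class absent")
  # invariance under strictly increasing transforms
  set.seed(45)
  s <- rnorm(40); l <- rbinom(40, 1, 0.5)
  expect_equal(auc(exp(s), l), auc(s, l))
  expect_equal(auc(rank(s), l), auc(s, l))
})

test_that("the p < 0.05 screen keeps signal, drops noise at the nominal rate", {
  set.seed(47)
  n <- 120
  cov_ <- cbind(cv1 = rnorm(n), cv2 = rbinom(n, 1, 0.5))
  y <- rnorm(n)
  X <- cbind(signal = y + rnorm(n, 0, 0.1), matrix(rnorm(n * 20), n, 20), cov_)
  colnames(X)[2:21] <- paste0("null", 1:20)
  kept <- pvalue_screen(X, c("signal", paste0("null", 1:20)), c("cv1", "cv2"),
                        y, "quantitative")
  expect_true("signal" %in% kept)
  expect_true(all(c("cv1", "cv2") %in% kept))

  # type-I calibration: ~5% of null features retained on average
  rates <- vapply(1:15, function(s) {
    set.seed(1000 + s)
    Xn <- matrix(rnorm(100 * 40), 100, 40)
    colnames(Xn) <- paste0("m", 1:40)
    yy <- rnorm(100)
    length(setdiff(pvalue_screen(Xn, colnames(Xn), character(0), yy,
                                 "quantitative"), character(0))) / 40
  }, numeric(1))
  # 600 null features in total: the binomial 95% band around 0.05 is ~ +/- 0.018
  expect_lt(abs(mean(rates) - 0.05), 0.02)

  # regression p-values agree with the standard least-squares fit
  m <- X[, "null3"]
  fit <- lm(y ~ m + cv1 + cv2, data = data.frame(y = y, m = m, cov_))
  p_ref <- summary(fit)$coefficients["m", 4]
  kept_lo <- pvalue_screen(X, "null3", c("cv1", "cv2"), y, "quantitative",
                           threshold = p_ref + 1e-9)
  kept_hi <- pvalue_screen(X, "null3", c("cv1", "cv2"), y, "quantitative",
                           threshold = p_ref - 1e-9)
  expect_true("null3" %in% kept_lo)
  expect_false("null3" %in% kept_hi)
})

test_that("with singleton grids nested CV reduces exactly to flat 5-fold CV", {
  set.seed(49)
  co <- generate_cohort(cohort_config(n_subjects = 100, n_metabolites = 10,
                                      n_redundant_blocks = 1, n_causal = 2, seed = 49))
  X <- co$features; y <- co$outcome
  plan <- make_fold_plan(100, seed = 50)
  sp <- model_spec("KR fixed", "none", "kernel_ridge",
                   predictor_grid = list(sigma_mult = 1, lambda = 0.1))
  res <- suppressWarnings(run_nested_cv(X, y, sp, plan, "quantitative",
                                        co$feature_kinds, co$metabolite_names,
                                        co$covariate_names))
  std <- function(M) {
    s <- apply(M, 2, sd); s[s == 0] <- 1
    sweep(sweep(M, 2, colMeans(M)), 2, s, "/")
  }
  flat <- vapply(1:5, function(f) {
    te <- plan$outer[[f]]; tr <- setdiff(1:100, te)
    base <- median_heuristic(std(X[tr, ]))
    fit <- fit_kernel_ridge(X[tr, ], y[tr], sigma = base, lambda = 0.1)
    pcc(predict(fit, X[te, ]), y[te])
  }, numeric(1))
  expect_equal(res$scores, flat, tolerance = 1e-12)
  expect_true(res$audit_ok)
})

test_that("held-out outcomes influence scores but never predictions", {
  set.seed(51)
  n <- 80
  X <- fixture_matrix(n, 6, seed = 51)
  y <- X[, 1] + rnorm(n, 0, 0.5)
  plan <- make_fold_plan(n, seed = 52)
  te <- plan$outer[[1]]; tr <- setdiff(1:n, te)
  base <- median_heuristic(X[tr, ])
  fit <- fit_kernel_ridge(X[tr, ], y[tr], sigma = base, lambda = 0.01)
  preds <- predict(fit, X[te, ])
  y2 <- y; y2[te] <- rev(y2[te]) + 100
  fit2 <- fit_kernel_ridge(X[tr, ], y2[tr], sigma = base, lambda = 0.01)
  expect_equal(predict(fit2, X[te, ]), preds)       # predictions untouched
  expect_false(isTRUE(all.equal(pcc(preds, y2[te]), pcc(preds, y[te]))))
})

test_that("the leakage audit passes for a tuned two-stage model", {
  co <- generate_cohort(cohort_config(n_subjects = 80, n_metabolites = 8,
                                      n_causal = 2, n_redundant_blocks = 1,
                                      seed = 53))
  sp <- model_spec("HSIC Lasso + KR", "hsic_lasso", "kernel_ridge",
                   selector_grid = list(k = c(2, 4)),
                   predictor_grid = list(sigma_mult = c(0.5, 1), lambda = 0.1))
  plan <- make_fold_plan(80, seed = 54)
  res <- suppressWarnings(run_nested_cv(co$features, co$outcome, sp, plan,
                                        "quantitative", co$feature_kinds,
                                        co$metabolite_names, co$covariate_names))
  expect_true(res$audit_ok)
  expect_length(res$scores, 5)
  expect_length(res$selected, 5)
  for (f in 1:5) expect_lte(length(res$selected[[f]]), 4)
})

test_that("the default registry mirrors the benchmarked model lineup", {
  reg <- default_model_registry("quantitative")
  expect_setequal(names(reg),
                  c("hsic_kernel", "lasso", "kernel_all", "kernel_pscreen",
                    "lasso_kernel", "pls", "spls", "random_forest",
                    "reg_pscreen", "reg_all", "kernel_covariates", "reg_covariates"))
  expect_equal(reg$hsic_kernel$selector, "hsic_lasso")
  expect_equal(reg$hsic_kernel$predictor, "kernel_ridge")
  expect_equal(reg$hsic_kernel$selector_grid$k, c(5, 10, 15, 20, 30, 50))
  regb <- default_model_registry("binary")
  expect_equal(regb$hsic_kernel$predictor, "svm_rbf")
  expect_equal(regb$reg_covariates$predictor, "logistic_regression")
})

test_that("baseline predictors run through the harness on a small cohort", {
  co <- generate_cohort(cohort_config(n_subjects = 75, n_metabolites = 6,
                                      n_redundant_blocks = 1, n_causal = 1,
                                      effect_functions = "linear", seed = 55))
  X <- co$features; y <- co$outcome
  plan <- make_fold_plan(75, seed = 56)
  specs <- list(
    model_spec("PLS", "none", "pls", predictor_grid = list(ncomp = 1:2)),
    model_spec("SPLS", "none", "spls",
               predictor_grid = list(ncomp = 1:2, eta = c(0.5, 0.9))),
    model_spec("MLR covariates", "covariates_only", "linear_regression"),
    model_spec("Random forest", "none", "random_forest"),
    model_spec("KR P<0.05", "pvalue_screen", "kernel_ridge",
               predictor_grid = list(sigma_mult = 1, lambda = 0.1)))
  for (sp in specs) {
    res <- suppressWarnings(run_nested_cv(X, y, sp, plan, "quantitative",
                                          co$feature_kinds, co$metabolite_names,
                                          co$covariate_names))
    expect_length(res$scores, 5)
    expect_true(all(is.na(res$scores) | (res$scores >= -1 & res$scores <= 1)),
                label = sp$name)
  }
})
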
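test_that("selection frequencies count fold membership", {
  sets <- list(c("a", "b"), c("a"), c("a", "b"), c("a", "c"), c("a", "b"))
  freq <- selection_frequency(sets)
  expect_equal(freq$count[freq$feature == "a"], 5L)
  expect_equal(freq$count[freq$feature == "b"], 3L)
  expect_equal(freq$label[freq$feature == "a"], "5/5")
  # double-counting identity on random fixtures
  set.seed(71)
  for (i in 1:10) {
    sets <- lapply(1:5, function(j) sample(letters, sample(3:8, 1)))
    freq <- selection_frequency(sets)
    expect_equal(sum(freq$count), sum(lengths(sets)))
  }
})

test_that("consistency requires the threshold in both outcome branches", {
  fq <- selection_frequency(list(c("a", "b"), c("a", "b"), c("a"), c("a", "b"), c("a", "b")))
  fb <- selection_frequency(list(c("a"), c("a", "b"), c("a"), c("a"), c("b")))
  # a: 5/5 and 4/5; b: 4/5 and 2/5
  expect_equal(consistent_markers(fq, fb, threshold = 4), "a")
  expect_equal(consistent_markers(fq, fb, threshold = 0), c("a", "b"))
  # weakly shrinking in the threshold
  sizes <- vapply(0:5, function(t) length(consistent_markers(fq, fb, t)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("adjusted regressions agree with the standard fitting machinery", {
  set.seed(73)
  n <- 40
  cov_ <- data.frame(c1 = rnorm(n), c2 = rbinom(n, 1, 0.4), c3 = rnorm(n))
  y <- 1 + 0.5 * cov_$c1 + rnorm(n)
  m <- y + rnorm(n, 0, 0.4)
  res <- adjusted_regression_stats(m, cov_, y, "quantitative")
  ms <- (m - mean(m)) / sd(m)
  ref <- summary(lm(y ~ ms + c1 + c2 + c3, data = cov_))$coefficients
  expect_equal(res$coefficient, ref["ms", 1], tolerance = 1e-10)
  expect_equal(res$p, ref["ms", 4], tolerance = 1e-10)
  expect_lt(res$p, 1e-6)

  yb <- as.integer(y > median(y))
  resb <- adjusted_regression_stats(m, cov_, yb, "binary")
  refb <- summary(glm(yb ~ ms + c1 + c2 + c3, data = cov_,
                      family = binomial()))$coefficients
  expect_equal(resb$coefficient, refb["ms", 1], tolerance = 1e-8)
  expect_equal(resb$p, refb["ms", 4], tolerance = 1e-8)

  # a metabolite orthogonal to the covariate-adjusted outcome residual
  # has coefficient 0
  r <- residuals(lm(y ~ ., data = cov_))
  Z <- cbind(1, as.matrix(cov_))
  cand <- rnorm(n)
  orth <- cand - Z %*% solve(crossprod(Z), crossprod(Z, cand))
  orth <- orth - r * sum(orth * r) / sum(r^2)
  res0 <- adjusted_regression_stats(drop(orth), cov_, y, "quantitative")
  expect_equal(res0$coefficient, 0, tolerance = 1e-10)

  # collinear metabolite flagged, not mis-estimated
  resc <- adjusted_regression_stats(cov_$c1, cov_, y, "quantitative")
  expect_false(resc$ok)
})

test_that("the pairwise dependency table is symmetric and self-consistent", {
  set.seed(75)
  n <- 60
  vars <- list(outcome = rnorm(n), sexv = rbinom(n, 1, 0.5),
               met1 = rnorm(n), met2 = rnorm(n))
  vars$met2 <- vars$outcome + rnorm(n, 0, 0.5)
  kinds <- c(outcome = "continuous", sexv = "categorical",
             met1 = "continuous", met2 = "continuous")
  dep <- pairwise_hsic_table(vars, kinds, covariate_names = "sexv")
  M <- dep$values
  expect_true(all(is.na(diag(M))))
  expect_equal(M[upper.tri(M)], t(M)[upper.tri(M)])
  expect_true(all(M[!is.na(M)] >= -1e-8))
  # entries recompute from hsic_statistic at the same scale
  expect_equal(M["outcome", "met2"],
               1e3 * hsic_statistic(vars$outcome, vars$met2))
  expect_equal(M["sexv", "met1"],
               1e3 * hsic_statistic(vars$sexv, vars$met1, "categorical", "continuous"))
  # covariate-sum row is the exact row sum over covariates
  expect_equal(dep$covariate_sum[["met1"]], M["met1", "sexv"])

  # duplicated variable: maximal normalized dependency between the copies
  vars2 <- list(a = vars$met1, b = vars$met1, c = rnorm(n))
  dep2 <- pairwise_hsic_table(vars2, c(a = "continuous", b = "continuous",
                                       c = "continuous"))
  expect_gt(dep2$values["a", "b"], dep2$values["a", "c"])
})

test_that("planted causal metabolites are selected more often than null ones", {
  counts_causal <- c(); counts_null <- c()
  for (s in 1:12) {
    co <- generate_cohort(cohort_config(n_subjects = 150, n_metabolites = 25,
                                        n_causal = 3, n_redundant_blocks = 2,
                                        seed = 500 + s))
    X <- co$features[, co$metabolite_names]
    plan <- make_fold_plan(150, seed = s)
    sets <- lapply(1:5, function(f) {
      tr <- setdiff(1:150, plan$outer[[f]])
      prob <- build_hsic_problem(X[tr, ], rep("continuous", 25), co$outcome[tr])
      path_select_k(prob, 5)$active_set
    })
    freq <- selection_frequency(sets, universe = co$metabolite_names)
    cnt <- setNames(freq$count, freq$feature)
    counts_causal <- c(counts_causal, cnt[co$causal_ids])
    counts_null <- c(counts_null, cnt[setdiff(co$metabolite_names, co$causal_ids)])
  }
  wt <- wilcox.test(counts_causal, counts_null, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("the marker report assembles frequencies and adjusted statistics", {
  co <- generate_cohort(cohort_config(n_subjects = 120, n_metabolites = 8,
                                      n_redundant_blocks = 1, n_causal = 1,
                                      effect_functions = "linear",
                                      effect_sizes = 6, seed = 77))
  mk_res <- function(sets) structure(list(selected = sets), class = "cv_result")
  cid <- co$causal_ids
  rq <- mk_res(replicate(5, c(cid, "met_002"), simplify = FALSE))
  rb <- mk_res(replicate(5, cid, simplify = FALSE))
  rep_ <- marker_report(list(hsic = rq), list(hsic = rb), co)
  expect_equal(rep_$consistent$feature, cid)
  expect_true(all(c("coef_quant", "p_quant", "coef_binary", "p_binary")
                  %in% colnames(rep_$consistent)))
  expect_lt(rep_$consistent$p_quant, 0.05)
})
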
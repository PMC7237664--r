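test_that("problem construction matches the dense all-Grams oracle", {
  X <- fixture_matrix(20, 5, seed = 101)
  y <- rnorm(20)
  prob <- build_hsic_problem(X, rep("continuous", 5), y, "quantitative")
  ora <- oracle_hsic_problem(X, y)
  expect_equal(unname(prob$Q), ora$Q, tolerance = 1e-10)
  expect_equal(unname(prob$c), ora$c, tolerance = 1e-10)
  # blocked computation agrees with a single block
  prob2 <- build_hsic_problem(X, rep("continuous", 5), y, block_size = 2)
  expect_equal(prob2$Q, prob$Q)
  expect_equal(prob2$c, prob$c)
  expect_true(all(prob$c >= -1e-10))
  ev <- eigen(prob$Q, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("self-dependency is maximal and duplicates collapse in Q", {
  set.seed(5)
  y <- rnorm(30)
  X <- cbind(outcome_copy = y, fixture_matrix(30, 3, seed = 6))
  prob <- build_hsic_problem(X, rep("continuous", 4), y, "quantitative")
  expect_equal(names(which.max(prob$c)), "outcome_copy")

  Xd <- cbind(a = X[, 2], b = X[, 2])
  pd <- build_hsic_problem(Xd, rep("continuous", 2), y)
  expect_equal(pd$Q[1, 2], pd$Q[1, 1], tolerance = 1e-10)
  expect_equal(pd$Q[2, 2], pd$Q[1, 1], tolerance = 1e-10)
})

test_that("zero-variance candidates are dropped with a warning, not an abort", {
  X <- fixture_matrix(15, 3, seed = 8)
  X[, 2] <- 7
  expect_warning(prob <- build_hsic_problem(X, rep("continuous", 3), rnorm(15)),
                 "zero-variance")
  expect_equal(prob$feature_ids, c("f1", "f3"))
  expect_equal(prob$dropped, "f2")
})

test_that("coordinate descent solves the nonnegative lasso with KKT certificates", {
  # stationarity at the origin for large penalties
  X <- fixture_matrix(25, 4, seed = 9)
  y <- rnorm(25)
  prob <- build_hsic_problem(X, rep("continuous", 4), y)
  sol <- solve_nonneg_lasso(prob, penalty = max(prob$c) * 1.01)
  expect_identical(unname(sol$alpha), rep(0, 4))

  # closed-form soft-threshold when Q is the identity
  prob_id <- structure(list(Q = diag(2), c = c(3, 1),
                            feature_ids = c("a", "b"),
                            outcome_kind = "quantitative", n = 10,
                            dropped = character(0)), class = "hsic_problem")
  sol_id <- solve_nonneg_lasso(prob_id, penalty = 2)
  expect_equal(unname(sol_id$alpha), c(1, 0))
  expect_equal(sol_id$active_set, "a")

  # objective matches a projected-gradient oracle on random problems
  set.seed(11)
  for (rep in 1:10) {
    p <- sample(3:8, 1)
    n <- sample(10:25, 1)
    Xr <- matrix(rnorm(n * p), n, p)
    colnames(Xr) <- paste0("g", 1:p)
    pr <- build_hsic_problem(Xr, rep("continuous", p), rnorm(n))
    lam <- runif(1, 0.01, 0.3) * max(pr$c)
    sol <- solve_nonneg_lasso(pr, lam)
    a_or <- oracle_nonneg_lasso(pr$Q, pr$c, lam)
    expect_lte(nnlasso_objective(pr$Q, pr$c, lam, unname(sol$alpha)),
               nnlasso_objective(pr$Q, pr$c, lam, a_or) + 1e-8)
    expect_lte(sol$kkt_residual, 1e-8)
    expect_true(all(sol$alpha >= 0))
  }
})

test_that("the penalty path reaches a requested feature count", {
  set.seed(13)
  X <- fixture_matrix(40, 8, seed = 13)
  y <- X[, 1] + 0.5 * X[, 2]^2 + rnorm(40, 0, 0.5)
  prob <- build_hsic_problem(X, rep("continuous", 8), y)

  sel3 <- path_select_k(prob, 3)
  expect_length(sel3$active_set, 3)
  expect_equal(sel3$requested_k, 3)
  # alphas sorted decreasing along the reported active set
  a <- sel3$alpha[sel3$active_set]
  expect_true(all(diff(a) <= 1e-12))

  # k = p at a vanishing penalty activates everything when every feature
  # contributes additive signal (near-diagonal Q with a positive solution)
  Xa <- fixture_matrix(60, 4, seed = 14)
  ya <- rowSums(Xa) + rnorm(60, 0, 0.3)
  proba <- build_hsic_problem(Xa, rep("continuous", 4), ya)
  expect_length(path_select_k(proba, 4)$active_set, 4)

  # a count beyond what the path supports comes back short, with a warning
  expect_warning(short <- path_select_k(prob, 8), "path_select_k")
  expect_lt(length(short$active_set), 8)
  expect_equal(short$requested_k, 8)

  # active-set size is non-increasing in the penalty
  lams <- seq(1e-6, max(prob$c), length.out = 50)
  sizes <- vapply(lams, function(l)
    length(solve_nonneg_lasso(prob, l)$active_set), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("redundant duplicated features are suppressed to a single copy", {
  set.seed(17)
  for (trial in 1:100) {
    n <- 30
    z <- rnorm(n)
    y <- z + rnorm(n, 0, 0.3)
    X <- cbind(dup1 = z, dup2 = z, matrix(rnorm(n * 3), n, 3))
    colnames(X)[3:5] <- paste0("n", 1:3)
    prob <- build_hsic_problem(X, rep("continuous", 5), y)
    lam <- runif(1, 0.05, 0.8) * max(prob$c)
    sol <- solve_nonneg_lasso(prob, lam)
    expect_lte(sum(c("dup1", "dup2") %in% sol$active_set), 1)
  }
  # and a 1-feature path selection across a duplicated causal pair keeps one
  z <- rnorm(50); y <- z + rnorm(50, 0, 0.2)
  X <- cbind(dup1 = z, dup2 = z)
  sel <- path_select_k(build_hsic_problem(X, rep("continuous", 2), y), 1)
  expect_length(intersect(c("dup1", "dup2"), sel$active_set), 1)
})

test_that("selection results serialize to JSON and back", {
  X <- fixture_matrix(20, 4, seed = 19)
  sel <- path_select_k(build_hsic_problem(X, rep("continuous", 4), rnorm(20)), 2)
  js <- jsonlite::fromJSON(write_selection_json(sel))
  expect_equal(js$active_set, sel$active_set)
  expect_equal(js$penalty, sel$penalty)
  expect_equal(js$requested_k, 2)
})
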
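# Independent reference computations used to check the package's bespoke
# numerics. These deliberately share no code with the implementation:
# dense matrix algebra, projected gradient, and expand.grid enumeration.

# centered (optionally Frobenius-normalized) Gram matrix, dense and direct
oracle_gram <- function(x, kind = "continuous", bandwidth = 1, normalize = TRUE) {
  n <- length(x)
  if (kind == "continuous") {
    z <- (x - mean(x)) / sd(x)
    K <- exp(-outer(z, z, "-")^2 / (2 * bandwidth^2))
  } else {
    f <- as.factor(x)
    cnt <- table(f)
    K <- outer(f, f, function(a, b) ifelse(a == b, 1 / cnt[as.character(a)], 0))
    K <- matrix(as.numeric(K), n, n)
  }
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% K %*% H
  if (normalize) Kc / sqrt(sum(Kc^2)) else Kc
}

# HSIC Lasso problem by materializing every Gram at once
oracle_hsic_problem <- function(X, y, kinds = NULL, outcome_kind = "quantitative") {
  p <- ncol(X)
  if (is.null(kinds)) kinds <- rep("continuous", p)
  grams <- lapply(seq_len(p), function(j) oracle_gram(X[, j], kinds[j]))
  L <- oracle_gram(y, if (outcome_kind == "binary") "categorical" else "continuous")
  Q <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    Q[i, j] <- sum(grams[[i]] * grams[[j]])
  cc <- vapply(grams, function(G) sum(G * L), numeric(1))
  list(Q = Q, c = cc)
}

# nonnegative lasso by projected gradient with a fixed small step; slow but
# independent of the coordinate-descent solver
oracle_nonneg_lasso <- function(Q, cc, lambda, iters = 2e5) {
  p <- length(cc)
  step <- 1 / (max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values) + 1e-12)
  a <- numeric(p)
  for (i in seq_len(iters)) {
    g <- drop(Q %*% a) - cc + lambda
    a_new <- pmax(0, a - step * g)
    if (max(abs(a_new - a)) < 1e-13) { a <- a_new; break }
    a <- a_new
  }
  a
}

nnlasso_objective <- function(Q, cc, lambda, a)
  0.5 * drop(t(a) %*% Q %*% a) - sum(cc * a) + lambda * sum(a)

# exact r x 2 Fisher p by expand.grid enumeration (small margins only)
oracle_fisher_rx2 <- function(tab) {
  rs <- rowSums(tab); n1 <- sum(tab[, 1]); N <- sum(tab)
  grid <- do.call(expand.grid, lapply(rs, function(r) 0:r))
  grid <- grid[rowSums(grid) == n1, , drop = FALSE]
  lp <- apply(grid, 1, function(x) sum(lchoose(rs, x))) - lchoose(N, n1)
  lp_obs <- sum(lchoose(rs, tab[, 1])) - lchoose(N, n1)
  sum(exp(lp[lp <= lp_obs + log1p(1e-7)]))
}

# tiny deterministic cohort-like fixture
fixture_matrix <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  X
}
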
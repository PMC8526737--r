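# Core sparse CCA-LPP machinery: graphs, penalties, objective, fit.

test_that("group graphs connect within and between groups as defined", {
  g <- build_group_graphs(c("p", "p", "t"))
  expect_equal(g$Gw, rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  expect_equal(g$Gb, rbind(c(0, 0, 1), c(0, 0, 1), c(1, 1, 0)))
  expect_equal(g$Lw, g$Dw - g$Gw)
  expect_error(build_group_graphs(rep("p", 5)), "two distinct groups")
  # Laplacian row sums vanish for any labeling
  set.seed(1)
  for (i in 1:5) {
    lab <- sample(c("a", "b"), 8, replace = TRUE)
    if (length(unique(lab)) < 2) next
    gg <- build_group_graphs(lab)
    expect_equal(as.vector(gg$Lw %*% rep(1, 8)), rep(0, 8))
    expect_equal(as.vector(gg$Lb %*% rep(1, 8)), rep(0, 8))
  }
})

test_that("LPP penalty equals the pairwise-difference sum over graph edges", {
  set.seed(2)
  for (i in 1:20) {
    lab <- rep(c("a", "b"), each = 4)
    g <- build_group_graphs(lab)
    Z <- matrix(rnorm(8 * 5), 8, 5)
    w <- rnorm(5)
    s <- as.vector(Z %*% w)
    # brute-force pairwise-sum oracle: w'Z'LZw = 1/2 sum_ij G(i,j)(s_i-s_j)^2
    qw <- 0; qb <- 0
    for (a in 1:8) for (b in 1:8) {
      qw <- qw + g$Gw[a, b] * (s[a] - s[b])^2 / 2
      qb <- qb + g$Gb[a, b] * (s[a] - s[b])^2 / 2
    }
    for (alpha in c(0, 0.3, 1)) {
      expect_equal(lpp_penalty(w, Z, g, alpha), alpha * qw - (1 - alpha) * qb,
                   tolerance = 1e-10)
    }
  }
})

test_that("LPP penalty degenerate cases", {
  lab <- rep(c("a", "b"), each = 3)
  g <- build_group_graphs(lab)
  # constant projected scores lie in the Laplacian null space
  Z <- cbind(rep(1, 6), matrix(rnorm(12), 6, 2))
  expect_equal(lpp_penalty(c(1, 0, 0), Z, g, 0.5), 0)
  # Gw == Gb at alpha = 0.5 cancels for any w
  g_eq <- g
  g_eq$Gb <- g$Gw; g_eq$Lb <- g$Lw
  set.seed(3)
  w <- rnorm(3)
  expect_equal(lpp_penalty(w, Z, g_eq, 0.5), 0, tolerance = 1e-10)
  expect_error(lpp_penalty(w, Z, g, 1.5), "alpha")
})

test_that("age regression residual is the squared error of the projection", {
  Z1 <- matrix(rnorm(12), 4, 3)
  A <- rnorm(4)
  expect_equal(age_regression_residual(rep(0, 3), Z1, rep(0, 4)), 0)
  expect_equal(age_regression_residual(rep(0, 3), Z1, A), sum(A^2))
  set.seed(4)
  w <- rnorm(3)
  r <- as.vector(Z1 %*% w) - A
  expect_equal(age_regression_residual(w, Z1, A), sum(r * r))   # direct oracle
  expect_error(age_regression_residual(w, Z1, rnorm(3)), "disagree")
})

test_that("objective equals a term-by-term independent recomputation", {
  set.seed(5)
  n <- 8; m <- 6
  labels <- rep(c("preterm", "term"), each = 4)
  X <- matrix(rnorm(n * m), n, m)
  Y <- matrix(rnorm(n * m), n, m)
  ages <- runif(4, 28, 36)
  data <- feature_pair(X, Y, labels, ages = ages)
  graphs <- build_group_graphs(labels)
  hp <- cclpp_control(lambda = 0.7, beta = 0.3, gamma = 0.2, omega = 0.1,
                      alpha = 0.4)
  u <- rnorm(m); v <- rnorm(m)
  # independent recomputation, term by term
  X1 <- X[1:4, ]; Y1 <- Y[1:4, ]
  expected <- -drop(t(u) %*% t(X) %*% Y %*% v) +
    0.7 * sum((X %*% u)^2) + 0.7 * sum((Y %*% v)^2) +
    0.3 * (0.4 * drop(t(X %*% u) %*% graphs$Lw %*% (X %*% u)) -
           0.6 * drop(t(X %*% u) %*% graphs$Lb %*% (X %*% u))) +
    0.3 * (0.4 * drop(t(Y %*% v) %*% graphs$Lw %*% (Y %*% v)) -
           0.6 * drop(t(Y %*% v) %*% graphs$Lb %*% (Y %*% v))) +
    0.2 * sum((X1 %*% u - ages)^2) + 0.2 * sum((Y1 %*% v - ages)^2) +
    0.1 * sum(abs(u)) + 0.1 * sum(abs(v))
  expect_equal(cclpp_objective(u, v, data, graphs, hp), expected, tolerance = 1e-10)
  # trivial cases
  expect_equal(cclpp_objective(rep(0, m), rep(0, m), data, graphs,
                               cclpp_control(gamma = 0)), 0)
  hp0 <- cclpp_control(lambda = 0, beta = 0, gamma = 0, omega = 0)
  expect_equal(cclpp_objective(u, v, data, graphs, hp0),
               -drop(t(u) %*% crossprod(X, Y) %*% v), tolerance = 1e-10)
})

test_that("canonical correlation is the Pearson correlation of the scores", {
  set.seed(6)
  X <- matrix(rnorm(40), 10, 4)
  u <- rnorm(4)
  expect_equal(canonical_correlation(X, X, u, u), 1)
  expect_equal(canonical_correlation(X, -X, u, u), -1)
  Y <- matrix(rnorm(40), 10, 4)
  v <- rnorm(4)
  expect_equal(canonical_correlation(X, Y, u, v),
               stats::cor(as.vector(X %*% u), as.vector(Y %*% v)))
  expect_error(canonical_correlation(X, Y, rep(0, 4), v), "zero variance")
})

test_that("with identical views and no penalties the fit attains correlation 1", {
  set.seed(7)
  n <- 50; m <- 5
  labels <- rep(c("preterm", "term"), each = 25)
  X <- matrix(rnorm(n * m), n, m)
  data <- feature_pair(X, X, labels)
  fit <- cclpp_fit(data, cclpp_control(beta = 0, gamma = 0, omega = 0,
                                       eta = 0, gram = "exact", eps = 0))
  expect_equal(fit$canonical_corr, 1, tolerance = 1e-6)
  cosang <- abs(sum(fit$u * fit$v)) / sqrt(sum(fit$u^2) * sum(fit$v^2))
  expect_equal(cosang, 1, tolerance = 1e-4)
})

test_that("without penalties the fit reduces to classical CCA", {
  set.seed(8)
  n <- 60; m <- 4
  labels <- rep(c("preterm", "term"), each = 30)
  Z <- matrix(rnorm(n), n, 1)
  X <- 0.9 * Z %*% t(runif(m, 0.5, 1)) + matrix(rnorm(n * m, sd = 0.6), n, m)
  Y <- 0.9 * Z %*% t(runif(m, 0.5, 1)) + matrix(rnorm(n * m, sd = 0.6), n, m)
  data <- feature_pair(X, Y, labels)
  fit <- cclpp_fit(data, cclpp_control(beta = 0, gamma = 0, omega = 0,
                                       eta = 0, gram = "exact", eps = 0,
                                       inner_tol = 1e-12, standardize = TRUE))
  rho_oracle <- stats::cancor(scale(X), scale(Y))$cor[1]
  expect_lt(abs(abs(fit$canonical_corr) - rho_oracle), 1e-6)
})

test_that("first half-update solves the ridge normal equations when only lambda acts", {
  set.seed(9)
  n <- 40; m <- 5
  labels <- rep(c("preterm", "term"), each = 20)
  X <- matrix(rnorm(n * m), n, m)
  Y <- matrix(rnorm(n * m), n, m)
  data <- feature_pair(X, Y, labels)
  hp <- cclpp_control(lambda = 0.9, beta = 0, gamma = 0, omega = 0,
                      eta = 0, gram = "exact", eps = 1e-10, max_iter = 1,
                      inner_tol = 1e-12, init = "ones")
  fit <- suppressWarnings(cclpp_fit(data, hp))
  # stationarity 2*lambda*X'X u = X'Y v0 for the first u-update (v at init)
  Xs <- scale(X); Ys <- scale(Y)
  v0 <- rep(1, m) / stats::sd(as.vector(Ys %*% rep(1, m)))
  u_star <- solve(2 * 0.9 * crossprod(Xs) / n, crossprod(Xs, Ys %*% v0) / n)
  # fit returns u after later v-update and final rescaling: compare directions
  cosang <- abs(sum(fit$u * u_star)) / sqrt(sum(fit$u^2) * sum(u_star^2))
  expect_equal(cosang, 1, tolerance = 1e-6)
})

test_that("a large enough L1 weight zeroes the weight vectors", {
  data <- make_noise_pair(seed = 13)
  expect_warning(
    expect_warning(fit <- cclpp_fit(data, cclpp_control(omega = 1e4)),
                   "collapsed to the zero vector"),
    "collapsed to the zero vector")
  expect_true(fit$zero_u || fit$zero_v)
  expect_true(is.na(fit$canonical_corr))
})

test_that("sparsity is non-increasing in the L1 weight", {
  synth <- generate_cohort(synth_config(n_preterm = 10, n_term = 10,
                                        n_patches = 16, m_edges = 100,
                                        k_signal = 10, seed = 21))
  nnz <- vapply(c(0.05, 0.2, 0.4, 0.8, 1.6), function(om) {
    fit <- suppressWarnings(cclpp_fit(synth$data, cclpp_control(omega = om,
                                                                max_iter = 40)))
    length(fit$support_u)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("fitting is deterministic given identical inputs", {
  synth <- generate_cohort(synth_config(n_preterm = 8, n_term = 8,
                                        n_patches = 12, m_edges = 40,
                                        k_signal = 5, seed = 2))
  f1 <- cclpp_fit(synth$data, cclpp_control(max_iter = 30))
  f2 <- cclpp_fit(synth$data, cclpp_control(max_iter = 30))
  expect_identical(f1$u, f2$u)
  expect_identical(f1$v, f2$v)
  expect_identical(f1$objective_history, f2$objective_history)
})

test_that("unit-variance constraints hold after the final rescaling", {
  synth <- generate_cohort(synth_config(n_preterm = 8, n_term = 8,
                                        n_patches = 12, m_edges = 40,
                                        k_signal = 5, seed = 4))
  fit <- cclpp_fit(synth$data, cclpp_control(max_iter = 30))
  Xs <- scale(synth$data$X); Ys <- scale(synth$data$Y)
  eps <- fit$hp$eps
  expect_equal(drop(crossprod(Xs %*% fit$u)) + eps * sum(fit$u^2), 1,
               tolerance = 1e-6)
  expect_equal(drop(crossprod(Ys %*% fit$v)) + eps * sum(fit$v^2), 1,
               tolerance = 1e-6)
})

test_that("a dominating between-group term triggers the convexity diagnostic", {
  data <- make_noise_pair(n_per_group = 8, m = 30, seed = 15)
  expect_error(cclpp_fit(data, cclpp_control(lambda = 0.01, beta = 5,
                                             gamma = 0, omega = 0.1,
                                             alpha = 0, eta = 0)),
               "not convex")
})
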
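test_that("ridge closed form matches hand-computable cases", {
  # X = I, y = e1, lambda = 1: (I + I)^-1 y = y / 2
  W <- ridge_fit(diag(4), c(1, 0, 0, 0), lambda = 1)
  expect_equal(unname(drop(W)), c(0.5, 0, 0, 0))
  # lambda = 0 on full-rank X reproduces ordinary least squares
  set.seed(3)
  X <- matrix(rnorm(60 * 5), 60)
  Y <- matrix(rnorm(60 * 2), 60)
  expect_equal(ridge_fit(X, Y, 0), qr.solve(X, Y), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("primal and dual ridge solutions agree when p > n", {
  set.seed(4)
  X <- matrix(rnorm(30 * 80), 30)
  Y <- matrix(rnorm(30 * 3), 30)
  W_dual <- ridge_fit(X, Y, 0.7)  # wide: dual path
  W_primal <- solve(crossprod(X) + diag(0.7, 80), crossprod(X, Y))
  expect_equal(W_dual, W_primal, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ridge input validation and singularity handling", {
  expect_error(ridge_fit(matrix(NA_real_, 2, 2), c(1, 2), 1), "finite")
  expect_error(ridge_fit(matrix(1, 3, 2), c(1, 2, 3), -1), "lambda")
  X_sing <- cbind(1:4, 1:4)  # rank 1
  expect_error(ridge_fit(X_sing, rnorm(4), 0), "singular")
})

test_that("shrinkage is monotone in lambda and columns are separable", {
  set.seed(5)
  X <- matrix(rnorm(50 * 8), 50)
  Y <- matrix(rnorm(50 * 6), 50)
  norms <- vapply(c(0.01, 0.1, 1, 10, 100),
                  function(l) sqrt(sum(ridge_fit(X, Y, l)^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
  # joint multi-target fit equals per-column fits
  W_joint <- ridge_fit(X, Y, 1)
  W_cols <- sapply(1:6, function(j) ridge_fit(X, Y[, j, drop = FALSE], 1))
  expect_equal(unname(W_joint), unname(W_cols), tolerance = 1e-12)
})

test_that("RFF sampler is seeded and matches its moment contract", {
  m1 <- rff_sample(5, 300, sigma = 2, seed = 9)
  m2 <- rff_sample(5, 300, sigma = 2, seed = 9)
  expect_identical(m1, m2)
  expect_error(rff_sample(5, 300, sigma = 0, seed = 1), "sigma")
  # Var(Omega) = 1/sigma^2 at D*d = 1e5 within 2%
  big <- rff_sample(10, 10000L, sigma = 2, seed = 1)
  expect_equal(stats::var(as.numeric(big$Omega)), 1 / 4, tolerance = 0.02)
  expect_true(all(big$b >= 0 & big$b < 2 * pi))
})

test_that("RFF transform has the cosine form and range", {
  map <- rff_sample(3, 50, sigma = 1, seed = 2)
  X <- matrix(rnorm(20 * 3), 20)
  Phi <- rff_transform(map, X)
  expect_equal(dim(Phi), c(20, 50))
  expect_true(all(abs(Phi) <= sqrt(2 / 50) + 1e-12))
  expect_equal(Phi, sqrt(2 / 50) *
                 cos(sweep(X %*% t(map$Omega), 2, map$b, "+")),
               tolerance = 1e-12)
  expect_error(rff_transform(map, matrix(0, 2, 4)), "columns")
})

test_that("RFF inner products approximate the RBF kernel", {
  set.seed(6)
  d <- 10; sigma <- 2
  X <- matrix(rnorm(200 * d), 200)
  i <- 1:100; j <- 101:200
  k_true <- exp(-rowSums((X[i, ] - X[j, ])^2) / (2 * sigma^2))
  map <- rff_sample(d, 10000L, sigma, seed = 13)
  Phi <- rff_transform(map, X)
  k_hat <- rowSums(Phi[i, ] * Phi[j, ])
  expect_lt(mean(abs(k_hat - k_true)), 0.05)
  # diagonal: phi(x)'phi(x) ~ 1
  expect_equal(mean(rowSums(Phi[i, ]^2)), 1, tolerance = 0.05)
})

test_that("RBF kernel matches an independent kernel implementation", {
  skip_if_not_installed("kernlab")
  set.seed(8)
  X <- matrix(rnorm(15 * 4), 15)
  sigma <- 1.5
  K_ours <- exp(-as.matrix(dist(X))^2 / (2 * sigma^2))
  K_ref <- kernlab::kernelMatrix(kernlab::rbfdot(sigma = 1 / (2 * sigma^2)),
                                 X)
  expect_equal(K_ours, matrix(K_ref@.Data, 15, 15), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("kernel ridge oracle behaves at its analytic limits", {
  set.seed(10)
  X <- matrix(rnorm(20 * 3), 20)
  Y <- matrix(rnorm(20 * 2), 20)
  # n = 1: prediction at the training point is the shrunk target
  p1 <- krr_rbf_oracle(X[1, , drop = FALSE], Y[1, , drop = FALSE],
                       lambda = 1, sigma = 1, X[1, , drop = FALSE])
  expect_equal(p1, Y[1, , drop = FALSE] / 2, tolerance = 1e-12,
               ignore_attr = TRUE)
  # sigma -> infinity: K -> all-ones; compare with that limit computed
  # directly from the constant kernel
  p_inf <- krr_rbf_oracle(X, Y, lambda = 1, sigma = 1e7, X[1:5, , drop = FALSE])
  J <- matrix(1, 20, 20)
  p_lim <- matrix(1, 5, 20) %*% solve(J + diag(1, 20), Y)
  expect_equal(p_inf, p_lim, tolerance = 1e-4)
})

test_that("RFF ridge converges to the exact kernel ridge oracle", {
  set.seed(12)
  n <- 50; d <- 10
  X <- matrix(rnorm(n * d), n)
  Y <- cbind(sin(X[, 1]) + 0.5 * X[, 2], X[, 3]^2 - 1)
  X_test <- matrix(rnorm(30 * d), 30)
  rng <- apply(Y, 2, function(v) diff(range(v)))
  oracle <- krr_rbf_oracle(X, Y, lambda = 1, sigma = 2, X_test)
  dev <- vapply(c(100L, 1000L, 10000L), function(D) {
    m <- rff_ridge_fit(X, Y, lambda = 1, sigma = 2, D = D, seed = 31)
    max(abs(predict(m, X_test) - oracle) / rep(rng, each = 30))
  }, numeric(1))
  expect_lt(dev[3], 0.02)       # within 2% of range at D = 1e4
  expect_lt(dev[3], dev[1])     # and decreasing with D
})

test_that("predictions are deterministic, row-consistent and shrink to zero", {
  set.seed(14)
  X <- matrix(rnorm(40 * 6), 40)
  Y <- matrix(rnorm(40 * 6), 40)
  m <- rff_ridge_fit(X, Y, lambda = 1, sigma = 1.5, D = 200, seed = 3)
  p <- predict(m, X)
  # row order invariance of the row-wise map
  perm <- sample(40)
  expect_equal(predict(m, X[perm, ])[order(perm), ], p, tolerance = 1e-12)
  # lambda -> infinity: predictions vanish
  m_inf <- rff_ridge_fit(X, Y, lambda = 1e12, sigma = 1.5, D = 200, seed = 3)
  expect_lt(max(abs(predict(m_inf, X))), 1e-6)
  # zero-weight linear model predicts zero
  m0 <- fit_model(X, Y, lambda = 1, feature_map = "identity")
  m0$weights[] <- 0
  expect_true(all(predict(m0, X) == 0))
})

test_that("an RFF model with tuned bandwidth fits a noiseless linear target", {
  set.seed(15)
  X <- matrix(runif(300 * 4), 300)
  Y <- X %*% matrix(c(1, -2, 0.5, 3), 4)
  grid <- median_heuristic_grid(X, n_grid = 6, seed = 1)
  s <- grid_search_sigma(X, Y, lambda = 1e-6, D = 300, sigma_grid = grid,
                         seed = 1)
  m <- rff_ridge_fit(X, Y, lambda = 1e-6, sigma = s, D = 300, seed = 2)
  expect_lt(nrmse(predict(m, X), Y)[1], 0.05)
})

test_that("bandwidth grid search is deterministic and recovers the truth", {
  expect_error(grid_search_sigma(diag(2), 1:2, sigma_grid = numeric(0)),
               "non-empty")
  expect_equal(grid_search_sigma(diag(2), matrix(1:2), sigma_grid = 3.3), 3.3)
  # RBF-generated targets: selected sigma within one grid step of truth
  sigma_true <- 1
  grid <- c(0.25, 0.5, 1, 2, 4)
  hits <- vapply(1:20, function(run) {
    set.seed(1000 + run)
    X <- matrix(rnorm(120 * 3), 120)
    centers <- X[1:15, ]
    K <- exp(-outer(rowSums(X^2), rowSums(centers^2), "+") / (2 * sigma_true^2) +
               tcrossprod(X, centers) / sigma_true^2)
    Y <- K %*% rnorm(15)
    s <- grid_search_sigma(X, Y, lambda = 0.1, D = 200, sigma_grid = grid,
                           seed = run)
    which(grid == s)
  }, numeric(1))
  expect_gte(mean(abs(hits - 3) <= 1), 0.9)
  # determinism
  set.seed(77)
  X <- matrix(rnorm(80 * 3), 80); Y <- rnorm(80)
  expect_identical(grid_search_sigma(X, Y, sigma_grid = grid, seed = 5),
                   grid_search_sigma(X, Y, sigma_grid = grid, seed = 5))
})

test_that("model serialization round-trips losslessly", {
  set.seed(16)
  X <- matrix(rnorm(30 * 4), 30)
  Y <- matrix(rnorm(30 * 2), 30)
  colnames(Y) <- c("a", "b")
  for (fm in c("identity", "rff")) {
    m <- fit_model(X, Y, lambda = 1, feature_map = fm, sigma = 1.2, D = 50,
                   seed = 4)
    path <- tempfile(fileext = ".json")
    write_model(m, path)
    m2 <- read_model(path)
    expect_equal(m2$weights, m$weights, tolerance = 1e-15)
    expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
    unlink(path)
  }
})
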
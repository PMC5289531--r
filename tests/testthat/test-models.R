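test_that("fit_ols reproduces the normal-equation solution", {
  # exact interpolation: zero residuals
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3)
  beta <- c(2, -1, 0.5)
  y <- drop(X %*% beta)
  m <- fit_ols(spectra(X, y))
  expect_equal(predict(m, X), y, tolerance = 1e-8)

  # orthonormal columns: beta = X'y (no standardization)
  Q <- rand_orthonormal(30, 4, seed = 2)
  set.seed(3)
  yq <- rnorm(30)
  mq <- fit_ols(Q, yq, standardize = FALSE)
  expect_equal(mq$beta_std, drop(crossprod(Q, yq)), tolerance = 1e-10)

  # 5 x 2 random system vs textbook solve
  set.seed(4)
  X5 <- matrix(rnorm(10), 5, 2)
  y5 <- rnorm(5)
  m5 <- fit_ols(X5, y5, standardize = FALSE)
  expect_equal(m5$beta_std, ols_oracle(X5, y5), tolerance = 1e-10)

  # residual orthogonality to the column space
  r <- y5 - predict(m5, X5)
  expect_lt(max(abs(crossprod(X5, r))), 1e-10)
})

test_that("fit_ols rejects rank deficiency unless the pseudo-inverse is requested", {
  set.seed(5)
  X <- matrix(rnorm(20), 10, 2)
  X <- cbind(X, X[, 1]) # duplicated column
  y <- rnorm(10)
  expect_error(fit_ols(X, y, standardize = FALSE), "rank-deficient")
  m <- fit_ols(X, y, standardize = FALSE, pseudo_inverse = TRUE)
  expect_equal(m$beta_std, drop(MASS::ginv(X) %*% y), tolerance = 1e-8)
})

test_that("NIPALS PLS matches the Krylov-subspace oracle", {
  set.seed(6)
  X <- matrix(rnorm(160), 20, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(20, sd = 0.3)
  ds <- spectra(X, y)
  st <- standardize(ds)
  for (h in c(1, 3, 5)) {
    m <- fit_pls(ds, h = h)
    expect_equal(m$beta_std, pls_krylov_oracle(st$data$X, st$data$y, h),
                 tolerance = 1e-8)
  }
})

test_that("PLS scores are orthogonal and residuals shrink with h", {
  set.seed(7)
  ds <- rand_spectra(25, 6, seed = 7)
  st <- standardize(ds)
  rss <- sapply(1:5, function(h) {
    m <- fit_pls(ds, h = h)
    Tm <- m$decomposition$T
    off <- crossprod(Tm)
    diag(off) <- 0
    expect_lt(max(abs(off)), 1e-8)
    sum((st$data$y - st$data$X %*% m$beta_std)^2)
  })
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("full-rank PLS equals OLS and one channel gives the simple slope", {
  ds <- rand_spectra(30, 7, seed = 8)
  m_pls <- fit_pls(ds, h = 7)
  m_ols <- fit_ols(ds)
  expect_equal(predict(m_pls, ds$X), predict(m_ols, ds$X), tolerance = 1e-8)

  ds1 <- rand_spectra(15, 1, seed = 9)
  st1 <- standardize(ds1)
  m1 <- fit_pls(ds1, h = 1)
  slope <- sum(st1$data$X * st1$data$y) / sum(st1$data$X^2)
  expect_equal(drop(m1$beta_std), slope, tolerance = 1e-10)
})

test_that("PLS stops early with a warning when the response is exhausted", {
  # rank-2 X with y lying in its column space: components 3+ have nothing left
  set.seed(10)
  T2 <- matrix(rnorm(24), 12, 2)
  P2 <- matrix(rnorm(10), 5, 2)
  X <- T2 %*% t(P2)
  y <- drop(T2 %*% c(1, -2))
  ds <- spectra(X, y)
  expect_warning(m <- fit_pls(ds, h = 4), "exhausted")
  expect_lt(m$hyperparams$h, 4)
  expect_equal(predict(m, X), y, tolerance = 1e-6)
  expect_error(fit_pls(ds, h = 20), "must be an integer in 1..")
})

test_that("elastic net matches the orthonormal closed form and its limits", {
  Q <- rand_orthonormal(40, 6, seed = 11)
  set.seed(12)
  y <- rnorm(40)
  # full shrinkage at lambda1 >= 2 max|X'y|
  l1_max <- 2 * max(abs(crossprod(Q, y)))
  m0 <- fit_enet(Q, y, lambda1 = l1_max * 1.001, lambda2 = 0.3,
                 standardize = FALSE)
  expect_true(all(m0$beta_std == 0))
  # unpenalized limit equals OLS
  mo <- fit_enet(Q, y, lambda1 = 0, lambda2 = 0, standardize = FALSE)
  expect_equal(mo$beta_std, drop(crossprod(Q, y)), tolerance = 1e-8)
  # closed form across penalties
  for (l1 in c(0.1, 0.6)) {
    for (l2 in c(0, 0.5, 2)) {
      m <- fit_enet(Q, y, lambda1 = l1, lambda2 = l2, standardize = FALSE)
      expect_equal(m$beta_std, enet_ortho_oracle(Q, y, l1, l2),
                   tolerance = 1e-8)
    }
  }
})

test_that("elastic net agrees with glmnet on a correlated random problem", {
  ds <- rand_spectra(50, 12, seed = 13)
  st <- standardize(ds)
  n <- 50
  l1 <- 8; l2 <- 3
  m <- fit_enet(ds, lambda1 = l1, lambda2 = l2)
  naive <- m$beta_std / (1 + l2 / n)
  # map the unnormalized objective to glmnet's 1/(2n)-scaled one
  alpha <- l1 / (l1 + 2 * l2)
  lam <- (l1 + 2 * l2) / (2 * n)
  g <- glmnet::glmnet(st$data$X, st$data$y, alpha = alpha, lambda = lam,
                      standardize = FALSE, intercept = FALSE, thresh = 1e-14)
  # tolerance reflects glmnet's own convergence on a single-lambda call; a
  # penalty-mapping or rescaling error would show up at the percent level
  expect_equal(naive, as.numeric(g$beta), tolerance = 1e-3)
})

test_that("elastic-net solutions satisfy the KKT conditions and sparsity is monotone", {
  for (seed in 1:5) {
    ds <- rand_spectra(30, 20, seed = 100 + seed, sigma = 1)
    nnz_path <- c()
    for (l1 in c(1, 4, 16, 64)) {
      m <- fit_enet(ds, lambda1 = l1, lambda2 = 2)
      expect_lt(enet_kkt_residual(m, ds), 1e-6)
      nnz_path <- c(nnz_path, sum(m$beta_std != 0))
    }
    expect_true(all(diff(nnz_path) <= 0))
  }
})

test_that("the grouping effect gives duplicated channels equal coefficients", {
  set.seed(14)
  X <- matrix(rnorm(80), 40, 2)
  X <- cbind(X, X[, 1]) # channel 3 duplicates channel 1
  y <- drop(X[, 1] * 2 - X[, 2]) + rnorm(40, sd = 0.2)
  m <- fit_enet(X, y, lambda1 = 5, lambda2 = 2)
  expect_equal(m$beta_std[1], m$beta_std[3], tolerance = 1e-6)
})

test_that("predictions agree through the standardized and raw pathways", {
  ds <- rand_spectra(25, 5, seed = 15)
  m <- fit_enet(ds, lambda1 = 3, lambda2 = 1)
  Xnew <- matrix(rnorm(20 * 5), 20, 5)
  std <- enetbeta:::apply_stats(m$stats, X = Xnew)
  via_std <- drop(std$X %*% m$beta_std) * m$stats$y_scale + m$stats$y_mean
  expect_equal(predict(m, Xnew), via_std, tolerance = 1e-10)
  # all-zero model predicts the training mean
  m0 <- fit_enet(ds, lambda1 = 1e6, lambda2 = 1)
  expect_equal(predict(m0, Xnew), rep(mean(ds$y), 20), tolerance = 1e-10)
  expect_error(predict(m, Xnew[, 1:3]), "channels")
})

test_that("grid search reproduces an exhaustive CV evaluation", {
  sim <- simulate_spectra(n = 60, p = 30, k_true = 3, rho = 0.9, snr = 20,
                          seed = 16)
  ds <- sim$data
  g1 <- c(2, 8, 32)
  g2 <- c(0.5, 4, 16)
  gs <- enet_grid_search(ds, lambda1_grid = g1, lambda2_grid = g2,
                         folds = 5, seed = 3)
  # independent exhaustive re-evaluation with an explicit fold loop
  folds <- enetbeta:::cv_folds(60, 5, seed = 3)
  cv <- outer(g1, g2, Vectorize(function(l1, l2) {
    mean(sapply(folds, function(idx) {
      m <- fit_enet(ds[-idx, ], lambda1 = l1, lambda2 = l2)
      sqrt(mean((ds$y[idx] - predict(m, ds$X[idx, , drop = FALSE]))^2))
    }))
  }))
  best <- which(cv == min(cv), arr.ind = TRUE)[1, ]
  expect_equal(gs$lambda1, g1[best["row"]])
  expect_equal(gs$lambda2, g2[best["col"]])
  expect_equal(min(gs$cv$cv_rmsep), min(cv), tolerance = 1e-10)

  # a one-point grid is returned as-is
  gs1 <- enet_grid_search(ds, lambda1_grid = 5, lambda2_grid = 1, folds = 5)
  expect_equal(gs1$lambda1, 5)
  expect_equal(gs1$lambda2, 1)
})

test_that("grid search finds a near-interpolating model when truth is realizable", {
  set.seed(17)
  X <- matrix(rnorm(70 * 10), 70, 10)
  beta <- c(3, -2, 1.5, rep(0, 7))
  y <- drop(X %*% beta) # noiseless
  ds <- spectra(X, y)
  gs <- enet_grid_search(ds, lambda1_grid = c(1e-4, 1e-2, 1),
                         lambda2_grid = c(1e-4, 1e-2), folds = 5, seed = 1)
  expect_lt(min(gs$cv$cv_rmsep), 0.05 * sd(y))
})
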
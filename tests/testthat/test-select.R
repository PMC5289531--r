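make_model_with_beta <- function(beta) {
  # minimal calib_model carrying a prescribed standardized coefficient vector
  enetbeta:::new_calib_model(beta, enetbeta:::identity_stats(length(beta)),
                             "ENET", list(lambda1 = 1, lambda2 = 1),
                             paste0("ch", seq_along(beta)))
}

test_that("coefficient ranking sorts by |beta| with index tie-breaks", {
  expect_identical(rank_by_coefficient(make_model_with_beta(c(0.1, -0.5, 0.3))),
                   c(2L, 3L, 1L))
  expect_identical(rank_by_coefficient(make_model_with_beta(rep(0, 4))),
                   1:4)
  b <- c(0.2, 0, 0, 0.7, 0, 0, -0.7)
  expect_identical(rank_by_coefficient(make_model_with_beta(b))[1:2], c(4L, 7L))
})

test_that("ht_reduce reproduces the hand-computed examples", {
  expect_identical(ht_reduce(c(0.6, 0.5, 0.45), i_star = 3, conf = 0.9), 2L)
  expect_identical(ht_reduce(c(0.50, 0.48, 0.46, 0.455, 0.45), i_star = 5,
                             conf = 0.9), 1L)
  # conf = 1 on a strictly decreasing curve keeps i_star
  expect_identical(ht_reduce(c(0.9, 0.7, 0.5), i_star = 3, conf = 1), 3L)
  expect_identical(ht_reduce(c(0.5, 0.6), i_star = 1, conf = 0.5), 1L)
  # zero-valued curve entries
  expect_identical(ht_reduce(c(0.5, 0), i_star = 2, conf = 0.9), 2L)
  expect_identical(ht_reduce(c(0, 0), i_star = 2, conf = 0.9), 1L)
  expect_error(ht_reduce(c(0.5, 0.4), i_star = 5, conf = 0.9), "index")
  expect_error(ht_reduce(c(0.5, 0.4), i_star = 2, conf = 0), "conf")
})

test_that("ht_reduce never enlarges the subset and is monotone in conf", {
  for (seed in 1:1000) {
    set.seed(seed)
    curve <- runif(sample(2:12, 1), 0.2, 1)
    i_star <- which.min(curve)
    confs <- sort(runif(4, 0.01, 1), decreasing = TRUE)
    sizes <- sapply(confs, function(cf) ht_reduce(curve, i_star, cf))
    expect_true(all(sizes <= i_star))
    # lowering conf can only shrink the accepted size
    expect_true(all(diff(sizes) <= 0))
    expect_identical(ht_reduce(curve, i_star, conf = 1e-9),
                     1L)
  }
})

test_that("the norm-ratio prefix rule matches hand arithmetic", {
  # |beta| = (3, 2, 1): prefix of 1 has ratio 3/sqrt(14) ~ 0.802 <= 0.9,
  # prefix of 2 has sqrt(13/14) ~ 0.964 > 0.9
  beta <- c(3, -2, 1)
  ranking <- c(1L, 2L, 3L)
  expect_identical(enetbeta:::prefix_by_norm(beta, ranking, 0.9), 2L)
  expect_identical(enetbeta:::prefix_by_norm(beta, ranking, 0.1), 1L)
  expect_identical(enetbeta:::prefix_by_norm(beta, ranking, 1), 3L)
})

test_that("pls_beta selects a norm-carrying prefix, shrinking as alpha falls", {
  ds <- rand_spectra(40, 8, seed = 41)
  sizes <- sapply(c(0.999, 0.9, 0.5, 0.05), function(a) {
    length(pls_beta(ds, h = 4, alpha = a)$selected)
  })
  expect_true(all(diff(sizes) <= 0))
  expect_identical(sizes[4], 1L)
  v <- pls_beta(ds, h = 4, alpha = 1)
  expect_identical(length(v$selected), 8L)
  expect_identical(v$final_model$method, "PLS")
  # selected channels carry > alpha of the coefficient norm
  v9 <- pls_beta(ds, h = 4, alpha = 0.9)
  full <- fit_pls(ds, h = 4)
  ratio <- sqrt(sum(full$beta_std[v9$selected]^2) / sum(full$beta_std^2))
  expect_gt(ratio, 0.9)
})

test_that("forward stepwise finds an exact predictor immediately", {
  set.seed(42)
  X <- matrix(rnorm(200), 50, 4)
  st_x3 <- (X[, 3] - mean(X[, 3])) / sd(X[, 3])
  y <- 2 * st_x3
  v <- fss_bic(spectra(X, y))
  expect_identical(v$ranking[1], 3L)
  expect_identical(v$selected, 3L)
  expect_equal(predict(v, X), y, tolerance = 1e-8)
})

test_that("forward stepwise keeps the intercept-only model on pure noise", {
  set.seed(43)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- rnorm(200)
  v <- fss_bic(spectra(X, y))
  expect_identical(length(v$selected), 0L)
  expect_equal(predict(v, X), rep(mean(y), 200), tolerance = 1e-10)
})

test_that("greedy forward path matches an exhaustive per-step oracle", {
  for (seed in c(51, 52, 53)) {
    ds <- rand_spectra(30, 4, seed = seed, sigma = 1.5)
    v <- fss_bic(ds)
    st <- standardize(ds)
    Xs <- st$data$X; ys <- st$data$y
    # oracle: at each step, refit OLS on active+candidate for every candidate
    active <- integer(0)
    remaining <- 1:4
    oracle_path <- integer(0)
    for (k in seq_len(length(v$ranking))) {
      ssr <- sapply(remaining, function(j) {
        Z <- Xs[, c(active, j), drop = FALSE]
        sum(lm.fit(Z, ys)$residuals^2)
      })
      j_best <- remaining[which.min(ssr)]
      oracle_path <- c(oracle_path, j_best)
      active <- c(active, j_best)
      remaining <- setdiff(remaining, j_best)
    }
    expect_identical(v$ranking, oracle_path)
    # BIC argmin over the path equals the reported size
    ssr_sizes <- sapply(0:length(oracle_path), function(k) {
      if (k == 0) sum(ys^2) else {
        Z <- Xs[, oracle_path[1:k], drop = FALSE]
        sum(lm.fit(Z, ys)$residuals^2)
      }
    })
    bics <- sapply(seq_along(ssr_sizes),
                   function(i) 30 * log(ssr_sizes[i] / 30) + (i - 1) * log(30))
    expect_identical(length(v$selected), which.min(bics) - 1L)
  }
})

test_that("forward stepwise is invariant to channel permutation", {
  ds <- rand_spectra(40, 6, seed = 61, sigma = 1)
  v <- fss_bic(ds)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  ds_p <- ds[, perm]
  v_p <- fss_bic(ds_p)
  expect_identical(perm[v_p$ranking], v$ranking)
  expect_setequal(perm[v_p$selected], v$selected)
})

test_that("enet_beta follows the rank-refit-relax procedure end to end", {
  sim <- simulate_spectra(n = 100, p = 40, k_true = 3, rho = 0.9, snr = 1e4,
                          seed = 71)
  ds <- sim$data
  v <- enet_beta(ds, lambda1 = 10, lambda2 = 2, folds = 5, seed = 1)
  # curve restricted to the enet support size
  expect_lte(length(v$rmsep_curve), 40)
  expect_identical(v$rmsep_curve[v$i_star], min(v$rmsep_curve))
  expect_lte(v$i_ht, v$i_star)
  expect_identical(v$selected, v$ranking[seq_len(v$i_ht)])
  expect_identical(v$final_model$method, "ENET")
  # near-noiseless truth: the selection covers most of the planted support
  sc <- score_recovery(v$selected, sim$truth)
  expect_gte(sc$sensitivity, 2 / 3)

  # penalty too large for any ranking signal is an error
  expect_error(enet_beta(ds, lambda1 = 1e8, lambda2 = 1), "penalty too large")
  # holdout policy requires a holdout set
  expect_error(enet_beta(ds, lambda1 = 10, lambda2 = 2, eval = "holdout"),
               "holdout")
})

test_that("enet_beta holdout policy scores prefixes on the supplied set", {
  sim <- simulate_spectra(n = 140, p = 25, k_true = 3, rho = 0.9, snr = 100,
                          seed = 72)
  sp <- split_spectra(sim$data, 0.3, seed = 2)
  v <- enet_beta(sp$train, lambda1 = 8, lambda2 = 2, eval = "holdout",
                 holdout = sp$test)
  # recompute one curve point by hand
  i <- v$i_star
  sub_idx <- v$ranking[seq_len(i)]
  m <- fit_enet(sp$train[, sub_idx], lambda1 = 8, lambda2 = 2)
  expect_equal(v$rmsep_curve[i],
               rmsep(sp$test$y, predict(m, sp$test$X[, sub_idx, drop = FALSE])),
               tolerance = 1e-10)
})

test_that("selection results are deterministic under a fixed seed", {
  sim <- simulate_spectra(n = 80, p = 20, k_true = 3, rho = 0.9, snr = 30,
                          seed = 73)
  v1 <- enet_beta(sim$data, lambda1 = 6, lambda2 = 2, folds = 5, seed = 9)
  v2 <- enet_beta(sim$data, lambda1 = 6, lambda2 = 2, folds = 5, seed = 9)
  expect_identical(v1$rmsep_curve, v2$rmsep_curve)
  expect_identical(v1$selected, v2$selected)
})
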
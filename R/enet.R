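#' Elastic-net calibration by cyclic coordinate descent
#'
#' Solves the (unnormalized) naive elastic-net problem on the standardized
#' scale,
#' \deqn{\hat\beta_{naive} = \arg\min_\beta \|y - X\beta\|^2
#'       + \lambda_1 \|\beta\|_1 + \lambda_2 \|\beta\|_2^2,}
#' by cyclic coordinate descent on the Gram form (covariance updates), and
#' returns the rescaled elastic-net estimator
#' \eqn{\hat\beta = (1 + \lambda_2/n)\,\hat\beta_{naive}}, which undoes the
#' extra shrinkage the ridge term applies on top of the lasso. The L1 part
#' produces exact zeros (variable selection); the L2 part removes the
#' saturation limit of the lasso for `p > n` and encourages the grouping
#' effect on correlated channels. The returned solution is certified against
#' the subgradient KKT conditions; non-convergence is an error.
#'
#' @inheritParams fit_ols
#' @param lambda1 nonnegative L1 penalty weight (note the unnormalized
#'   objective: the all-zero solution appears at
#'   `lambda1 >= 2 * max|X'y|`).
#' @param lambda2 nonnegative L2 penalty weight.
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change in a full sweep.
#' @param kkt_tol required bound on the subgradient stationarity residual at
#'   the returned solution (absolute, on the standardized Gram scale).
#' @param max_iter maximum number of sweeps.
#' @param beta_init optional warm-start vector (naive scale).
#' @return A `"calib_model"` with `method = "ENET"`; `$hyperparams` holds
#'   `lambda1`, `lambda2`; `$sweeps` the sweep count.
#' @examples
#' sim <- simulate_spectra(n = 60, p = 20, k_true = 3, seed = 7)
#' m <- fit_enet(sim$data, lambda1 = 20, lambda2 = 1)
#' sum(coef(m, "std") != 0)
#' @export
fit_enet <- function(x, y = NULL, lambda1, lambda2, standardize = TRUE,
                     tol = 1e-8, max_iter = 1e5, beta_init = NULL,
                     kkt_tol = 1e-7) {
  if (!is.numeric(lambda1) || length(lambda1) != 1L || lambda1 < 0) {
    stop_bad_arg("`lambda1` must be a single nonnegative number")
  }
  if (!is.numeric(lambda2) || length(lambda2) != 1L || lambda2 < 0) {
    stop_bad_arg("`lambda2` must be a single nonnegative number")
  }
  tr <- resolve_training(x, y, standardize)
  n <- nrow(tr$Xs)
  p <- ncol(tr$Xs)
  G <- crossprod(tr$Xs)
  xy <- drop(crossprod(tr$Xs, tr$ys))
  if (is.null(beta_init)) beta_init <- numeric(p)
  fit <- .enet_cd(G, xy, lambda1, lambda2, as.numeric(beta_init),
                  tol, as.integer(max_iter), kkt_tol)
  if (!fit$converged) {
    kkt <- kkt_violation(G, xy, fit$beta, lambda1, lambda2)
    stop_bad_arg(sprintf(
      "coordinate descent did not converge in %d sweeps (last step %.3e, KKT residual %.3e)",
      fit$iter, fit$max_delta, kkt))
  }
  beta_std <- (1 + lambda2 / n) * fit$beta
  model <- new_calib_model(beta_std, tr$stats, "ENET",
                           list(lambda1 = lambda1, lambda2 = lambda2),
                           tr$labels,
                           extra = list(n_train = n, sweeps = fit$iter,
                                        tol = tol))
  model$fitted_raw <- predict(model, if (inherits(x, "spectra")) x$X else as.matrix(x))
  model$y_train <- tr$y_raw
  model
}

# Maximum violation of the subgradient stationarity conditions of the naive
# objective ||y - Xb||^2 + l1 |b| + l2 b^2, in Gram form. For b_j = 0 the
# condition is |2 (G b - xy)_j| <= l1; for b_j != 0 it is
# 2 (G b - xy)_j + 2 l2 b_j + l1 sign(b_j) = 0.
kkt_violation <- function(G, xy, beta, lambda1, lambda2) {
  g <- 2 * (drop(G %*% beta) - xy)
  zero <- beta == 0
  v_zero <- if (any(zero)) max(pmax(0, abs(g[zero]) - lambda1)) else 0
  v_nz <- if (any(!zero)) {
    max(abs(g[!zero] + 2 * lambda2 * beta[!zero] + lambda1 * sign(beta[!zero])))
  } else 0
  max(v_zero, v_nz)
}

#' KKT residual of a fitted elastic-net model
#'
#' Recomputes, on the model's own standardized training scale, the maximum
#' violation of the subgradient stationarity conditions of the naive
#' elastic-net objective at the fitted solution. A correct solution has a
#' residual at the level of the solver tolerance (well below 1e-6).
#'
#' @param model a `"calib_model"` fitted by [fit_enet()].
#' @param x the training data ([spectra] or matrix, raw scale as passed to
#'   [fit_enet()]).
#' @param y training response when `x` is a matrix.
#' @return The maximum KKT violation (a nonnegative scalar).
#' @export
enet_kkt_residual <- function(model, x, y = NULL) {
  stopifnot(inherits(model, "calib_model"))
  if (model$method != "ENET") stop_bad_arg("model was not fitted by fit_enet()")
  X <- if (inherits(x, "spectra")) x$X else as.matrix(x)
  yv <- if (inherits(x, "spectra")) x$y else as.numeric(y)
  std <- apply_stats(model$stats, X = X, y = yv)
  l1 <- model$hyperparams$lambda1
  l2 <- model$hyperparams$lambda2
  naive <- model$beta_std / (1 + l2 / model$n_train)
  kkt_violation(crossprod(std$X), drop(crossprod(std$X, std$y)), naive, l1, l2)
}

#' Cross-validated grid search for the elastic-net penalties
#'
#' Evaluates every pair on a (lambda1, lambda2) grid by K-fold
#' cross-validated RMSEP on the training set (per-fold standardization, no
#' leakage) and refits the winning pair on all training data. Ties within
#' 1e-12 go to the smallest `lambda1`, then the smallest `lambda2`.
#'
#' Default grids are data-scaled: `lambda1` runs on a log scale below the
#' full-shrinkage bound `2 max|X'y|` (computed on the standardized training
#' data), and `lambda2` is scaled by the Gram diagonal `n - 1`.
#'
#' @param x a [spectra] training dataset.
#' @param lambda1_grid,lambda2_grid numeric vectors of candidate penalties;
#'   `NULL` for the data-scaled defaults.
#' @param folds number of CV folds (default 9).
#' @param seed integer seed for the fold partition.
#' @param tol,max_iter passed to [fit_enet()].
#' @return A list of class `"enet_grid"`: `lambda1`, `lambda2`, `model` (the
#'   refit on all training data), `cv` (a data frame of all grid points and
#'   their CV RMSEP), `folds`, `seed`.
#' @export
enet_grid_search <- function(x, lambda1_grid = NULL, lambda2_grid = NULL,
                             folds = 9L, seed = 1L, tol = 1e-8,
                             max_iter = 1e5) {
  stopifnot(inherits(x, "spectra"))
  n <- nrow(x$X)
  if (is.null(lambda1_grid) || is.null(lambda2_grid)) {
    st <- standardize(x)
    lam_max <- 2 * max(abs(crossprod(st$data$X, st$data$y)))
    if (is.null(lambda1_grid)) {
      lambda1_grid <- lam_max * 10^seq(-3, 0, length.out = 7L)
    }
    if (is.null(lambda2_grid)) lambda2_grid <- (n - 1) * c(0.01, 0.1, 1)
  }
  if (!length(lambda1_grid) || !length(lambda2_grid)) {
    stop_bad_arg("penalty grids must be nonempty")
  }
  grid <- expand.grid(lambda1 = sort(as.numeric(lambda1_grid)),
                      lambda2 = sort(as.numeric(lambda2_grid)))
  cv_err <- vapply(seq_len(nrow(grid)), function(i) {
    fitter <- enet_fitter(grid$lambda1[i], grid$lambda2[i], tol, max_iter)
    kfold_cv(x, fitter, folds = folds, seed = seed)
  }, numeric(1))
  grid$cv_rmsep <- cv_err
  if (diff(range(cv_err)) < 1e-15) {
    # flat CV surface: check whether every candidate collapses to the empty
    # model; if so warn and return the largest penalty (most conservative)
    i_big <- which(grid$lambda1 == max(grid$lambda1) &
                     grid$lambda2 == max(grid$lambda2))[1L]
    m_big <- fit_enet(x, lambda1 = grid$lambda1[i_big],
                      lambda2 = grid$lambda2[i_big],
                      tol = tol, max_iter = max_iter)
    if (all(m_big$beta_std == 0)) {
      warning("all grid points give the empty model; returning the largest penalty",
              call. = FALSE)
      out <- list(lambda1 = grid$lambda1[i_big], lambda2 = grid$lambda2[i_big],
                  model = m_big, cv = grid, folds = folds, seed = seed)
      class(out) <- "enet_grid"
      return(out)
    }
  }
  best <- min(cv_err)
  cand <- which(cv_err <= best + 1e-12)
  cand <- cand[order(grid$lambda1[cand], grid$lambda2[cand])]
  i_best <- cand[1L]
  model <- fit_enet(x, lambda1 = grid$lambda1[i_best],
                    lambda2 = grid$lambda2[i_best],
                    tol = tol, max_iter = max_iter)
  out <- list(lambda1 = grid$lambda1[i_best], lambda2 = grid$lambda2[i_best],
              model = model, cv = grid, folds = folds, seed = seed)
  class(out) <- "enet_grid"
  out
}

#' @export
print.enet_grid <- function(x, ...) {
  cat(sprintf("<enet_grid> %d grid points, %d-fold CV\n", nrow(x$cv), x$folds))
  cat(sprintf("  selected: lambda1 = %.4g, lambda2 = %.4g (CV RMSEP %.4g)\n",
              x$lambda1, x$lambda2, min(x$cv$cv_rmsep)))
  invisible(x)
}

# Fitter factory for cross-validation and selectors.
enet_fitter <- function(lambda1, lambda2, tol = 1e-8, max_iter = 1e5) {
  force(lambda1); force(lambda2); force(tol); force(max_iter)
  function(train) fit_enet(train, lambda1 = lambda1, lambda2 = lambda2,
                           tol = tol, max_iter = max_iter)
}

pls_fitter <- function(h) {
  force(h)
  function(train) fit_pls(train, h = h)
}
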
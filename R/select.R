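# Coefficient-based variable selection: Enet-BETA (the main procedure),
# PLS-BETA and forward stepwise selection with BIC. All return a "varsel"
# object.

new_varsel <- function(method, ranking, rmsep_curve, i_star, i_ht, selected,
                       final_model, labels, details = list()) {
  structure(list(method = method,
                 ranking = as.integer(ranking),
                 rmsep_curve = rmsep_curve,
                 i_star = as.integer(i_star),
                 i_ht = as.integer(i_ht),
                 selected = as.integer(selected),
                 channel_labels = labels,
                 final_model = final_model,
                 details = details),
            class = "varsel")
}

#' Rank channels by coefficient magnitude
#'
#' Orders the channel indices by decreasing absolute standardized
#' coefficient; ties are broken by ascending channel index, so the ranking is
#' deterministic (an all-zero coefficient vector yields `1:p`).
#'
#' @param model a `"calib_model"`.
#' @return An integer permutation of `1:p`.
#' @export
rank_by_coefficient <- function(model) {
  stopifnot(inherits(model, "calib_model"))
  b <- model$beta_std
  order(-abs(b), seq_along(b))
}

# Shortest prefix of the |beta|-descending ranking whose coefficient
# sub-vector has L2 norm ratio > alpha against the full vector (the full
# prefix qualifies at the >= boundary, so selection always terminates).
prefix_by_norm <- function(beta, ranking, alpha) {
  check_prob(alpha, "alpha")
  total <- sqrt(sum(beta^2))
  ratio <- sqrt(cumsum(beta[ranking]^2)) / total
  i <- which(ratio > alpha)[1L]
  if (is.na(i)) i <- length(beta)
  as.integer(i)
}

#' Relax a subset size by the RMSEP confidence-ratio rule
#'
#' Given the RMSEP curve over subset sizes and its minimizer `i_star`,
#' returns the smallest size `i <= i_star` whose RMSEP is within a factor
#' `1/conf` of the best: `curve[i_star] / curve[i] >= conf`. With `conf`
#' close to 1 only (near-)optimal sizes qualify; lowering `conf` trades
#' prediction accuracy for sparsity. `i_star` itself always qualifies
#' (ratio 1), so the rule never increases the size. Zero curve values are
#' handled by defining the ratio as 1 when both entries are zero and 0
#' otherwise.
#'
#' @param curve numeric vector of RMSEP values indexed by subset size.
#' @param i_star index of the curve minimum.
#' @param conf confidence ratio in (0, 1], default 0.9.
#' @return The relaxed subset size (integer `<= i_star`).
#' @examples
#' ht_reduce(c(0.6, 0.5, 0.45), i_star = 3, conf = 0.9) # 2
#' @export
ht_reduce <- function(curve, i_star, conf = 0.9) {
  curve <- as.numeric(curve)
  if (!length(curve) || any(!is.finite(curve)) || any(curve < 0)) {
    stop_bad_arg("`curve` must be a nonempty vector of finite nonnegative values")
  }
  if (!is_count(i_star) || i_star < 1L || i_star > length(curve)) {
    stop_bad_arg("`i_star` must index into the curve")
  }
  check_prob(conf, "conf")
  best <- curve[i_star]
  for (i in seq_len(i_star)) {
    ratio <- if (curve[i] > 0) best / curve[i] else if (best == 0) 1 else 0
    if (ratio >= conf) return(as.integer(i))
  }
  as.integer(i_star) # unreachable: i_star has ratio 1
}

#' Enet-BETA variable selection
#'
#' The full procedure for high-collinearity spectrum data:
#' \enumerate{
#'   \item standardize the training data and fit the elastic net on all `p`
#'     channels (inside [fit_enet()]);
#'   \item rank channels by decreasing absolute coefficient;
#'   \item for each prefix of the ranking (sizes `1..m`, where `m` is the
#'     elastic-net support size; `full_path = TRUE` extends to `1..p`),
#'     refit the elastic net with the same penalties on the prefix and record
#'     its RMSEP under the evaluation policy;
#'   \item take `i_star`, the size minimizing the RMSEP curve (smallest size
#'     on ties);
#'   \item relax to `i_ht <= i_star` with the confidence-ratio rule
#'     ([ht_reduce()], default `conf = 0.9`);
#'   \item refit on the first `i_ht` ranked channels.
#' }
#'
#' The default evaluation policy (`eval = "cv"`) scores each prefix by K-fold
#' cross-validated RMSEP on the training set, so no held-out information
#' enters the selection; `eval = "holdout"` scores on a supplied held-out
#' set instead, mirroring workflows that report test-set RMSEP curves.
#'
#' @param x a [spectra] training dataset.
#' @param lambda1,lambda2 elastic-net penalties (see [fit_enet()]); tune with
#'   [enet_grid_search()] if unknown.
#' @param conf confidence ratio of the relaxation step, in (0, 1].
#' @param eval evaluation policy for the RMSEP curve: `"cv"` (default) or
#'   `"holdout"`.
#' @param holdout a [spectra] dataset with the same channels, required for
#'   `eval = "holdout"`.
#' @param folds,seed cross-validation folds and seed (policy `"cv"`).
#' @param full_path evaluate all `p` prefix sizes instead of stopping at the
#'   elastic-net support size.
#' @param tol,max_iter passed to [fit_enet()].
#' @return A `"varsel"` object: `ranking`, `rmsep_curve`, `i_star`, `i_ht`,
#'   `selected` (the first `i_ht` ranked channel indices), `final_model`.
#' @examples
#' sim <- simulate_spectra(n = 120, p = 30, k_true = 4, seed = 3)
#' sel <- enet_beta(sim$data, lambda1 = 30, lambda2 = 5, folds = 5)
#' sel$selected
#' @export
enet_beta <- function(x, lambda1, lambda2, conf = 0.9,
                      eval = c("cv", "holdout"), holdout = NULL,
                      folds = 9L, seed = 1L, full_path = FALSE,
                      tol = 1e-8, max_iter = 1e5) {
  stopifnot(inherits(x, "spectra"))
  eval <- match.arg(eval)
  check_prob(conf, "conf")
  if (eval == "holdout" && !inherits(holdout, "spectra")) {
    stop_bad_arg("`eval = \"holdout\"` requires a spectra `holdout` dataset")
  }
  p <- ncol(x$X)
  full <- fit_enet(x, lambda1 = lambda1, lambda2 = lambda2,
                   tol = tol, max_iter = max_iter)
  ranking <- rank_by_coefficient(full)
  m <- sum(full$beta_std != 0)
  if (m == 0L) {
    stop_bad_arg("penalty too large: all elastic-net coefficients are zero, ",
                 "no ranking signal")
  }
  sizes <- seq_len(if (full_path) p else m)
  fitter <- enet_fitter(lambda1, lambda2, tol, max_iter)
  curve <- vapply(sizes, function(i) {
    sub_idx <- ranking[seq_len(i)]
    sub <- x[, sub_idx]
    val <- if (eval == "cv") {
      as.numeric(kfold_cv(sub, fitter, folds = folds, seed = seed))
    } else {
      mod <- fitter(sub)
      rmsep(holdout$y, predict(mod, holdout$X[, sub_idx, drop = FALSE]))
    }
    if (!is.finite(val)) {
      stop_bad_arg("non-finite RMSEP at prefix size ", i)
    }
    val
  }, numeric(1))
  i_star <- which.min(curve) # first minimum = smallest size on ties
  i_ht <- ht_reduce(curve, i_star, conf)
  selected <- ranking[seq_len(i_ht)]
  final <- fit_enet(x[, selected], lambda1 = lambda1, lambda2 = lambda2,
                    tol = tol, max_iter = max_iter)
  new_varsel("enet-beta", ranking, curve, i_star, i_ht, selected, final,
             x$channel_labels,
             details = list(lambda1 = lambda1, lambda2 = lambda2, conf = conf,
                            eval = eval, folds = folds, seed = seed,
                            support_size = m, full_path = full_path))
}

#' PLS-BETA variable selection
#'
#' Fits PLS with `h` components on all channels, ranks channels by decreasing
#' absolute coefficient and keeps the shortest prefix whose coefficient
#' sub-vector carries more than a fraction `alpha` of the L2 norm of the full
#' coefficient vector. The final model is PLS refit on the selected channels.
#'
#' @inheritParams enet_beta
#' @param h number of PLS components for the full fit.
#' @param alpha norm-ratio threshold in (0, 1]; `alpha = 1` keeps all
#'   channels (the ratio reaches 1 only at the full prefix).
#' @return A `"varsel"` object; the norm-ratio curve is stored in
#'   `$details$norm_ratio`.
#' @export
pls_beta <- function(x, h, alpha = 0.9) {
  stopifnot(inherits(x, "spectra"))
  full <- fit_pls(x, h = h)
  ranking <- rank_by_coefficient(full)
  i_sel <- prefix_by_norm(full$beta_std, ranking, alpha)
  selected <- ranking[seq_len(i_sel)]
  h_final <- min(full$hyperparams$h, length(selected))
  final <- fit_pls(x[, selected], h = h_final)
  ratio <- sqrt(cumsum(full$beta_std[ranking]^2)) / sqrt(sum(full$beta_std^2))
  new_varsel("pls-beta", ranking, NULL, i_sel, i_sel, selected, final,
             x$channel_labels,
             details = list(h = full$hyperparams$h, alpha = alpha,
                            norm_ratio = ratio))
}

# Intercept-only calibration model (empty selection).
null_model <- function(y) {
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy <= 0) sdy <- 1
  stats <- new_std_stats(numeric(0), numeric(0), mean(y), sdy)
  model <- new_calib_model(numeric(0), stats, "OLS", list(), character(0),
                           extra = list(n_train = length(y)))
  model$fitted_raw <- rep(mean(y), length(y))
  model$y_train <- y
  model
}

#' Forward stepwise selection with BIC
#'
#' Greedy forward path on the standardized training data: starting from the
#' intercept-only model, each step adds the channel giving the largest
#' decrease in the OLS residual sum of squares (computed exactly via
#' Gram-Schmidt orthogonalization against the active set; ties go to the
#' smaller channel index). The path is capped at `min(p, n - 2)` so the OLS
#' fit with an intercept stays well-posed. The final size is the BIC argmin
#' along the path (size 0, the intercept-only model, is a valid winner on
#' pure-noise responses) and the final model is OLS on that subset.
#'
#' @param x a [spectra] training dataset with `n >= 3`.
#' @return A `"varsel"` object; `ranking` is the greedy addition order (length
#'   = path length, not necessarily `p`), and `$details` holds the SSR and
#'   BIC paths (indexed by size 0, 1, 2, ...).
#' @export
fss_bic <- function(x) {
  stopifnot(inherits(x, "spectra"))
  n <- nrow(x$X)
  p <- ncol(x$X)
  if (n < 3L) stop_bad_arg("forward stepwise selection needs n >= 3")
  st <- standardize(x)
  Z <- st$data$X
  r <- st$data$y
  kmax <- min(p, n - 2L)
  remaining <- seq_len(p)
  path <- integer(0)
  ssr_path <- sum(r^2) # size 0
  for (k in seq_len(kmax)) {
    Zr <- Z[, remaining, drop = FALSE]
    znorm2 <- colSums(Zr^2)
    zr <- drop(crossprod(Zr, r))
    gain <- ifelse(znorm2 > 1e-10, zr^2 / znorm2, -Inf)
    if (!any(is.finite(gain))) break # active set spans the remaining columns
    j_local <- which.max(gain) # first max = smallest channel index on ties
    j <- remaining[j_local]
    q <- Zr[, j_local] / sqrt(znorm2[j_local])
    r <- r - q * sum(q * r)
    remaining <- remaining[-j_local]
    if (length(remaining)) {
      Z[, remaining] <- Z[, remaining, drop = FALSE] -
        q %*% crossprod(q, Z[, remaining, drop = FALSE])
    }
    path <- c(path, j)
    ssr_path <- c(ssr_path, sum(r^2))
  }
  sizes <- seq_along(ssr_path) - 1L
  bic_path <- vapply(seq_along(sizes), function(i) {
    suppressWarnings(aic_bic(ssr_path[i], n, sizes[i])$bic)
  }, numeric(1))
  k_best <- sizes[which.min(bic_path)]
  selected <- path[seq_len(k_best)]
  final <- if (k_best == 0L) null_model(x$y) else fit_ols(x[, selected])
  new_varsel("fss", path, NULL, k_best, k_best, selected, final,
             x$channel_labels,
             details = list(ssr_path = ssr_path, bic_path = bic_path,
                            sizes = sizes))
}

#' @export
print.varsel <- function(x, ...) {
  cat(sprintf("<varsel> method: %s | %d of %d channels selected\n",
              x$method, length(x$selected), length(x$channel_labels)))
  if (!is.null(x$rmsep_curve)) {
    cat(sprintf("  RMSEP curve over %d sizes: min %.4g at i* = %d, relaxed i_HT = %d\n",
                length(x$rmsep_curve), min(x$rmsep_curve), x$i_star, x$i_ht))
  }
  sel <- x$channel_labels[x$selected]
  cat("  selected:", paste(utils::head(sel, 10L), collapse = ", "),
      if (length(sel) > 10L) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.varsel <- function(object, ...) {
  out <- list(method = object$method,
              p = length(object$channel_labels),
              novs = length(object$selected),
              i_star = object$i_star,
              i_ht = object$i_ht,
              selected_labels = object$channel_labels[object$selected],
              final_model = summary(object$final_model))
  class(out) <- "summary.varsel"
  out
}

#' @export
print.summary.varsel <- function(x, ...) {
  cat(sprintf("Variable selection (%s): %d of %d channels\n",
              x$method, x$novs, x$p))
  cat(sprintf("  i* = %d, i_HT = %d\n", x$i_star, x$i_ht))
  cat("  selected:", paste(x$selected_labels, collapse = ", "), "\n")
  print(x$final_model)
  invisible(x)
}

#' @export
coef.varsel <- function(object, ...) coef(object$final_model, ...)

#' Predict from a variable-selection result
#'
#' Subsets the new spectra to the selected channels and predicts with the
#' refit final model.
#'
#' @param object a `"varsel"` object.
#' @param newdata a [spectra] object or matrix with all original channels.
#' @param ... unused.
#' @return Numeric predictions in raw `y` units.
#' @export
predict.varsel <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra")) newdata$X else as.matrix(newdata)
  if (ncol(X) != length(object$channel_labels)) {
    stop_bad_arg("newdata has ", ncol(X), " channels; expected ",
                 length(object$channel_labels))
  }
  if (length(object$selected) == 0L) {
    return(predict(object$final_model, X[, 0, drop = FALSE]))
  }
  predict(object$final_model, X[, object$selected, drop = FALSE])
}

#' Plot a variable-selection result
#'
#' Draws the RMSEP curve over subset sizes with `i_star` and `i_ht` marked,
#' or (when no curve exists, e.g. PLS-BETA/FSS) the coefficient stems of the
#' final model.
#'
#' @param x a `"varsel"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.varsel <- function(x, ...) {
  if (!is.null(x$rmsep_curve)) {
    sizes <- seq_along(x$rmsep_curve)
    graphics::plot(sizes, x$rmsep_curve, type = "b", pch = 16, cex = 0.7,
                   xlab = "subset size", ylab = "RMSEP",
                   main = paste(x$method, "RMSEP curve"), ...)
    graphics::abline(v = x$i_star, lty = 2)
    graphics::abline(v = x$i_ht, lty = 3)
    graphics::legend("topright", legend = c("i*", "i_HT"), lty = c(2, 3),
                     bty = "n")
  } else {
    plot(x$final_model, ...)
  }
  invisible(x)
}
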
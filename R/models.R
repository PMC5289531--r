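# Calibration models: OLS, NIPALS-PLS and the elastic net all return a
# "calib_model" holding coefficients on the standardized scale together with
# the standardization statistics, so predictions can be served on the raw
# concentration scale through either pathway (standardize-predict-revert, or
# beta_raw + intercept_raw directly).

# Resolve the (x, y) fitting interface: x may be a spectra dataset (then it is
# standardized internally, unless standardize = FALSE) or a plain numeric
# matrix with an explicit y (then standardize = FALSE means "use as is",
# e.g. for pre-centred orthonormal designs).
resolve_training <- function(x, y, standardize) {
  if (inherits(x, "spectra")) {
    labels <- x$channel_labels
    if (standardize) {
      st <- standardize(x)
      list(Xs = st$data$X, ys = st$data$y, stats = st$stats, labels = labels,
           y_raw = x$y)
    } else {
      list(Xs = x$X, ys = x$y, stats = identity_stats(ncol(x$X)),
           labels = labels, y_raw = x$y)
    }
  } else {
    X <- as.matrix(x)
    if (is.null(y)) stop_bad_arg("`y` is required when `x` is a matrix")
    y <- as.numeric(y)
    if (length(y) != nrow(X)) stop_bad_arg("length(y) must equal nrow(x)")
    labels <- colnames(X)
    if (is.null(labels)) labels <- paste0("v", seq_len(ncol(X)))
    if (standardize) {
      ds <- spectra(X, y, channel_labels = labels)
      st <- standardize(ds)
      list(Xs = st$data$X, ys = st$data$y, stats = st$stats, labels = labels,
           y_raw = y)
    } else {
      list(Xs = X, ys = y, stats = identity_stats(ncol(X)), labels = labels,
           y_raw = y)
    }
  }
}

new_calib_model <- function(beta_std, stats, method, hyperparams, labels,
                            extra = list()) {
  beta_std <- as.numeric(beta_std)
  beta_raw <- if (length(beta_std)) {
    stats$y_scale * beta_std / stats$x_scale
  } else {
    numeric(0)
  }
  intercept_raw <- stats$y_mean - sum(beta_raw * stats$x_mean)
  obj <- c(list(beta_std = beta_std, beta_raw = beta_raw,
                intercept_raw = intercept_raw, method = method,
                hyperparams = hyperparams, stats = stats,
                channel_labels = labels),
           extra)
  class(obj) <- "calib_model"
  obj
}

#' Ordinary least squares calibration
#'
#' Fits OLS on the standardized scale (both `X` and `y` centred and scaled to
#' unit sample sd, statistics estimated on the training data). Rank-deficient
#' designs are rejected unless `pseudo_inverse = TRUE`, in which case the
#' minimum-norm least-squares solution (Moore-Penrose) is returned.
#'
#' @param x a [spectra] dataset, or a numeric matrix (then `y` is required).
#' @param y numeric response when `x` is a matrix.
#' @param standardize logical; standardize internally (default). Set to
#'   `FALSE` only for data already on the fitting scale.
#' @param pseudo_inverse allow rank-deficient designs via the pseudo-inverse.
#' @return A `"calib_model"` with `method = "OLS"`.
#' @export
fit_ols <- function(x, y = NULL, standardize = TRUE, pseudo_inverse = FALSE) {
  tr <- resolve_training(x, y, standardize)
  p <- ncol(tr$Xs)
  qrX <- qr(tr$Xs)
  if (qrX$rank < p) {
    if (!pseudo_inverse) {
      stop_bad_arg("design is rank-deficient (rank ", qrX$rank, " < p = ", p,
                   "); set pseudo_inverse = TRUE for the minimum-norm solution")
    }
    beta <- drop(MASS::ginv(tr$Xs) %*% tr$ys)
  } else {
    beta <- qr.coef(qrX, tr$ys)
  }
  model <- new_calib_model(beta, tr$stats, "OLS", list(), tr$labels,
                           extra = list(n_train = nrow(tr$Xs)))
  model$fitted_raw <- predict(model, if (inherits(x, "spectra")) x$X else as.matrix(x))
  model$y_train <- tr$y_raw
  model
}

#' Partial least squares calibration (NIPALS)
#'
#' Single-response PLS1 via the NIPALS recursion with X-deflation: at each
#' component the weight vector is the (normalized) covariance `X'y`, scores
#' `t = Xw` are extracted, and `X`, `y` are deflated by the rank-one fit. The
#' coefficient vector is `W (P'W)^{-1} q`. If the response residual is
#' exhausted before `h` components (numerically zero weight), extraction
#' stops early with a warning and the achieved number of components is kept.
#'
#' @inheritParams fit_ols
#' @param h number of latent components, `1 <= h <= min(n - 1, p)`.
#' @return A `"calib_model"` with `method = "PLS"`; the decomposition (scores
#'   `T`, loadings `P`, weights `W`, y-loadings `q`, achieved `h`) is stored
#'   in `$decomposition`.
#' @export
fit_pls <- function(x, y = NULL, h, standardize = TRUE) {
  tr <- resolve_training(x, y, standardize)
  n <- nrow(tr$Xs)
  p <- ncol(tr$Xs)
  if (!is_count(h) || h < 1L || h > min(n - 1L, p)) {
    stop_bad_arg("`h` must be an integer in 1..min(n - 1, p) = ",
                 min(n - 1L, p))
  }
  h <- as.integer(h)
  Xd <- tr$Xs
  yd <- tr$ys
  W <- matrix(0, p, h)
  P <- matrix(0, p, h)
  Tm <- matrix(0, n, h)
  q <- numeric(h)
  w0 <- sqrt(sum(crossprod(tr$Xs, tr$ys)^2))
  achieved <- 0L
  for (l in seq_len(h)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw < 1e-12 * max(w0, 1)) {
      warning("response residual exhausted after ", achieved,
              " of ", h, " components; returning the achieved decomposition",
              call. = FALSE)
      break
    }
    w <- w / nw
    t_l <- drop(Xd %*% w)
    tt <- sum(t_l^2)
    if (!is.finite(tt) || tt < 1e-24) {
      warning("score variance exhausted after ", achieved,
              " of ", h, " components; returning the achieved decomposition",
              call. = FALSE)
      break
    }
    p_l <- drop(crossprod(Xd, t_l)) / tt
    q_l <- sum(yd * t_l) / tt
    Xd <- Xd - tcrossprod(t_l, p_l)
    yd <- yd - t_l * q_l
    W[, l] <- w
    P[, l] <- p_l
    Tm[, l] <- t_l
    q[l] <- q_l
    achieved <- l
  }
  if (achieved == 0L) stop_bad_arg("no PLS component could be extracted")
  W <- W[, seq_len(achieved), drop = FALSE]
  P <- P[, seq_len(achieved), drop = FALSE]
  Tm <- Tm[, seq_len(achieved), drop = FALSE]
  q <- q[seq_len(achieved)]
  beta <- drop(W %*% solve(crossprod(P, W), q))
  model <- new_calib_model(beta, tr$stats, "PLS", list(h = achieved),
                           tr$labels,
                           extra = list(
                             n_train = nrow(tr$Xs),
                             decomposition = list(T = Tm, P = P, W = W, q = q,
                                                  h = achieved,
                                                  h_requested = h)))
  model$fitted_raw <- predict(model, if (inherits(x, "spectra")) x$X else as.matrix(x))
  model$y_train <- tr$y_raw
  model
}

#' Predict from a calibration model
#'
#' Applies the model's stored training standardization to new raw-scale
#' spectra, multiplies by the standardized coefficients and de-standardizes
#' the result, so predictions are in the original concentration units.
#'
#' @param object a `"calib_model"`.
#' @param newdata a [spectra] object or numeric matrix with the model's `p`
#'   channels (raw scale).
#' @param ... unused.
#' @return Numeric vector of predictions in raw `y` units.
#' @export
predict.calib_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra")) newdata$X else as.matrix(newdata)
  p <- length(object$beta_raw)
  if (p == 0L) return(rep(object$intercept_raw, nrow(X)))
  if (ncol(X) != p) {
    stop_bad_arg("newdata has ", ncol(X), " channels; model expects ", p)
  }
  drop(X %*% object$beta_raw) + object$intercept_raw
}

#' @export
coef.calib_model <- function(object, scale = c("raw", "std"), ...) {
  scale <- match.arg(scale)
  if (scale == "std") {
    stats::setNames(object$beta_std, object$channel_labels)
  } else {
    c("(Intercept)" = object$intercept_raw,
      stats::setNames(object$beta_raw, object$channel_labels))
  }
}

#' @export
residuals.calib_model <- function(object, ...) {
  if (is.null(object$fitted_raw)) stop_bad_arg("model stores no training fit")
  object$y_train - object$fitted_raw
}

#' @export
fitted.calib_model <- function(object, ...) object$fitted_raw

#' @export
print.calib_model <- function(x, ...) {
  nnz <- sum(x$beta_std != 0)
  hp <- if (length(x$hyperparams)) {
    paste(names(x$hyperparams),
          vapply(x$hyperparams, function(v) format(v, digits = 4L), ""),
          sep = " = ", collapse = ", ")
  } else "none"
  cat(sprintf("<calib_model> method: %s | channels: %d | nonzero: %d\n",
              x$method, length(x$beta_std), nnz))
  cat("  hyperparameters:", hp, "\n")
  invisible(x)
}

#' @export
summary.calib_model <- function(object, ...) {
  out <- list(method = object$method,
              p = length(object$beta_std),
              nonzero = sum(object$beta_std != 0),
              hyperparams = object$hyperparams)
  if (!is.null(object$fitted_raw)) {
    out$rmsep_train <- rmsep(object$y_train, object$fitted_raw)
    out$r2_train <- r_squared(object$y_train, object$fitted_raw)
  }
  class(out) <- "summary.calib_model"
  out
}

#' @export
print.summary.calib_model <- function(x, ...) {
  cat(sprintf("Calibration model (%s): %d channels, %d nonzero coefficients\n",
              x$method, x$p, x$nonzero))
  if (!is.null(x$rmsep_train)) {
    cat(sprintf("  training RMSEP: %.4g   training R2: %.4f\n",
                x$rmsep_train, x$r2_train))
  }
  invisible(x)
}

#' Coefficient stem plot of a calibration model
#'
#' @param x a `"calib_model"`.
#' @param scale coefficient scale to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.calib_model <- function(x, scale = c("std", "raw"), ...) {
  scale <- match.arg(scale)
  b <- if (scale == "std") x$beta_std else x$beta_raw
  idx <- seq_along(b)
  graphics::plot(idx, b, type = "n", xlab = "channel",
                 ylab = paste0("coefficient (", scale, ")"),
                 main = paste(x$method, "coefficients"), ...)
  graphics::segments(idx, 0, idx, b)
  graphics::points(idx[b != 0], b[b != 0], pch = 16, cex = 0.6)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
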
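# Evaluation criteria for calibration models. All are computed on the
# original concentration scale of y.

#' Root-mean-square error of prediction
#'
#' `sqrt(sum((y - yhat)^2) / n)`. With `root = FALSE` the un-rooted mean
#' squared error `sum((y - yhat)^2) / n` is returned instead, for
#' comparability with reports that quote the plain mean square.
#'
#' @param y observed response.
#' @param yhat predicted response, same length.
#' @param root take the square root (default `TRUE`).
#' @return Nonnegative scalar in `y` units (squared units if `root = FALSE`).
#' @examples
#' rmsep(c(1, 2, 3), c(1, 2, 5)) # sqrt(4/3)
#' @export
rmsep <- function(y, yhat, root = TRUE) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) == 0L) stop_bad_arg("empty response")
  if (length(y) != length(yhat)) {
    stop_bad_arg("length mismatch: ", length(y), " vs ", length(yhat))
  }
  mse <- sum((y - yhat)^2) / length(y)
  if (root) sqrt(mse) else mse
}

#' Normalized mean square error
#'
#' `sum((y - yhat)^2) / sum(y^2)`: the squared prediction error scaled by the
#' raw sum of squares of the response. Unlike R-squared it is not invariant
#' to a common shift of `y` and `yhat`.
#'
#' @inheritParams rmsep
#' @return Nonnegative unitless scalar.
#' @export
nmse <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) == 0L) stop_bad_arg("empty response")
  if (length(y) != length(yhat)) {
    stop_bad_arg("length mismatch: ", length(y), " vs ", length(yhat))
  }
  ss <- sum(y^2)
  if (ss <= 0) stop_bad_arg("sum(y^2) must be positive for NMSE")
  sum((y - yhat)^2) / ss
}

#' Coefficient of determination
#'
#' `1 - SSR/SST` with `SSR = sum((y - yhat)^2)` and
#' `SST = sum((y - mean(y))^2)`.
#'
#' @inheritParams rmsep
#' @return Scalar `<= 1` (negative when predictions are worse than the mean).
#' @export
r_squared <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) == 0L) stop_bad_arg("empty response")
  if (length(y) != length(yhat)) {
    stop_bad_arg("length mismatch: ", length(y), " vs ", length(yhat))
  }
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop_bad_arg("constant y: SST = 0, R-squared undefined")
  1 - sum((y - yhat)^2) / sst
}

#' AIC and BIC from a Gaussian residual sum of squares
#'
#' Profiles the Gaussian error variance out of the likelihood and drops
#' additive constants shared across compared models, giving
#' `AIC = n log(SSR/n) + 2 k` and `BIC = n log(SSR/n) + k log(n)` where `k`
#' is the number of selected variables. Only differences between models fit
#' to the *same* data are meaningful. An SSR below the variance floor is
#' clamped (with a warning) so interpolating fits do not produce `-Inf`.
#'
#' @param ssr residual sum of squares (nonnegative).
#' @param n sample count.
#' @param k number of selected variables.
#' @param var_floor lower clamp on `SSR/n`.
#' @return A list with elements `aic` and `bic`.
#' @examples
#' aic_bic(ssr = 20, n = 20, k = 3) # aic = 6, bic = 3 log(20)
#' @export
aic_bic <- function(ssr, n, k, var_floor = 1e-12) {
  if (!is.numeric(ssr) || length(ssr) != 1L || ssr < 0) {
    stop_bad_arg("`ssr` must be a single nonnegative number")
  }
  if (!is_count(n) || n < 1) stop_bad_arg("`n` must be a positive integer")
  if (!is_count(k) || k < 0) stop_bad_arg("`k` must be a nonnegative integer")
  msr <- ssr / n
  if (msr < var_floor) {
    warning("SSR/n below variance floor (", var_floor, "); clamped",
            call. = FALSE)
    msr <- var_floor
  }
  ll <- n * log(msr)
  list(aic = ll + 2 * k, bic = ll + k * log(n))
}

# Seeded contiguous-after-shuffle fold assignment; every fold nonempty.
cv_folds <- function(n, K, seed) {
  if (!is_count(K) || K < 2L || K > n) {
    stop_bad_arg("`folds` must be an integer in 2..n")
  }
  ord <- with_seed(seed, sample.int(n))
  bounds <- floor(seq(0, n, length.out = K + 1))
  lapply(seq_len(K), function(k) ord[(bounds[k] + 1):bounds[k + 1]])
}

#' K-fold cross-validated RMSEP
#'
#' Partitions the samples into `folds` contiguous blocks of a seeded shuffle;
#' for each fold the supplied fitter is trained on the remaining samples
#' (fitters standardize internally, so per-fold statistics never see the
#' held-out fold) and RMSEP is computed on the held-out fold on the raw `y`
#' scale. Returns the mean over folds, with the per-fold values attached as
#' attribute `"per_fold"`.
#'
#' @param ds a [spectra] dataset.
#' @param fitter function taking a training [spectra] and returning an object
#'   with a [predict()] method accepting a raw-scale matrix.
#' @param folds number of folds `K`, `2 <= K <= n` (`K = n` is leave-one-out).
#' @param seed integer seed for the fold partition.
#' @return Mean cross-validated RMSEP (scalar).
#' @export
kfold_cv <- function(ds, fitter, folds = 9L, seed = 1L) {
  stopifnot(inherits(ds, "spectra"), is.function(fitter))
  n <- nrow(ds$X)
  fold_idx <- cv_folds(n, folds, seed)
  per_fold <- vapply(fold_idx, function(idx) {
    model <- fitter(ds[-idx, ])
    rmsep(ds$y[idx], predict(model, ds$X[idx, , drop = FALSE]))
  }, numeric(1))
  structure(mean(per_fold), per_fold = per_fold)
}
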
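#' Simulate spectrum-like calibration data with planted sparse truth
#'
#' Generates a dataset emulating the regime of near-infrared calibration
#' problems: hundreds of smoothly varying, highly collinear channels, a small
#' quality-related channel subset and additive noise. The design is a mixture
#' of shared latent Gaussian peak profiles (random per-sample amplitudes on
#' many overlapping peaks along the channel axis, giving smooth
#' spectrum-shaped rows whose between-channel correlation decays with channel
#' distance, as overlapping absorbance bands do) and stationary AR(1) channel
#' noise with autocorrelation `rho`, so adjacent channels correlate at least
#' about `rho`. The response is `y = X %*% beta_true + eps`, with the
#' noise variance set so that `var(signal) / var(eps) = snr` on the generated
#' sample.
#'
#' The true support is clustered on contiguous channel pairs near peak
#' centres (constant sign within a pair, magnitudes uniform in 0.5-1.5),
#' which exercises the grouping effect of the elastic net the way real
#' absorbance bands do while keeping every support channel identifiable:
#' longer contiguous runs at this correlation level carry members whose
#' individual contribution no selection method could resolve.
#'
#' @param n number of samples (`>= 4`).
#' @param p number of channels.
#' @param k_true size of the true support (`<= p`).
#' @param rho target adjacent-channel correlation of the AR(1) noise
#'   component, in `[0, 1)`.
#' @param snr signal-to-noise variance ratio of the response (positive).
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @param n_peaks number of latent peak profiles.
#' @param peak_width Gaussian peak width in channels.
#' @param noise_sd_frac sd of the AR(1) channel noise as a fraction of the
#'   pooled signal sd.
#' @return A list with `data` (a [spectra]) and `truth` (class
#'   `"synthetic_truth"`: `support`, `beta_true`, `snr`, `peak_centers`,
#'   `seed`).
#' @examples
#' sim <- simulate_spectra(n = 50, p = 40, k_true = 4, seed = 1)
#' sim$truth$support
#' @export
simulate_spectra <- function(n = 400L, p = 100L, k_true = 10L, rho = 0.95,
                             snr = 50, seed = 1L,
                             n_peaks = max(4L, round(p / 3)),
                             peak_width = NULL,
                             noise_sd_frac = 0.5) {
  if (!is_count(n) || n < 4L) stop_bad_arg("`n` must be an integer >= 4")
  if (!is_count(p) || p < 2L) stop_bad_arg("`p` must be an integer >= 2")
  if (!is_count(k_true) || k_true < 1L || k_true > p) {
    stop_bad_arg("`k_true` must be an integer in 1..p")
  }
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1) {
    stop_bad_arg("`rho` must be in [0, 1)")
  }
  if (!is.numeric(snr) || length(snr) != 1L || !is.finite(snr) || snr <= 0) {
    stop_bad_arg("`snr` must be a positive number")
  }
  if (is.null(peak_width)) {
    # match the smooth component's adjacent-channel correlation to rho:
    # densely overlapping Gaussian peaks of width w give a squared-exponential
    # channel covariance with corr(d) ~ exp(-d^2 / (4 w^2)), so solve
    # exp(-1/(4 w^2)) = rho for w (floored for weak requested correlation)
    peak_width <- sqrt(1 / (4 * log(1 / max(rho, 0.6))))
  }
  with_seed(seed, {
    # latent smooth peaks
    centers <- seq(0.05, 0.95, length.out = n_peaks) * p +
      stats::runif(n_peaks, -p / (2 * n_peaks), p / (2 * n_peaks))
    S <- vapply(centers, function(c0) exp(-(seq_len(p) - c0)^2 /
                                            (2 * peak_width^2)),
                numeric(p)) # p x n_peaks
    A <- matrix(stats::rnorm(n * n_peaks), n, n_peaks)
    signal <- A %*% t(S)
    # AR(1) channel noise, stationary unit variance, autocorrelation rho
    E <- matrix(stats::rnorm(n * p), n, p)
    if (p > 1L && rho > 0) {
      for (j in 2:p) E[, j] <- rho * E[, j - 1] + sqrt(1 - rho^2) * E[, j]
    }
    tau <- noise_sd_frac * sqrt(mean(apply(signal, 2L, stats::var)))
    X <- signal + tau * E
    # clustered sparse truth near peak centres: contiguous pairs, the minimal
    # grouping unit -- longer runs at this correlation level would make the
    # individual member channels unidentifiable from data
    n_clusters <- max(1L, ceiling(k_true / 2))
    sizes <- rep(2L, n_clusters)
    if (k_true %% 2L == 1L) sizes[n_clusters] <- 1L
    anchor <- round(sort(sample(centers, n_clusters,
                                replace = n_clusters > n_peaks)))
    support <- integer(0)
    for (c_i in seq_len(n_clusters)) {
      start <- anchor[c_i] - sizes[c_i] %/% 2L
      start <- max(1L, min(start, p - sizes[c_i] + 1L))
      block <- seq.int(start, start + sizes[c_i] - 1L)
      # nudge right past any channel already used by an earlier cluster
      while (any(block %in% support) && max(block) < p) block <- block + 1L
      support <- union(support, block)
    }
    # top up if clamping/overlap lost channels
    if (length(support) < k_true) {
      free <- setdiff(seq_len(p), support)
      support <- c(support, free[seq_len(k_true - length(support))])
    }
    support <- sort(as.integer(support[seq_len(k_true)]))
    beta_true <- numeric(p)
    # one sign per contiguous run (an absorbance band contributes one way)
    runs <- split(support, cumsum(c(1L, diff(support) != 1L)))
    for (run in runs) {
      s <- sample(c(-1, 1), 1L)
      beta_true[run] <- s * stats::runif(length(run), 0.5, 1.5)
    }
    y_signal <- drop(X[, support, drop = FALSE] %*% beta_true[support])
    sd_eps <- stats::sd(y_signal) / sqrt(snr)
    y <- y_signal + stats::rnorm(n, 0, sd_eps)
    ds <- spectra(X, y, channel_labels = paste0("ch", seq_len(p)))
    truth <- structure(list(support = support, beta_true = beta_true,
                            snr = snr, peak_centers = centers, seed = seed),
                       class = "synthetic_truth")
    list(data = ds, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> support size %d, snr %.3g, seed %d\n",
              length(x$support), x$snr, x$seed))
  cat("  support:", paste(x$support, collapse = ", "), "\n")
  invisible(x)
}

#' Score support recovery of a selection against the planted truth
#'
#' @param selected integer vector of selected channel indices.
#' @param truth a `"synthetic_truth"` object from [simulate_spectra()].
#' @return A list with `sensitivity` (fraction of the true support selected)
#'   and `false_positives` (count of selected channels off the support).
#' @examples
#' tr <- structure(list(support = c(1, 2, 3)), class = "synthetic_truth")
#' score_recovery(c(2, 3, 9), tr)
#' @export
score_recovery <- function(selected, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  selected <- as.integer(selected)
  support <- truth$support
  list(sensitivity = length(intersect(selected, support)) / length(support),
       false_positives = length(setdiff(selected, support)))
}
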
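#' Spectra dataset
#'
#' Container for a multivariate calibration dataset: a numeric matrix `X` of
#' `n` spectra measured on `p` channels (wavelengths) and a single numeric
#' response `y` of length `n` (a reference concentration). Missing values are
#' rejected rather than imputed.
#'
#' @param X numeric matrix, `n` samples by `p` channels.
#' @param y numeric response vector of length `n`.
#' @param channel_labels optional character vector of `p` channel names
#'   (wavelengths); defaults to the column names of `X`, else `"v1"..."vp"`.
#' @param sample_ids optional character vector of `n` sample identifiers;
#'   auto-numbered when absent.
#'
#' @return An object of class `"spectra"`: a list with elements `X`, `y`,
#'   `channel_labels`, `sample_ids`.
#' @examples
#' ds <- spectra(matrix(rnorm(20), 5, 4), rnorm(5))
#' dim(ds)
#' @export
spectra <- function(X, y, channel_labels = NULL, sample_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop_bad_arg("a spectra dataset needs at least 2 samples, got ", n)
  if (p < 1L) stop_bad_arg("a spectra dataset needs at least 1 channel")
  if (length(y) != n) {
    stop_bad_arg("length(y) = ", length(y), " does not match nrow(X) = ", n)
  }
  if (any(!is.finite(X))) stop_bad_arg("X contains missing or non-finite values")
  if (any(!is.finite(y))) stop_bad_arg("y contains missing or non-finite values")
  if (is.null(channel_labels)) {
    channel_labels <- colnames(X)
    if (is.null(channel_labels)) channel_labels <- paste0("v", seq_len(p))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != p) {
    stop_bad_arg("channel_labels must have length p = ", p)
  }
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop_bad_arg("sample_ids must have length n = ", n)
  colnames(X) <- NULL
  rownames(X) <- NULL
  structure(list(X = X, y = y,
                 channel_labels = channel_labels,
                 sample_ids = sample_ids),
            class = "spectra")
}

#' @export
dim.spectra <- function(x) dim(x$X)

#' @export
print.spectra <- function(x, ...) {
  cat(sprintf("<spectra> %d samples x %d channels\n", nrow(x$X), ncol(x$X)))
  cat(sprintf("  y: mean %.4g, sd %.4g\n", mean(x$y), stats::sd(x$y)))
  cat("  channels:", paste(utils::head(x$channel_labels, 5L), collapse = ", "),
      if (ncol(x$X) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Subset a spectra dataset
#'
#' `ds[i, j]` keeps samples `i` and channels `j` (either may be missing).
#'
#' @param x a [spectra] object.
#' @param i sample index vector.
#' @param j channel index vector.
#' @return A [spectra] object.
#' @export
`[.spectra` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$X))
  if (missing(j)) j <- seq_len(ncol(x$X))
  spectra(x$X[i, j, drop = FALSE], x$y[i],
          channel_labels = x$channel_labels[j],
          sample_ids = x$sample_ids[i])
}

#' Read a spectra dataset from delimited text
#'
#' Reads a rectangular delimited table (CSV by default) holding one response
#' column and `p` numeric channel columns. Channel labels come from the
#' header row when present, otherwise `"v1"..."vp"`.
#'
#' @param path file path (UTF-8 text).
#' @param delimiter field separator, `","` by default (`"\t"` for TSV).
#' @param header logical; does the first row hold column names?
#' @param response response column, by name (requires a header) or by
#'   1-based column index.
#' @return A [spectra] object.
#' @export
read_spectra <- function(path, delimiter = ",", header = TRUE, response = 1L) {
  if (!file.exists(path)) stop_bad_arg("file not found: ", path)
  tab <- tryCatch(
    utils::read.table(path, sep = delimiter, header = header,
                      colClasses = "character", check.names = FALSE,
                      comment.char = "", quote = "\"",
                      fileEncoding = "UTF-8", stringsAsFactors = FALSE),
    error = function(e) stop_bad_arg("cannot parse ", path, ": ",
                                     conditionMessage(e)))
  if (nrow(tab) < 1L || ncol(tab) < 2L) {
    stop_bad_arg("table must have at least 1 row and 2 columns")
  }
  cols <- names(tab)
  if (is.character(response)) {
    if (!header) stop_bad_arg("response selected by name requires a header row")
    r_idx <- match(response, cols)
    if (is.na(r_idx)) {
      stop_bad_arg("response column '", response, "' not found; columns are: ",
                   paste(cols, collapse = ", "))
    }
  } else {
    r_idx <- as.integer(response)
    if (is.na(r_idx) || r_idx < 1L || r_idx > ncol(tab)) {
      stop_bad_arg("response column index ", response,
                   " out of range 1..", ncol(tab))
    }
  }
  num <- vector("list", ncol(tab))
  for (j in seq_along(tab)) {
    raw <- tab[[j]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad)) {
      stop_bad_arg("non-numeric value '", raw[bad[1L]], "' at row ", bad[1L],
                   ", column ", j, " (", cols[j], ")")
    }
    num[[j]] <- val
  }
  y <- num[[r_idx]]
  Xcols <- num[-r_idx]
  X <- do.call(cbind, Xcols)
  labels <- if (header) cols[-r_idx] else paste0("v", seq_len(ncol(X)))
  spectra(X, y, channel_labels = labels)
}

#' Write a spectra dataset as delimited text
#'
#' Inverse of [read_spectra()]: channels first (header = channel labels),
#' response last. Values are printed with 15 significant digits so a
#' read-back reproduces the dataset to full printed precision.
#'
#' @param ds a [spectra] object.
#' @param path output file path.
#' @param delimiter field separator.
#' @param response_label header name for the response column.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path, delimiter = ",", response_label = "response") {
  stopifnot(inherits(ds, "spectra"))
  out <- as.data.frame(ds$X)
  names(out) <- ds$channel_labels
  out[[response_label]] <- ds$y
  fmt <- as.data.frame(lapply(out, function(v) format(v, digits = 15L,
                                                      scientific = FALSE,
                                                      trim = TRUE)))
  names(fmt) <- names(out)
  utils::write.table(fmt, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Split a dataset into train and test subsets
#'
#' Draws a seeded random partition of the samples. The split is disjoint and
#' exhaustive and deterministic given `seed`.
#'
#' @param ds a [spectra] object.
#' @param test_fraction fraction of samples assigned to the test set,
#'   in (0, 1).
#' @param seed integer seed for the partition.
#' @return A list with components `train` and `test`, both [spectra] objects.
#' @export
split_spectra <- function(ds, test_fraction, seed = 1L) {
  stopifnot(inherits(ds, "spectra"))
  check_prob(test_fraction, "test_fraction")
  if (test_fraction >= 1) stop_bad_arg("`test_fraction` must be < 1")
  n <- nrow(ds$X)
  n_test <- round(n * test_fraction)
  if (n_test < 2L || (n - n_test) < 2L) {
    stop_bad_arg("degenerate split: train = ", n - n_test, ", test = ", n_test,
                 " (both need at least 2 samples)")
  }
  idx <- with_seed(seed, sample.int(n))
  test_idx <- sort(idx[seq_len(n_test)])
  train_idx <- sort(idx[-seq_len(n_test)])
  list(train = ds[train_idx, ], test = ds[test_idx, ])
}

#' Standardization statistics
#'
#' Per-channel means and sample standard deviations (denominator `n - 1`) of
#' `X`, and the mean and sd of `y`, estimated on a training dataset. The
#' transform is invertible; scales are strictly positive by construction.
#'
#' @param x_mean,x_scale numeric vectors of length `p`.
#' @param y_mean,y_scale scalars, `y_scale > 0`.
#' @return An object of class `"std_stats"`.
#' @keywords internal
new_std_stats <- function(x_mean, x_scale, y_mean, y_scale) {
  structure(list(x_mean = as.numeric(x_mean), x_scale = as.numeric(x_scale),
                 y_mean = as.numeric(y_mean), y_scale = as.numeric(y_scale)),
            class = "std_stats")
}

identity_stats <- function(p) new_std_stats(rep(0, p), rep(1, p), 0, 1)

#' Standardize a dataset to zero mean and unit variance
#'
#' Centres and scales every channel of `X` and the response `y` to zero mean
#' and unit sample standard deviation (denominator `n - 1`). Model fitting in
#' this package happens on the standardized scale; predictions and error
#' criteria are always reported back on the original concentration scale.
#'
#' @param ds a [spectra] object with at least 2 samples and no zero-variance
#'   channel.
#' @return A list with `data` (the standardized [spectra]) and `stats`
#'   (a `"std_stats"` object allowing exact inversion).
#' @examples
#' ds <- spectra(matrix(rnorm(40), 10, 4), rnorm(10))
#' st <- standardize(ds)
#' colMeans(st$data$X) # ~ 0
#' @export
standardize <- function(ds) {
  stopifnot(inherits(ds, "spectra"))
  n <- nrow(ds$X)
  if (n < 2L) stop_bad_arg("standardization needs at least 2 samples")
  x_mean <- colMeans(ds$X)
  x_scale <- apply(ds$X, 2L, stats::sd)
  dead <- which(!is.finite(x_scale) | x_scale <= 0)
  if (length(dead)) {
    stop_bad_arg("zero-variance channel(s): ",
                 paste(ds$channel_labels[dead], collapse = ", "))
  }
  y_mean <- mean(ds$y)
  y_scale <- stats::sd(ds$y)
  if (!is.finite(y_scale) || y_scale <= 0) {
    stop_bad_arg("response has zero variance; cannot standardize y")
  }
  stats <- new_std_stats(x_mean, x_scale, y_mean, y_scale)
  std <- apply_stats(stats, X = ds$X, y = ds$y)
  list(data = spectra(std$X, std$y, channel_labels = ds$channel_labels,
                      sample_ids = ds$sample_ids),
       stats = stats)
}

# Forward transform: raw -> standardized.
apply_stats <- function(stats, X = NULL, y = NULL) {
  out <- list()
  if (!is.null(X)) {
    out$X <- sweep(sweep(X, 2L, stats$x_mean, "-"), 2L, stats$x_scale, "/")
  }
  if (!is.null(y)) out$y <- (y - stats$y_mean) / stats$y_scale
  out
}

# Inverse transform: standardized -> raw.
revert_stats <- function(stats, X = NULL, y = NULL) {
  out <- list()
  if (!is.null(X)) {
    out$X <- sweep(sweep(X, 2L, stats$x_scale, "*"), 2L, stats$x_mean, "+")
  }
  if (!is.null(y)) out$y <- y * stats$y_scale + stats$y_mean
  out
}
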
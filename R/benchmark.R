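#' Benchmark the five selection methods on a train/test split
#'
#' Runs PLS (all channels), PLS-BETA, FSS with BIC, the elastic net, and
#' Enet-BETA with shared hyperparameters on a training set, and reports for
#' each method the number of selected variables (NOVS) and the standard
#' accuracy criteria: test RMSEP and NMSE, and the coefficient of
#' determination on the training and test sets. Hyperparameters left `NULL`
#' are tuned on the training data: the number of PLS components by K-fold
#' cross-validation over `1..h_max`, the elastic-net penalties by
#' [enet_grid_search()]. A method failure is recorded as an error row, not a
#' crash. Deterministic given `seed`.
#'
#' @param train,test [spectra] datasets with identical channels.
#' @param h number of PLS components, or `NULL` to tune by CV.
#' @param h_max largest component count tried when tuning `h`.
#' @param alpha PLS-BETA norm-ratio threshold.
#' @param lambda1,lambda2 elastic-net penalties, or `NULL` to tune by grid
#'   search.
#' @param conf Enet-BETA confidence ratio.
#' @param folds CV folds used throughout.
#' @param seed integer seed for all CV partitions.
#' @param eval Enet-BETA curve evaluation policy (`"cv"` or `"holdout"`; the
#'   holdout policy scores prefixes on `test`).
#' @return A `"benchmark_report"`: a data frame with columns `method`,
#'   `novs`, `rmsep_te`, `nmse_te`, `r2_tr`, `r2_te`, `error`, with the run
#'   configuration in `attr(, "meta")`.
#' @export
run_benchmark <- function(train, test, h = NULL, h_max = 15L, alpha = 0.9,
                          lambda1 = NULL, lambda2 = NULL, conf = 0.9,
                          folds = 9L, seed = 1L, eval = c("cv", "holdout")) {
  stopifnot(inherits(train, "spectra"), inherits(test, "spectra"))
  eval <- match.arg(eval)
  p <- ncol(train$X)
  if (ncol(test$X) != p ||
      !identical(train$channel_labels, test$channel_labels)) {
    stop_bad_arg("train and test must share the same channels")
  }
  if (is.null(h)) {
    hs <- seq_len(min(h_max, nrow(train$X) - 1L, p))
    cv_h <- vapply(hs, function(hh) {
      as.numeric(kfold_cv(train, pls_fitter(hh), folds = folds, seed = seed))
    }, numeric(1))
    h <- hs[which.min(cv_h)]
  }
  if (is.null(lambda1) || is.null(lambda2)) {
    gs <- enet_grid_search(train, folds = folds, seed = seed)
    lambda1 <- gs$lambda1
    lambda2 <- gs$lambda2
    enet_model <- gs$model
  } else {
    enet_model <- NULL
  }

  measure <- function(predict_fn, novs) {
    yhat_tr <- predict_fn(train$X)
    yhat_te <- predict_fn(test$X)
    data.frame(novs = novs,
               rmsep_te = rmsep(test$y, yhat_te),
               nmse_te = nmse(test$y, yhat_te),
               r2_tr = r_squared(train$y, yhat_tr),
               r2_te = r_squared(test$y, yhat_te),
               error = NA_character_,
               stringsAsFactors = FALSE)
  }
  error_row <- function(e) {
    data.frame(novs = NA_integer_, rmsep_te = NA_real_, nmse_te = NA_real_,
               r2_tr = NA_real_, r2_te = NA_real_,
               error = conditionMessage(e), stringsAsFactors = FALSE)
  }
  runs <- list(
    PLS = function() {
      m <- fit_pls(train, h = h)
      measure(function(X) predict(m, X), p)
    },
    `PLS-BETA` = function() {
      v <- pls_beta(train, h = h, alpha = alpha)
      measure(function(X) predict(v, X), length(v$selected))
    },
    FSS = function() {
      v <- fss_bic(train)
      measure(function(X) predict(v, X), length(v$selected))
    },
    Enet = function() {
      m <- if (is.null(enet_model)) {
        fit_enet(train, lambda1 = lambda1, lambda2 = lambda2)
      } else enet_model
      measure(function(X) predict(m, X), sum(m$beta_std != 0))
    },
    `Enet-BETA` = function() {
      v <- enet_beta(train, lambda1 = lambda1, lambda2 = lambda2, conf = conf,
                     eval = eval, holdout = if (eval == "holdout") test,
                     folds = folds, seed = seed)
      measure(function(X) predict(v, X), length(v$selected))
    }
  )
  rows <- lapply(names(runs), function(nm) {
    row <- tryCatch(runs[[nm]](), error = error_row)
    cbind(data.frame(method = nm, stringsAsFactors = FALSE), row)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "meta") <- list(seed = seed, folds = folds, h = h,
                               alpha = alpha, lambda1 = lambda1,
                               lambda2 = lambda2, conf = conf, eval = eval,
                               n_train = nrow(train$X), n_test = nrow(test$X),
                               p = p)
  class(report) <- c("benchmark_report", "data.frame")
  report
}

#' @export
print.benchmark_report <- function(x, digits = 4L, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Benchmark: %d train / %d test samples, %d channels (seed %d)\n",
              meta$n_train, meta$n_test, meta$p, meta$seed))
  cat(sprintf("  h = %d, alpha = %.3g, lambda1 = %.4g, lambda2 = %.4g, conf = %.2f, %d-fold CV\n",
              meta$h, meta$alpha, meta$lambda1, meta$lambda2, meta$conf,
              meta$folds))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Render a benchmark report as a Markdown table
#'
#' @param report a `"benchmark_report"`.
#' @param digits significant digits for the numeric columns.
#' @return A single character string (Markdown).
#' @export
report_markdown <- function(report, digits = 6L) {
  stopifnot(inherits(report, "benchmark_report"))
  df <- as.data.frame(report)
  cols <- c("method", "novs", "rmsep_te", "nmse_te", "r2_tr", "r2_te")
  hdr <- c("Method", "NOVS", "RMSEP_te", "NMSE_te", "R2_tr", "R2_te")
  fmt <- function(v) {
    ifelse(is.na(v), "NA",
           ifelse(v == round(v) & abs(v) < 1e6, format(v, scientific = FALSE),
                  format(signif(v, digits), scientific = FALSE)))
  }
  body <- apply(df[cols], 1L, function(row) {
    vals <- c(row[["method"]],
              vapply(cols[-1], function(cn) fmt(as.numeric(row[[cn]])), ""))
    paste0("| ", paste(trimws(vals), collapse = " | "), " |")
  })
  paste(c(paste0("| ", paste(hdr, collapse = " | "), " |"),
          paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
          body),
        collapse = "\n")
}

#' Render a benchmark report as JSON
#'
#' @inheritParams report_markdown
#' @return A JSON string with `meta` and `rows`.
#' @export
report_json <- function(report, digits = 6L) {
  stopifnot(inherits(report, "benchmark_report"))
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  as.character(jsonlite::toJSON(list(meta = attr(report, "meta"), rows = df),
                                auto_unbox = TRUE, digits = NA, na = "null"))
}
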
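check_pairs <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    stop("y and y_hat must have equal length", call. = FALSE)
  }
  if (!length(y)) stop("need at least one pair", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(y_hat))) {
    stop("y and y_hat must be finite", call. = FALSE)
  }
}

#' Coefficient of determination
#'
#' `R2 = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`.  At most 1, can
#' be negative; scale-invariant.  Errors (rather than returning 0) when
#' the actual values have zero variance, since the ratio is then
#' undefined.
#'
#' @param y Actual values.
#' @param y_hat Predicted values.
#' @return The R-squared value.
#' @export
r_squared <- function(y, y_hat) {
  check_pairs(y, y_hat)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("R-squared is undefined: actual values have zero variance",
         call. = FALSE)
  }
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return `sqrt(mean((y - y_hat)^2))`, in the units of `y`.
#' @export
rmse <- function(y, y_hat) {
  check_pairs(y, y_hat)
  sqrt(mean((y - y_hat)^2))
}

#' Mean absolute error
#'
#' @inheritParams r_squared
#' @return `mean(abs(y - y_hat))`, in the units of `y`.
#' @export
mae <- function(y, y_hat) {
  check_pairs(y, y_hat)
  mean(abs(y - y_hat))
}

#' Metrics report for a prediction set
#'
#' @param y Actual fractions.
#' @param y_hat Predicted fractions.
#' @param scale `"percent"` (default; RMSE and MAE reported as labels
#'   x100, the conventional reporting unit) or `"fraction"`.  R-squared is
#'   scale-invariant.
#' @param granularity Bookkeeping tag: `"row"` (one stable-value time
#'   point per evaluated pair) or `"per_sample"`.
#' @return Object of class `metrics_report` with fields `r2`, `rmse`,
#'   `mae`, `scale`, `granularity`, `n`.
#' @export
metrics_report <- function(y, y_hat, scale = c("percent", "fraction"),
                           granularity = c("row", "per_sample")) {
  scale <- match.arg(scale)
  granularity <- match.arg(granularity)
  mult <- if (scale == "percent") 100 else 1
  structure(list(r2 = r_squared(y, y_hat),
                 rmse = mult * rmse(y, y_hat),
                 mae = mult * mae(y, y_hat),
                 scale = scale, granularity = granularity,
                 n = length(y)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  unit <- if (x$scale == "percent") "%" else ""
  cat(sprintf("R2 = %.4f, RMSE = %.4f%s, MAE = %.4f%s  (n = %d, %s)\n",
              x$r2, x$rmse, unit, x$mae, unit, x$n, x$granularity))
  invisible(x)
}

#' Evaluate a fitted model on a test dataset
#'
#' Builds the model's input representation from the dataset (stable-value
#' rows for the SVR/RFR/BPNN baselines, the 10-channel tensor for the
#' convolutional models), predicts, and computes R-squared, RMSE and MAE.
#' For stable-value models, `granularity = "row"` scores each of a
#' sample's 10 stable time points as an independent pair (the default),
#' while `"per_sample"` averages the 10 row predictions per sample first.
#' Convolutional models predict once per sample, so their reports always
#' carry `granularity = "per_sample"`.
#'
#' @param model A fitted `enose_svr`, `enose_rfr`, `enose_bpnn`,
#'   `enose_cnn` or `enose_hybrid`.
#' @param dataset The test [enose_dataset()].
#' @param granularity See above.
#' @param scale `"percent"` or `"fraction"`.
#' @return A [metrics_report()].
#' @export
evaluate_model <- function(model, dataset,
                           granularity = c("row", "per_sample"),
                           scale = c("percent", "fraction")) {
  granularity <- match.arg(granularity)
  scale <- match.arg(scale)
  stopifnot(inherits(dataset, "enose_dataset"))
  if (!length(dataset)) stop("empty test dataset", call. = FALSE)
  if (inherits(model, c("enose_cnn", "enose_hybrid"))) {
    mc <- to_multichannel(dataset)
    pred <- predict(model, mc)
    return(metrics_report(mc$labels, pred, scale = scale,
                          granularity = "per_sample"))
  }
  sv <- build_sv_matrix(dataset)
  pred <- predict(model, sv$rows)
  if (granularity == "per_sample") {
    agg <- tapply(pred, factor(sv$sample_index,
                               levels = unique(sv$sample_index)), mean)
    y <- sv$labels[!duplicated(sv$sample_index)]
    metrics_report(y, as.numeric(agg), scale = scale,
                   granularity = "per_sample")
  } else {
    metrics_report(sv$labels, pred, scale = scale, granularity = "row")
  }
}

#' PCA projection of stable-value rows
#'
#' Selects `per_proportion` samples per proportion level (seeded), keeps
#' their stable-value rows, mean-centers the sensor features (optionally
#' standardizing) and computes principal components.
#'
#' @param sv An [build_sv_matrix()] object.
#' @param n_components Number of component scores to return.
#' @param per_proportion Samples drawn per proportion level.
#' @param subset_seed Seed for the random sample selection.
#' @param standardize Also scale features to unit variance (default
#'   `FALSE`: the G/G0 ratios share units, so centering suffices).
#' @return List with `scores` (rows x `n_components`),
#'   `explained` (all variance ratios, non-increasing, summing to 1),
#'   `sample_ids` (the selected samples) and the `prcomp` fit.
#' @export
pca_projection <- function(sv, n_components = 3L, per_proportion = 9L,
                           subset_seed = 1L, standardize = FALSE) {
  stopifnot(inherits(sv, "sv_matrix"))
  if (n_components > ncol(sv$rows)) {
    stop("n_components exceeds the number of sensor features",
         call. = FALSE)
  }
  ub <- !duplicated(sv$sample_index)
  ids <- sv$sample_index[ub]
  labs <- sv$labels[ub]
  set.seed(subset_seed)
  chosen <- character()
  for (lv in sort(unique(labs))) {
    pool <- ids[labs == lv]
    if (length(pool) < per_proportion) {
      stop(sprintf("only %d samples at proportion %s; need %d",
                   length(pool), format(lv), per_proportion),
           call. = FALSE)
    }
    chosen <- c(chosen, pool[sample.int(length(pool), per_proportion)])
  }
  keep <- sv$sample_index %in% chosen
  fit <- stats::prcomp(sv$rows[keep, , drop = FALSE], center = TRUE,
                       scale. = standardize)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x[, seq_len(n_components), drop = FALSE],
       explained = explained,
       sample_ids = chosen,
       labels = sv$labels[keep],
       fit = fit)
}
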
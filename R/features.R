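#' Extract the stable-value block of a sample
#'
#' The plateau of an E-nose response curve carries most of its chemical
#' information; the stable values (SVs) are the readings from 91 s to
#' 100 s.  Returns those 10 rows for all 10 sensors.
#'
#' @param sample An [enose_sample()].
#' @param window Time points (1-based seconds) to retain, default 91:100.
#' @return A 10 x 10 numeric matrix (time points x sensors).
#' @export
extract_stable_values <- function(sample, window = 91:100) {
  cv <- sample$curves
  if (!is.matrix(cv) || nrow(cv) < max(window)) {
    stop(sprintf("sample %s has %s time points; need at least %d",
                 sample$sample_id,
                 if (is.matrix(cv)) nrow(cv) else "?", max(window)),
         call. = FALSE)
  }
  cv[window, , drop = FALSE]
}

#' Stack stable values of a dataset into a row matrix
#'
#' Each of the 10 stable time points of each sample becomes one row, so a
#' dataset of n samples yields a `10n x 10` matrix (e.g. 210 samples give
#' 2100 x 10).  Labels are repeated across a sample's 10 rows; this is the
#' input representation for the SVR, RFR and BPNN baselines.
#'
#' @param dataset A nonempty [enose_dataset()].
#' @return Object of class `sv_matrix`: list with `rows` (matrix),
#'   `labels` (fractions, one per row) and `sample_index` (sample_id per
#'   row).
#' @export
build_sv_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "enose_dataset"))
  if (!length(dataset)) stop("dataset is empty", call. = FALSE)
  blocks <- lapply(dataset$samples, extract_stable_values)
  rows <- do.call(rbind, blocks)
  labels <- rep(vapply(dataset$samples, `[[`, numeric(1), "proportion"),
                each = 10L)
  ids <- rep(vapply(dataset$samples, `[[`, character(1), "sample_id"),
             each = 10L)
  structure(list(rows = rows, labels = labels, sample_index = ids),
            class = "sv_matrix")
}

#' @export
print.sv_matrix <- function(x, ...) {
  cat(sprintf("<sv_matrix> %d rows x %d sensors (%d samples)\n",
              nrow(x$rows), ncol(x$rows), length(unique(x$sample_index))))
  invisible(x)
}

#' Convert a dataset to the 10-channel input representation
#'
#' Transposes each sample's 100 x 10 curve matrix into a 10 x 100 channel
#' matrix (one channel per sensor) and stacks them into an
#' `n x 10 x 100` array — the input of the convolutional models.  No
#' scaling or normalization is applied.
#'
#' @param dataset A nonempty [enose_dataset()].
#' @return Object of class `multichannel_input`: list with `tensor`
#'   (array `[n, channels, time]`), `labels` (fractions) and
#'   `sample_index`.
#' @export
to_multichannel <- function(dataset) {
  stopifnot(inherits(dataset, "enose_dataset"))
  if (!length(dataset)) stop("dataset is empty", call. = FALSE)
  n <- length(dataset)
  len <- nrow(dataset$samples[[1L]]$curves)
  nch <- ncol(dataset$samples[[1L]]$curves)
  tensor <- array(0, dim = c(n, nch, len))
  for (i in seq_len(n)) {
    tensor[i, , ] <- t(dataset$samples[[i]]$curves)
  }
  structure(list(
    tensor = tensor,
    labels = vapply(dataset$samples, `[[`, numeric(1), "proportion"),
    sample_index = vapply(dataset$samples, `[[`, character(1), "sample_id")
  ), class = "multichannel_input")
}

#' @export
print.multichannel_input <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<multichannel_input> %d samples x %d channels x %d points\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Day-blocked train/test split
#'
#' Splits a dataset by measurement day: samples from the first
#' `train_days` days form the training set, the remainder the test set.
#' Day is taken from each sample's metadata, not from file order.
#'
#' @param dataset An [enose_dataset()].
#' @param train_days Number of leading days to train on; must satisfy
#'   `1 <= train_days < max(day)`.
#' @return List with elements `train` and `test` (both `enose_dataset`),
#'   a partition of the input with within-split order preserved.
#' @export
split_by_day <- function(dataset, train_days) {
  meta <- dataset_meta(dataset)
  n_days <- max(meta$day)
  if (train_days < 1 || train_days >= n_days) {
    stop(sprintf("train_days must lie in [1, %d), got %s", n_days,
                 format(train_days)), call. = FALSE)
  }
  list(train = dataset[which(meta$day <= train_days)],
       test = dataset[which(meta$day > train_days)])
}
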
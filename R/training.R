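#' Training hyperparameters for the convolutional regressor
#'
#' Mini-batch SGD on MSE loss with a step-decayed learning rate.  Defaults
#' follow the package's standard protocol: batch size 49 (21 for the
#' small-training-set experiment), initial learning rate 0.001, 1100
#' epochs, learning rate halved every 550 epochs, momentum 0.95,
#' checkpoints every 20 epochs plus the final epoch.
#'
#' @param batch_size Mini-batch size.
#' @param n_epochs Number of epochs.
#' @param initial_lr Initial learning rate.
#' @param lr_step Epochs between learning-rate decays.
#' @param lr_gamma Multiplicative decay factor in (0, 1].
#' @param momentum SGD momentum.
#' @param checkpoint_every Checkpoint cadence in epochs.
#' @param seed Integer seed (batch shuffling).
#' @return Object of class `train_hyper`.
#' @export
train_hyper <- function(batch_size = 49L, n_epochs = 1100L,
                        initial_lr = 0.001, lr_step = 550L,
                        lr_gamma = 0.5, momentum = 0.95,
                        checkpoint_every = 20L, seed = 1L) {
  stopifnot(batch_size >= 1, n_epochs >= 1, initial_lr >= 0,
            lr_gamma > 0, lr_gamma <= 1, lr_step >= 1,
            checkpoint_every >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs),
                 initial_lr = initial_lr, lr_step = as.integer(lr_step),
                 lr_gamma = lr_gamma, momentum = momentum,
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "train_hyper")
}

#' Train the convolutional regressor
#'
#' Runs `n_epochs` of mini-batch SGD on MSE loss over fraction labels,
#' with the step-decayed learning rate of [train_hyper()].  Training is
#' deterministic given the seed.  Checkpoints (full weight snapshots,
#' including batch-norm running statistics) are stored every
#' `checkpoint_every` epochs and at the final epoch.
#'
#' @param model An [build_1dcnn()] model (updated in place).
#' @param train_inputs A [to_multichannel()] object with labels.
#' @param hyper A [train_hyper()].
#' @param engine `"compiled"` (default; the whole loop runs in native
#'   code) or `"reference"` (the layer-by-layer R loop).  Both engines
#'   draw identical batch orders from the seed and implement the same
#'   arithmetic.
#' @return Object of class `cnn_history`: per-epoch loss vector,
#'   checkpoint registry, the hyperparameters, and a reference to the
#'   model.
#' @export
train_1dcnn <- function(model, train_inputs, hyper = train_hyper(),
                        engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  stopifnot(inherits(model, "enose_cnn"),
            inherits(train_inputs, "multichannel_input"))
  X <- as_clb(train_inputs)
  check_input_shape(X, model$backbone$in_channels,
                    model$backbone$input_length)
  y <- train_inputs$labels
  n <- length(y)
  if (!n) stop("empty training set", call. = FALSE)
  layers <- cnn_all_layers(model)
  set.seed(hyper$seed)
  perms <- vapply(seq_len(hyper$n_epochs),
                  function(e) sample.int(n), integer(n))
  dim(perms) <- c(n, hyper$n_epochs)
  if (engine == "compiled") {
    res <- cpp_train_sgd(lapply(layers, layer_export), X, y, perms,
                         hyper$batch_size, hyper$initial_lr,
                         hyper$lr_step, hyper$lr_gamma, hyper$momentum,
                         hyper$checkpoint_every)
    loss <- as.numeric(res$loss)
    checkpoints <- lapply(res$checkpoints, normalize_cpp_state)
    layers_set_state_full(layers, normalize_cpp_state(res$final))
  } else {
    loss <- numeric(hyper$n_epochs)
    checkpoints <- list()
    for (epoch in seq_len(hyper$n_epochs)) {
      lr <- hyper$initial_lr *
        hyper$lr_gamma^((epoch - 1L) %/% hyper$lr_step)
      perm <- perms[, epoch]
      tot <- 0
      for (start in seq(1L, n, by = hyper$batch_size)) {
        idx <- perm[start:min(start + hyper$batch_size - 1L, n)]
        Xb <- X[, , idx, drop = FALSE]
        yb <- y[idx]
        out <- layers_forward(layers, Xb, training = TRUE)
        err <- as.numeric(out) - yb
        tot <- tot + sum(err^2)
        dY <- matrix(2 * err / length(idx), 1L)
        layers_backward(layers, dY)
        layers_step(layers, lr, hyper$momentum)
      }
      loss[epoch] <- tot / n
      if (!is.finite(loss[epoch])) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; lower the learning rate or check the input data",
             call. = FALSE)
      }
      if (epoch %% hyper$checkpoint_every == 0L ||
          epoch == hyper$n_epochs) {
        checkpoints[[as.character(epoch)]] <- layers_state(layers)
      }
    }
  }
  structure(list(loss = loss, checkpoints = checkpoints, hyper = hyper,
                 model = model),
            class = "cnn_history")
}

# Serialize a layer environment for the native training driver.
layer_export <- function(l) {
  switch(l$type,
    conv1d = list(type = "conv1d", W = l$W, vW = l$vW, kernel = l$kernel,
                  stride = l$stride, padding = l$padding, c_in = l$c_in,
                  c_out = l$c_out),
    batchnorm = list(type = "batchnorm", gamma = l$gamma, beta = l$beta,
                     vgamma = l$vgamma, vbeta = l$vbeta,
                     running_mean = l$running_mean,
                     running_var = l$running_var, eps = l$eps,
                     momentum = l$momentum, channels = l$channels),
    pool = list(type = if (l$kind == "max") "maxpool" else "avgpool",
                kernel = l$kernel, stride = l$stride),
    dense = list(type = "dense", W = l$W, b = l$b, vW = l$vW, vb = l$vb),
    list(type = l$type)
  )
}

# Vector-valued parameters come back from native code as n x 1 matrices;
# flatten everything that the R layers store as plain vectors.
normalize_cpp_state <- function(state) {
  lapply(state, function(st) {
    for (nm in names(st)) {
      if (!nm %in% c("W", "vW")) st[[nm]] <- as.numeric(st[[nm]])
    }
    st
  })
}

layers_set_state_full <- function(layers, state) {
  for (i in seq_along(layers)) {
    for (nm in names(state[[i]])) {
      assign(nm, state[[i]][[nm]], envir = layers[[i]])
    }
  }
  invisible(layers)
}

#' @export
print.cnn_history <- function(x, ...) {
  cat(sprintf(
    "<cnn_history> %d epochs, final loss %.3g, %d checkpoints\n",
    length(x$loss), x$loss[length(x$loss)], length(x$checkpoints)))
  invisible(x)
}

#' Restore model weights from a training checkpoint
#'
#' @param history A `cnn_history`.
#' @param epoch A checkpointed epoch.
#' @param model Model to restore into; defaults to the trained model
#'   referenced by the history.
#' @return The model, invisibly.
#' @export
restore_checkpoint <- function(history, epoch, model = history$model) {
  key <- as.character(epoch)
  if (!key %in% names(history$checkpoints)) {
    stop("no checkpoint at epoch ", epoch, "; available: ",
         paste(names(history$checkpoints), collapse = ", "),
         call. = FALSE)
  }
  layers_set_state(cnn_all_layers(model), history$checkpoints[[key]])
  invisible(model)
}

#' Automated convergence-epoch selection
#'
#' Smooths the loss curve with a trailing window mean and returns the
#' smallest epoch whose smoothed loss is within `rel_tol` (relative) of
#' the global minimum smoothed loss.  For an everywhere-constant history
#' this is the first epoch with a full window.
#'
#' @param history A `cnn_history` or a numeric loss vector.
#' @param window Trailing smoothing window in epochs.
#' @param rel_tol Relative tolerance above the minimum smoothed loss.
#' @return The selected epoch (integer).
#' @export
select_convergence_epoch <- function(history, window = 50L,
                                     rel_tol = 0.02) {
  loss <- if (inherits(history, "cnn_history")) history$loss else history
  n <- length(loss)
  if (n < window) stop("history shorter than the smoothing window",
                       call. = FALSE)
  if (any(!is.finite(loss))) stop("non-finite losses in history",
                                  call. = FALSE)
  cs <- cumsum(loss)
  sm <- (cs[window:n] - c(0, cs)[(window:n) - window + 1L]) / window
  lo <- min(sm)
  eligible <- which(sm <= lo * (1 + rel_tol))
  as.integer(window - 1L + eligible[1L])
}

#' Nearest checkpointed epoch
#'
#' @param history A `cnn_history`.
#' @param epoch Target epoch.
#' @return The available checkpoint epoch closest to `epoch` (ties go to
#'   the earlier one).
#' @export
nearest_checkpoint <- function(history, epoch) {
  avail <- as.integer(names(history$checkpoints))
  avail[which.min(abs(avail - epoch))]
}

#' Hyperparameter grids
#'
#' `svr_grid()` and `rfr_grid()` return the package's standard search
#' grids: penalty factor (1, 5, 10, 20, 50, 100, 200, 500) crossed with
#' gamma (0.01, 0.1, 1, 5, 10, 20) for the SVR (48 combinations), and max
#' depth (3, 5, 7, 9, 11, 13) crossed with minimum samples to split (7,
#' 14, 21, 28, 35, 42) for the random forest (36 combinations).
#'
#' @return Named list of parameter vectors.
#' @export
svr_grid <- function() {
  list(C = c(1, 5, 10, 20, 50, 100, 200, 500),
       gamma = c(0.01, 0.1, 1, 5, 10, 20))
}

#' @rdname svr_grid
#' @export
rfr_grid <- function() {
  list(max_depth = c(3, 5, 7, 9, 11, 13),
       min_samples_split = c(7, 14, 21, 28, 35, 42))
}

# Stratified k-fold assignment: within each label level (and optionally at
# the block level, so rows of one sample stay together) folds are dealt
# round-robin after a seeded shuffle.
stratified_folds <- function(y, k, seed, blocks = NULL) {
  set.seed(seed)
  if (is.null(blocks)) blocks <- seq_along(y)
  ub <- !duplicated(blocks)
  bl_id <- blocks[ub]
  bl_y <- y[ub]
  fold_of_block <- integer(length(bl_id))
  names(fold_of_block) <- as.character(bl_id)
  # the round-robin counter continues across strata so that singleton
  # strata (continuous labels) still spread evenly over the folds
  off <- 0L
  for (lv in unique(bl_y)) {
    members <- which(bl_y == lv)
    members <- members[sample.int(length(members))]
    fold_of_block[members] <- (off + seq_along(members) - 1L) %% k + 1L
    off <- off + length(members)
  }
  fold_of_block[as.character(blocks)]
}

#' Exhaustive grid search with k-fold cross-validation
#'
#' Evaluates every combination of the grid by k-fold cross-validated MSE
#' (folds stratified by label value, seeded) and returns the winner plus
#' the full CV table.  Ties are broken by enumeration order (the first
#' grid axis varies fastest).
#'
#' @param model_family `"svr"` or `"rfr"`.
#' @param grid Named list of parameter vectors, e.g. [svr_grid()].
#' @param X Feature matrix.
#' @param y Labels (fractions).
#' @param k_folds Number of folds (default 3).
#' @param seed Integer seed for fold assignment and forest fitting.
#' @param blocks Optional per-row grouping (e.g. sample ids) kept intact
#'   across folds.
#' @return List with `best` (named parameter list), `best_mse`, and
#'   `table` (data.frame of all combinations with mean and per-fold MSE).
#' @export
grid_search_cv <- function(model_family = c("svr", "rfr"), grid, X, y,
                           k_folds = 3L, seed = 1L, blocks = NULL) {
  model_family <- match.arg(model_family)
  if (!length(grid) || !all(lengths(grid) > 0)) {
    stop("empty grid", call. = FALSE)
  }
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= k_folds)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  fold <- stratified_folds(y, k_folds, seed, blocks)
  fold_mse <- matrix(NA_real_, nrow(combos), k_folds)
  for (ci in seq_len(nrow(combos))) {
    pars <- as.list(combos[ci, , drop = FALSE])
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      fit <- switch(model_family,
        svr = fit_svr(X[tr, , drop = FALSE], y[tr],
                      svr_params(C = pars$C, gamma = pars$gamma)),
        rfr = fit_rfr(X[tr, , drop = FALSE], y[tr],
                      rfr_params(max_depth = pars$max_depth,
                                 min_samples_split = pars$min_samples_split,
                                 seed = seed)))
      pred <- predict(fit, X[!tr, , drop = FALSE])
      fold_mse[ci, f] <- mean((pred - y[!tr])^2)
    }
  }
  mean_mse <- rowMeans(fold_mse)
  best_i <- which.min(mean_mse)  # which.min returns the first minimum
  tab <- cbind(combos, mean_mse = mean_mse,
               as.data.frame(fold_mse) |>
                 stats::setNames(paste0("fold", seq_len(k_folds))))
  list(best = as.list(combos[best_i, , drop = FALSE]),
       best_mse = mean_mse[best_i], table = tab, family = model_family)
}

#' Assemble the hybrid backbone + forest model
#'
#' Loads the backbone weights from the checkpoint nearest the selected
#' convergence epoch, freezes them, extracts features for every training
#' sample in inference mode, grid-searches the forest hyperparameters on
#' those features and fits the final forest.
#'
#' @param history A `cnn_history` from [train_1dcnn()].
#' @param train_inputs The [to_multichannel()] training set.
#' @param epoch Epoch whose weights to use.  `NULL` (default) applies
#'   [select_convergence_epoch()] and snaps to the nearest available
#'   checkpoint (with a message when they differ); an explicitly given
#'   epoch must be checkpointed.
#' @param grid Forest search grid, default [rfr_grid()].
#' @param k_folds,seed Cross-validation settings.
#' @return Object of class `enose_hybrid` with the frozen backbone, the
#'   fitted forest, the epoch used and the CV audit table.
#' @export
assemble_hybrid <- function(history, train_inputs, epoch = NULL,
                            grid = rfr_grid(), k_folds = 3L, seed = 1L) {
  stopifnot(inherits(history, "cnn_history"))
  if (is.null(epoch)) {
    epoch <- select_convergence_epoch(history)
    ck <- nearest_checkpoint(history, epoch)
    if (ck != epoch) {
      message("converged at epoch ", epoch,
              "; using nearest checkpoint ", ck,
              " (delta ", abs(ck - epoch), ")")
    }
  } else if (!as.character(epoch) %in% names(history$checkpoints)) {
    stop("no checkpoint at epoch ", epoch, "; available: ",
         paste(names(history$checkpoints), collapse = ", "),
         call. = FALSE)
  } else {
    ck <- epoch
  }
  src <- history$model
  backbone <- build_backbone(src$backbone$spec, src$backbone$in_channels,
                             src$backbone$input_length, seed = 0L)
  n_bb <- length(backbone$layers)
  layers_set_state(backbone$layers,
                   history$checkpoints[[as.character(ck)]][seq_len(n_bb)])
  feats <- backbone_features(backbone, train_inputs)
  cv <- grid_search_cv("rfr", grid, feats, train_inputs$labels,
                       k_folds = k_folds, seed = seed)
  forest <- fit_rfr(feats, train_inputs$labels,
                    rfr_params(max_depth = cv$best$max_depth,
                               min_samples_split = cv$best$min_samples_split,
                               seed = seed))
  structure(list(backbone = backbone, forest = forest, epoch = ck,
                 requested_epoch = epoch, cv = cv),
            class = "enose_hybrid")
}

#' @export
predict.enose_hybrid <- function(object, newdata, ...) {
  hybrid_predict(object$backbone, object$forest, newdata)
}

#' @export
print.enose_hybrid <- function(x, ...) {
  cat(sprintf(
    "<enose_hybrid> backbone frozen at epoch %d; forest (max_depth=%s, min_samples_split=%s)\n",
    x$epoch, x$forest$params$max_depth, x$forest$params$min_samples_split))
  invisible(x)
}
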
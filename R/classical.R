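#' Random-forest regressor parameters
#'
#' @param n_trees Number of trees (default 100).
#' @param max_depth Maximal tree depth (`NULL` = unlimited).
#' @param min_samples_split Minimum node size eligible for splitting.
#' @param mtry Predictors sampled at each split; default is the
#'   regression-forest rule `ceiling(M / 3)` applied at fit time.
#' @param bootstrap Draw bootstrap resamples per tree (disable only for
#'   deterministic single-tree checks).
#' @param seed Integer seed.
#' @return Object of class `rfr_params`.
#' @export
rfr_params <- function(n_trees = 100L, max_depth = NULL,
                       min_samples_split = 2L, mtry = NULL,
                       bootstrap = TRUE, seed = 1L) {
  stopifnot(n_trees >= 1, min_samples_split >= 2,
            is.null(max_depth) || max_depth >= 1)
  structure(list(n_trees = as.integer(n_trees), max_depth = max_depth,
                 min_samples_split = as.integer(min_samples_split),
                 mtry = mtry, bootstrap = bootstrap,
                 seed = as.integer(seed)),
            class = "rfr_params")
}

#' Fit a random-forest regressor
#'
#' Bagged regression trees with per-node feature subsampling, grown by
#' \pkg{ranger}.  Predictions are the mean over trees, so they always lie
#' within the range of the training labels.
#'
#' @param X Numeric feature matrix (rows = observations).
#' @param y Numeric labels.
#' @param params An [rfr_params()].
#' @return Object of class `enose_rfr`.
#' @export
fit_rfr <- function(X, y, params = rfr_params()) {
  X <- as.matrix(X)
  if (!nrow(X)) stop("empty feature matrix", call. = FALSE)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < params$min_samples_split) {
    stop("fewer rows than min_samples_split", call. = FALSE)
  }
  df <- data.frame(y = y, X)
  mtry <- if (is.null(params$mtry)) ceiling(ncol(X) / 3) else params$mtry
  fit <- ranger::ranger(
    dependent.variable.name = "y", data = df,
    num.trees = params$n_trees,
    mtry = min(mtry, ncol(X)),
    min.node.size = params$min_samples_split,
    max.depth = if (is.null(params$max_depth)) 0 else params$max_depth,
    replace = params$bootstrap,
    sample.fraction = 1,
    seed = params$seed, num.threads = 1, verbose = FALSE)
  structure(list(fit = fit, params = params,
                 feature_names = colnames(df)[-1],
                 y_range = range(y)),
            class = "enose_rfr")
}

#' @export
predict.enose_rfr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$feature_names
  as.numeric(stats::predict(object$fit, data = as.data.frame(newdata),
                            num.threads = 1)$predictions)
}

#' Support vector regression parameters
#'
#' RBF-kernel epsilon-insensitive SVR.  `epsilon` defaults to 0.1 (on the
#' fraction label scale).
#'
#' @param C Penalty factor (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param epsilon Insensitive-tube half width.
#' @return Object of class `svr_params`.
#' @export
svr_params <- function(C = 1, gamma = 0.1, epsilon = 0.1) {
  stopifnot(C > 0, gamma > 0, epsilon >= 0)
  structure(list(C = C, gamma = gamma, epsilon = epsilon),
            class = "svr_params")
}

#' Fit an RBF-kernel support vector regressor
#'
#' Thin wrapper around [e1071::svm()] (eps-regression); features are used
#' unscaled, consistently with the rest of the package.
#'
#' @param X Numeric feature matrix with 10 columns (stable-value rows).
#' @param y Numeric labels (fractions).
#' @param params An [svr_params()].
#' @return Object of class `enose_svr`.
#' @export
fit_svr <- function(X, y, params = svr_params()) {
  X <- as.matrix(X)
  if (ncol(X) != 10L) {
    stop("expected 10 feature columns (stable values), got ", ncol(X),
         call. = FALSE)
  }
  fit <- e1071::svm(x = X, y = y, type = "eps-regression",
                    kernel = "radial", cost = params$C,
                    gamma = params$gamma, epsilon = params$epsilon,
                    scale = FALSE, fitted = FALSE)
  structure(list(fit = fit, params = params, y_mean = mean(y)),
            class = "enose_svr")
}

#' @export
predict.enose_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  # with every residual inside the epsilon tube there are no support
  # vectors and the solution is the constant level
  if (object$fit$tot.nSV == 0) {
    return(rep(object$y_mean, nrow(newdata)))
  }
  as.numeric(stats::predict(object$fit, newdata = newdata))
}

#' Feed-forward network specification (stable-value baseline)
#'
#' A single-hidden-layer perceptron with ReLU hidden activation and a
#' linear output, trained by mini-batch SGD on MSE loss.  The default
#' topology is 10-21-1.
#'
#' @param n_input Input width (10 stable-value sensors).
#' @param n_hidden Hidden layer width.
#' @return Object of class `bpnn_spec`.
#' @export
bpnn_spec <- function(n_input = 10L, n_hidden = 21L) {
  structure(list(n_input = as.integer(n_input),
                 n_hidden = as.integer(n_hidden)),
            class = "bpnn_spec")
}

#' Fit the feed-forward baseline network
#'
#' @param X Numeric feature matrix whose column count matches
#'   `spec$n_input`.
#' @param y Numeric labels (fractions).
#' @param spec A [bpnn_spec()].
#' @param n_epochs,batch_size,lr,momentum SGD hyperparameters.
#' @param seed Integer seed (weights and batch order).
#' @return Object of class `enose_bpnn` with the per-epoch training loss
#'   in `$loss`.
#' @export
fit_bpnn <- function(X, y, spec = bpnn_spec(), n_epochs = 500L,
                     batch_size = 49L, lr = 0.003, momentum = 0.9,
                     seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) != spec$n_input) {
    stop(sprintf("expected %d feature columns, got %d", spec$n_input,
                 ncol(X)), call. = FALSE)
  }
  stopifnot(nrow(X) == length(y))
  set.seed(seed)
  layers <- list(nn_dense(spec$n_input, spec$n_hidden, init = "he"),
                 nn_relu(),
                 nn_dense(spec$n_hidden, 1L, init = "glorot"))
  Xt <- t(X)
  n <- length(y)
  loss <- numeric(n_epochs)
  for (epoch in seq_len(n_epochs)) {
    perm <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      Xb <- Xt[, idx, drop = FALSE]
      yb <- y[idx]
      out <- layers_forward(layers, Xb, training = TRUE)
      err <- as.numeric(out) - yb
      tot <- tot + sum(err^2)
      dY <- matrix(2 * err / length(idx), 1L)
      layers_backward(layers, dY)
      layers_step(layers, lr, momentum)
    }
    loss[epoch] <- tot / n
    if (!is.finite(loss[epoch])) {
      stop("BPNN training diverged (non-finite loss) at epoch ", epoch,
           call. = FALSE)
    }
  }
  structure(list(layers = layers, spec = spec, loss = loss, seed = seed),
            class = "enose_bpnn")
}

#' @export
predict.enose_bpnn <- function(object, newdata, ...) {
  as.numeric(layers_forward(object$layers, t(as.matrix(newdata)),
                            training = FALSE))
}

#' Predict with a frozen backbone plus fitted forest
#'
#' The hybrid inference path: extract features with the backbone in
#' inference mode, then average the forest's tree predictions.
#'
#' @param backbone A trained `enose_backbone`.
#' @param forest A fitted `enose_rfr` trained on that backbone's features.
#' @param inputs A [to_multichannel()] object or `[n, channels, length]`
#'   array.
#' @return Numeric vector of predicted fractions.
#' @export
hybrid_predict <- function(backbone, forest, inputs) {
  feats <- backbone_features(backbone, inputs)
  if (ncol(feats) != length(forest$feature_names)) {
    stop(sprintf("backbone yields %d features but forest expects %d",
                 ncol(feats), length(forest$feature_names)),
         call. = FALSE)
  }
  predict(forest, feats)
}
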
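#' Declarative backbone architecture
#'
#' The default is the compact 1-D convolutional feature extractor used
#' throughout the package: four ConvBNReLU blocks (kernel 3) interleaved
#' with two max-pooling layers, closed by an average-pooling layer and a
#' flatten, mapping a 10-channel, 100-point input to a 128-dimensional
#' feature vector.
#'
#' @param layers List of layer descriptors; each is a list with fields
#'   `name`, `type` (`"conv"`, `"maxpool"`, `"avgpool"`, `"flatten"`) and,
#'   where relevant, `filters`, `kernel`, `padding`, `stride`.
#' @return Object of class `backbone_spec`.
#' @export
backbone_spec <- function(layers = NULL) {
  if (is.null(layers)) {
    layers <- list(
      list(name = "Conv1", type = "conv", filters = 16L, kernel = 3L,
           padding = 1L, stride = 2L),
      list(name = "Conv2", type = "conv", filters = 32L, kernel = 3L,
           padding = 0L, stride = 1L),
      list(name = "Pool1", type = "maxpool", kernel = 2L, stride = 2L),
      list(name = "Conv3", type = "conv", filters = 64L, kernel = 3L,
           padding = 1L, stride = 2L),
      list(name = "Pool2", type = "maxpool", kernel = 2L, stride = 2L),
      list(name = "Conv4", type = "conv", filters = 128L, kernel = 3L,
           padding = 1L, stride = 2L),
      list(name = "Pool3", type = "avgpool", kernel = 3L, stride = 1L),
      list(name = "Flatten", type = "flatten")
    )
  }
  structure(list(layers = layers), class = "backbone_spec")
}

#' Regression head architecture
#'
#' Two fully-connected layers (64 ReLU units, then 32 Sigmoid units)
#' followed by a linear single-output layer.  The final 32-to-1 linear
#' layer turns the Sigmoid-compressed representation into a scalar
#' proportion estimate; labels are fractions in \[0, 1\].
#'
#' @param units Hidden layer widths.
#' @param activations Activation per hidden layer (`"relu"` or
#'   `"sigmoid"`).
#' @return Object of class `head_spec`.
#' @export
head_spec <- function(units = c(64L, 32L),
                      activations = c("relu", "sigmoid")) {
  stopifnot(length(units) == length(activations),
            all(activations %in% c("relu", "sigmoid")))
  structure(list(units = as.integer(units), activations = activations),
            class = "head_spec")
}

#' Layer-by-layer output shapes of a backbone
#'
#' Pure convolution/pooling arithmetic:
#' `len_out = floor((len_in + 2 * padding - kernel) / stride) + 1`.
#' The flatten row reports the flattened feature width in `channels`
#' (with `length = 1`).
#'
#' @param spec A [backbone_spec()].
#' @param input_shape `c(channels, length)` of the input.
#' @return data.frame with columns `layer`, `channels`, `length`, one row
#'   per layer including the input row.
#' @export
backbone_output_shape <- function(spec, input_shape = c(10L, 100L)) {
  stopifnot(inherits(spec, "backbone_spec"), length(input_shape) == 2)
  ch <- as.integer(input_shape[1]); len <- as.integer(input_shape[2])
  out <- data.frame(layer = "Input", channels = ch, length = len,
                    stringsAsFactors = FALSE)
  for (ly in spec$layers) {
    if (ly$type == "conv") {
      if (len + 2L * ly$padding < ly$kernel) {
        stop(sprintf("%s: input length %d (+2*%d padding) < kernel %d",
                     ly$name, len, ly$padding, ly$kernel), call. = FALSE)
      }
      len <- conv_out_len(len, ly$kernel, ly$padding, ly$stride)
      ch <- ly$filters
    } else if (ly$type %in% c("maxpool", "avgpool")) {
      if (len < ly$kernel) {
        stop(sprintf("%s: input length %d < filter size %d",
                     ly$name, len, ly$kernel), call. = FALSE)
      }
      len <- conv_out_len(len, ly$kernel, 0L, ly$stride)
    } else if (ly$type == "flatten") {
      ch <- ch * len
      len <- 1L
    } else {
      stop("unknown layer type ", ly$type, call. = FALSE)
    }
    out <- rbind(out, data.frame(layer = ly$name, channels = ch,
                                 length = len, stringsAsFactors = FALSE))
  }
  out
}

build_backbone_layers <- function(spec, in_channels) {
  layers <- list()
  ch <- in_channels
  for (ly in spec$layers) {
    if (ly$type == "conv") {
      layers <- c(layers, list(
        nn_conv1d(ch, ly$filters, ly$kernel, ly$stride, ly$padding),
        nn_batchnorm(ly$filters),
        nn_relu()))
      ch <- ly$filters
    } else if (ly$type == "maxpool") {
      layers <- c(layers, list(nn_pool("max", ly$kernel, ly$stride)))
    } else if (ly$type == "avgpool") {
      layers <- c(layers, list(nn_pool("avg", ly$kernel, ly$stride)))
    } else if (ly$type == "flatten") {
      layers <- c(layers, list(nn_flatten()))
    }
  }
  layers
}

#' Build a trainable convolutional backbone
#'
#' Instantiates the layer stack of a [backbone_spec()] with seeded weight
#' initialization (He-normal for convolutions).  The returned object is an
#' environment, so any model holding it shares its weights by reference.
#'
#' @param spec A [backbone_spec()].
#' @param in_channels Number of input channels (sensors), default 10.
#' @param input_length Number of time points per channel, default 100.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `enose_backbone`.
#' @export
build_backbone <- function(spec = backbone_spec(), in_channels = 10L,
                           input_length = 100L, seed = 1L) {
  shapes <- backbone_output_shape(spec, c(in_channels, input_length))
  set.seed(seed)
  bb <- new.env(parent = emptyenv())
  bb$layers <- build_backbone_layers(spec, in_channels)
  bb$spec <- spec
  bb$in_channels <- as.integer(in_channels)
  bb$input_length <- as.integer(input_length)
  bb$out_dim <- shapes$channels[nrow(shapes)]
  class(bb) <- "enose_backbone"
  bb
}

check_input_shape <- function(X, in_channels, input_length) {
  d <- dim(X)
  if (length(d) != 3 || d[1] != in_channels || d[2] != input_length) {
    stop(sprintf("input must be %d x %d per sample, got %s x %s",
                 in_channels, input_length, d[1], d[2]), call. = FALSE)
  }
}

# (channels, length, batch) layout used by the layer primitives.
as_clb <- function(inputs) {
  tensor <- if (inherits(inputs, "multichannel_input")) inputs$tensor
            else inputs
  stopifnot(length(dim(tensor)) == 3)
  aperm(tensor, c(2, 3, 1))
}

#' Extract backbone features
#'
#' Runs the backbone in inference mode (batch normalization uses its
#' stored running statistics) and returns one feature row per sample.
#'
#' @param backbone An `enose_backbone`.
#' @param inputs A [to_multichannel()] object or an `[n, channels, length]`
#'   array.
#' @return Numeric matrix, samples x features.
#' @export
backbone_features <- function(backbone, inputs) {
  X <- as_clb(inputs)
  check_input_shape(X, backbone$in_channels, backbone$input_length)
  t(layers_forward(backbone$layers, X, training = FALSE))
}

#' Build the full convolutional regressor
#'
#' Combines a [build_backbone()] with the fully-connected regression head
#' of [head_spec()].  The backbone is held by reference and can be pulled
#' out with [extract_backbone()]; both views share the same weights.
#'
#' @param spec A [backbone_spec()].
#' @param head A [head_spec()].
#' @param seed Integer seed for weight initialization.
#' @param in_channels,input_length Input geometry.
#' @return Object of class `enose_cnn`.
#' @export
build_1dcnn <- function(spec = backbone_spec(), head = head_spec(),
                        seed = 1L, in_channels = 10L, input_length = 100L) {
  set.seed(seed)
  backbone <- build_backbone(spec, in_channels, input_length, seed = seed)
  head_layers <- list()
  n_in <- backbone$out_dim
  for (i in seq_along(head$units)) {
    init <- if (head$activations[i] == "relu") "he" else "glorot"
    head_layers <- c(head_layers, list(
      nn_dense(n_in, head$units[i], init = init),
      if (head$activations[i] == "relu") nn_relu() else nn_sigmoid()))
    n_in <- head$units[i]
  }
  head_layers <- c(head_layers, list(nn_dense(n_in, 1L, init = "glorot")))
  m <- new.env(parent = emptyenv())
  m$backbone <- backbone
  m$head_layers <- head_layers
  m$head <- head
  m$seed <- as.integer(seed)
  class(m) <- "enose_cnn"
  m
}

#' Pull the backbone out of a convolutional regressor
#'
#' Returns the model's backbone by reference: weight updates to either
#' view are visible through both.
#'
#' @param model An `enose_cnn`.
#' @return The `enose_backbone` held by the model.
#' @export
extract_backbone <- function(model) {
  stopifnot(inherits(model, "enose_cnn"))
  model$backbone
}

cnn_all_layers <- function(model) c(model$backbone$layers, model$head_layers)

cnn_forward <- function(model, X, training = FALSE) {
  check_input_shape(X, model$backbone$in_channels,
                    model$backbone$input_length)
  out <- layers_forward(cnn_all_layers(model), X, training)
  as.numeric(out)
}

#' Predict adulterated proportions with the convolutional regressor
#'
#' @param object An `enose_cnn`.
#' @param newdata A [to_multichannel()] object or `[n, channels, length]`
#'   array.
#' @param ... Unused.
#' @return Numeric vector of predicted fractions, one per sample.
#' @export
predict.enose_cnn <- function(object, newdata, ...) {
  cnn_forward(object, as_clb(newdata), training = FALSE)
}

#' @export
print.enose_cnn <- function(x, ...) {
  cat(sprintf("<enose_cnn> backbone -> %d features -> head (%s) -> 1\n",
              x$backbone$out_dim, paste(x$head$units, collapse = "-")))
  invisible(x)
}

#' @export
print.enose_backbone <- function(x, ...) {
  cat(sprintf("<enose_backbone> %d x %d input -> %d features\n",
              x$in_channels, x$input_length, x$out_dim))
  invisible(x)
}
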
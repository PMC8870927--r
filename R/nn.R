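# Minimal 1-D neural-network primitives: conv1d, batch-norm, ReLU/Sigmoid,
# max/avg pooling, flatten and dense layers with exact backpropagation and
# SGD-with-momentum updates.  Data flows as (channels, length, batch)
# arrays; convolutions are im2col gathers (precomputed flat-index vectors,
# cached per input geometry) followed by one BLAS matrix product, so the
# whole stack runs at vector speed in plain R.  Layers are environments so
# that a backbone extracted from a trained network shares (aliases) its
# weights.

new_layer <- function(type, ...) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$icache <- list()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = l)
  class(l) <- c(paste0("nn_", type), "nn_layer")
  l
}

conv_out_len <- function(len, kernel, padding, stride) {
  (len + 2L * padding - kernel) %/% stride + 1L
}

# Flat-index plans for an im2col convolution / pooling window over an
# array laid out (channels, length, batch).  idx_k[[kk]] addresses the
# kk-th kernel tap of every (channel, output position, sample); gidx
# interleaves them in (channel, tap) row order; fidx addresses the
# unpadded region inside the padded buffer.
make_window_idx <- function(C, K, stride, padding, l_in, B) {
  l_pad <- l_in + 2L * padding
  l_out <- conv_out_len(l_in, K, padding, stride)
  off_b <- C * l_pad * (0:(B - 1L))
  idx_k <- vector("list", K)
  for (kk in seq_len(K)) {
    t_pos <- kk + stride * (0:(l_out - 1L))
    idx_k[[kk]] <- rep.int(1:C, l_out * B) +
      rep(rep(C * (t_pos - 1L), each = C), times = B) +
      rep(off_b, each = C * l_out)
  }
  tmp <- array(0L, c(C, l_out * B, K))
  for (kk in seq_len(K)) tmp[, , kk] <- idx_k[[kk]]
  gidx <- as.integer(aperm(tmp, c(1, 3, 2)))
  fidx <- if (padding > 0L) {
    rep.int(1:C, l_in * B) +
      rep(rep(C * (padding + (1:l_in) - 1L), each = C), times = B) +
      rep(off_b, each = C * l_in)
  } else NULL
  list(l_pad = l_pad, l_out = l_out, idx_k = idx_k, gidx = gidx,
       fidx = fidx, B = B, l_in = l_in)
}

window_plan <- function(l, C, l_in, B) {
  key <- paste0(l_in, "_", B)
  ic <- l$icache[[key]]
  if (is.null(ic)) {
    ic <- make_window_idx(C, l$kernel, l$stride, l$padding, l_in, B)
    l$icache[[key]] <- ic
  }
  ic
}

nn_conv1d <- function(c_in, c_out, kernel, stride = 1L, padding = 0L) {
  # He-normal initialization (fan-in = c_in * kernel), no bias: the
  # following batch-norm layer absorbs any bias term.  Weights are kept
  # as a (c_out, c_in * kernel) matrix, taps in im2col row order.
  W <- matrix(stats::rnorm(c_out * c_in * kernel,
                           sd = sqrt(2 / (c_in * kernel))),
              c_out, c_in * kernel)
  new_layer("conv1d", W = W, vW = matrix(0, c_out, c_in * kernel),
            c_in = as.integer(c_in), c_out = as.integer(c_out),
            kernel = as.integer(kernel), stride = as.integer(stride),
            padding = as.integer(padding))
}

nn_batchnorm <- function(channels, eps = 1e-5, momentum = 0.1) {
  new_layer("batchnorm",
            gamma = rep(1, channels), beta = rep(0, channels),
            vgamma = rep(0, channels), vbeta = rep(0, channels),
            running_mean = rep(0, channels), running_var = rep(1, channels),
            channels = as.integer(channels), eps = eps, momentum = momentum)
}

nn_relu <- function() new_layer("relu")
nn_sigmoid <- function() new_layer("sigmoid")

nn_pool <- function(kind = c("max", "avg"), kernel, stride) {
  kind <- match.arg(kind)
  new_layer("pool", kind = kind, kernel = as.integer(kernel),
            stride = as.integer(stride), padding = 0L)
}

nn_flatten <- function() new_layer("flatten")

nn_dense <- function(n_in, n_out, init = c("he", "glorot")) {
  init <- match.arg(init)
  sd <- if (init == "he") sqrt(2 / n_in) else sqrt(2 / (n_in + n_out))
  W <- matrix(stats::rnorm(n_out * n_in, sd = sd), n_out, n_in)
  b <- rep(0, n_out)
  new_layer("dense", W = W, b = b,
            vW = matrix(0, n_out, n_in), vb = rep(0, n_out))
}

layer_params <- function(l) {
  switch(l$type,
         conv1d = "W",
         batchnorm = c("gamma", "beta"),
         dense = c("W", "b"),
         character())
}

layer_state_names <- function(l) {
  c(layer_params(l),
    if (l$type == "batchnorm") c("running_mean", "running_var"))
}

layer_forward <- function(l, X, training = FALSE) {
  switch(l$type,
    conv1d = {
      d <- dim(X)
      if (d[2] + 2L * l$padding < l$kernel) {
        stop(sprintf("conv1d: input length %d (+2*%d padding) < kernel %d",
                     d[2], l$padding, l$kernel), call. = FALSE)
      }
      out <- cpp_conv_fwd(X, l$W, l$kernel, l$stride, l$padding)
      if (training) {
        l$cache <- list(Xcol = out$Xcol, l_in = d[2], B = d[3],
                        l_out = dim(out$Y)[2])
      }
      out$Y
    },
    batchnorm = {
      C <- l$channels
      n <- length(X) / C
      if (training) {
        out <- cpp_bn_fwd(X, l$gamma, l$beta, C, l$eps)
        l$running_mean <- (1 - l$momentum) * l$running_mean +
          l$momentum * as.numeric(out$mu)
        l$running_var <- (1 - l$momentum) * l$running_var +
          l$momentum * as.numeric(out$v) * n / max(n - 1, 1)
        l$cache <- list(xhat = out$xhat, sdv = out$sdv)
        Y <- out$Y
        dim(Y) <- dim(X)
        Y
      } else {
        # length-C vectors recycle channel-first over the flat layout, so
        # no reshape is needed
        xhat <- (X - l$running_mean) / sqrt(l$running_var + l$eps)
        l$gamma * xhat + l$beta
      }
    },
    relu = {
      Y <- cpp_relu_fwd(X)
      dim(Y) <- dim(X)
      if (training) l$cache <- Y
      Y
    },
    sigmoid = {
      Y <- 1 / (1 + exp(-X))
      if (training) l$cache <- Y
      Y
    },
    pool = {
      d <- dim(X)
      if (d[2] < l$kernel) {
        stop(sprintf("pool: input length %d < filter size %d",
                     d[2], l$kernel), call. = FALSE)
      }
      K <- l$kernel
      if (l$kind == "max") {
        out <- cpp_maxpool_fwd(X, K, l$stride)
        if (training) l$cache <- list(arg = out$arg, l_in = d[2])
        out$Y
      } else {
        ic <- window_plan(l, d[1], d[2], d[3])
        Y <- X[ic$idx_k[[1L]]]
        for (kk in seq_len(K)[-1L]) Y <- Y + X[ic$idx_k[[kk]]]
        Y <- Y / K
        if (training) l$cache <- list(ic = ic, dims = d)
        dim(Y) <- c(d[1], ic$l_out, d[3])
        Y
      }
    },
    flatten = {
      d <- dim(X)
      l$cache <- d
      dim(X) <- c(prod(d[-length(d)]), d[length(d)])
      X
    },
    dense = {
      if (training) l$cache <- X
      l$W %*% X + l$b
    },
    stop("unknown layer type ", l$type)
  )
}

layer_backward <- function(l, dY) {
  switch(l$type,
    conv1d = {
      cc <- l$cache
      dim(dY) <- c(l$c_out, cc$l_out * cc$B)
      out <- cpp_conv_bwd(dY, cc$Xcol, l$W, l$c_in, cc$l_in, cc$B,
                          l$kernel, l$stride, l$padding)
      l$gW <- out$gW
      out$dX
    },
    batchnorm = {
      cc <- l$cache
      out <- cpp_bn_bwd(dY, cc$xhat, cc$sdv, l$gamma, l$channels)
      l$ggamma <- as.numeric(out$ggamma)
      l$gbeta <- as.numeric(out$gbeta)
      dX <- out$dX
      dim(dX) <- dim(dY)
      dX
    },
    relu = {
      dX <- cpp_relu_bwd(dY, l$cache)
      dim(dX) <- dim(dY)
      dX
    },
    sigmoid = dY * l$cache * (1 - l$cache),
    pool = {
      cc <- l$cache
      if (l$kind == "max") {
        cpp_maxpool_bwd(dY, cc$arg, cc$l_in, l$kernel, l$stride)
      } else {
        ic <- cc$ic
        dX <- numeric(prod(cc$dims))
        dYv <- as.numeric(dY) / l$kernel
        for (kk in seq_len(l$kernel)) {
          dX[ic$idx_k[[kk]]] <- dX[ic$idx_k[[kk]]] + dYv
        }
        dim(dX) <- cc$dims
        dX
      }
    },
    flatten = {
      dim(dY) <- l$cache
      dY
    },
    dense = {
      l$gW <- tcrossprod(dY, l$cache)
      l$gb <- .rowSums(dY, nrow(dY), ncol(dY))
      crossprod(l$W, dY)
    },
    stop("unknown layer type ", l$type)
  )
}

layer_step <- function(l, lr, momentum) {
  for (nm in layer_params(l)) {
    g <- get(paste0("g", nm), envir = l)
    v <- momentum * get(paste0("v", nm), envir = l) - lr * g
    assign(paste0("v", nm), v, envir = l)
    assign(nm, get(nm, envir = l) + v, envir = l)
  }
  invisible(l)
}

layers_forward <- function(layers, X, training = FALSE) {
  for (l in layers) X <- layer_forward(l, X, training)
  X
}

layers_backward <- function(layers, dY) {
  for (l in rev(layers)) dY <- layer_backward(l, dY)
  dY
}

layers_step <- function(layers, lr, momentum) {
  for (l in layers) layer_step(l, lr, momentum)
  invisible(layers)
}

layers_state <- function(layers) {
  lapply(layers, function(l) {
    st <- lapply(layer_state_names(l), get, envir = l)
    names(st) <- layer_state_names(l)
    st
  })
}

layers_set_state <- function(layers, state) {
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    for (nm in names(state[[i]])) assign(nm, state[[i]][[nm]],
                                         envir = layers[[i]])
  }
  invisible(layers)
}
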
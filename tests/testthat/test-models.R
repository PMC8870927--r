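test_that("backbone shape arithmetic matches a sliding-window oracle", {
  # brute force: slide the window explicitly and count placements
  oracle_len <- function(len, k, p, s) {
    padded <- len + 2 * p
    count <- 0L
    pos <- 1L
    while (pos + k - 1L <= padded) {
      count <- count + 1L
      pos <- pos + s
    }
    count
  }
  set.seed(11)
  for (i in 1:200) {
    len <- sample(5:200, 1)
    k <- sample(1:5, 1)
    p <- sample(0:2, 1)
    s <- sample(1:3, 1)
    if (len + 2 * p < k) next
    spec <- backbone_spec(list(list(name = "C", type = "conv",
                                    filters = 4L, kernel = k,
                                    padding = p, stride = s)))
    got <- backbone_output_shape(spec, c(3, len))
    expect_identical(got$length[2], oracle_len(len, k, p, s))
  }
})

test_that("too-short inputs produce a shape error naming the layer", {
  expect_error(backbone_output_shape(backbone_spec(), c(10, 9)), "Pool")
  expect_error(backbone_output_shape(backbone_spec(), c(10, 4)), "Conv2")
})

test_that("backbone forward is deterministic, seeded, and shape-checked", {
  set.seed(123)
  X <- array(rnorm(5 * 10 * 100), c(5, 10, 100))
  b1 <- build_backbone(seed = 42)
  b2 <- build_backbone(seed = 42)
  f1 <- backbone_features(b1, X)
  f2 <- backbone_features(b2, X)
  expect_equal(dim(f1), c(5, 128))
  expect_identical(f1, f2)
  b3 <- build_backbone(seed = 43)
  expect_false(identical(f1, backbone_features(b3, X)))

  Xbad <- array(rnorm(5 * 10 * 99), c(5, 10, 99))
  expect_error(backbone_features(b1, Xbad), "10 x 100")
})

test_that("the full regressor yields finite scalars and aliases its backbone", {
  m <- build_1dcnn(seed = 7)
  set.seed(5)
  X <- array(rnorm(5 * 10 * 100), c(5, 10, 100))
  p <- predict(m, X)
  expect_length(p, 5)
  expect_true(all(is.finite(p)))

  # mutation through the extracted view is visible in the model
  bb <- extract_backbone(m)
  bb$layers[[1]]$W <- bb$layers[[1]]$W * 2
  expect_false(identical(p, predict(m, X)))
})

test_that("random-forest regressor honours its contracts", {
  set.seed(21)
  X <- matrix(runif(200 * 5), 200)
  # constant labels -> constant prediction
  cfit <- fit_rfr(X, rep(0.3, 200), rfr_params(seed = 1))
  expect_equal(predict(cfit, X[1:10, ]), rep(0.3, 10))

  # predictions bounded by the training label range
  y <- runif(200)
  fit <- fit_rfr(X, y, rfr_params(seed = 1))
  pr <- predict(fit, matrix(runif(500 * 5, -2, 3), 500))
  expect_true(all(pr >= min(y) & pr <= max(y)))

  # hand-built stump oracle: one binary feature, bootstrap off,
  # depth 1 -> exact group means
  Xb <- matrix(rep(c(0, 1), each = 20), ncol = 1)
  yb <- rep(c(0, 1), each = 20)
  stump <- fit_rfr(Xb, yb, rfr_params(n_trees = 1, max_depth = 1,
                                      min_samples_split = 2, mtry = 1,
                                      bootstrap = FALSE, seed = 1))
  expect_equal(predict(stump, matrix(c(0, 1), ncol = 1)), c(0, 1))

  expect_error(fit_rfr(X[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("averaging more trees does not increase prediction variance", {
  set.seed(31)
  X <- matrix(runif(80 * 5), 80)
  y <- X[, 1] + rnorm(80, 0, 0.2)
  q <- matrix(runif(5), 1)
  pred_with <- function(n_trees) {
    vapply(1:50, function(s) {
      predict(fit_rfr(X, y, rfr_params(n_trees = n_trees, seed = s)), q)
    }, numeric(1))
  }
  expect_lt(var(pred_with(100)), var(pred_with(5)))
})

test_that("SVR fits and respects its interface", {
  set.seed(41)
  X <- matrix(runif(100 * 10), 100)
  fit <- fit_svr(X, rep(0.4, 100), svr_params(C = 10, gamma = 0.1))
  expect_true(all(abs(predict(fit, X) - 0.4) <= 0.1 + 1e-6))
  expect_error(fit_svr(X[, 1:9], rep(0.4, 100)), "10 feature columns")
})

test_that("BPNN converges on a linear toy problem", {
  set.seed(51)
  X <- cbind(runif(200), matrix(0, 200, 9))
  y <- X[, 1]
  fit <- fit_bpnn(X, y, n_epochs = 1000, seed = 1)
  expect_lt(min(fit$loss), 1e-2)
  # output layer is a single neuron
  expect_equal(nrow(fit$layers[[3]]$W), 1L)
  expect_length(predict(fit, X[1:7, ]), 7)
  expect_error(fit_bpnn(X[, 1:4], y), "expected 10")
})

test_that("hybrid prediction composes backbone and forest", {
  ds <- tiny_dataset(seed = 61, n_days = 2, reps = 1)
  mc <- to_multichannel(ds)
  bb <- build_backbone(seed = 1)
  feats <- backbone_features(bb, mc)
  expect_equal(ncol(feats), 128)

  cfor <- fit_rfr(feats, rep(0.2, nrow(feats)), rfr_params(seed = 1))
  expect_equal(hybrid_predict(bb, cfor, mc), rep(0.2, length(ds)))

  # inference is deterministic
  rfor <- fit_rfr(feats, mc$labels, rfr_params(seed = 1))
  expect_identical(hybrid_predict(bb, rfor, mc),
                   hybrid_predict(bb, rfor, mc))

  # feature-width mismatch is caught
  small <- fit_rfr(feats[, 1:5], mc$labels, rfr_params(seed = 1))
  expect_error(hybrid_predict(bb, small, mc), "128")
})
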
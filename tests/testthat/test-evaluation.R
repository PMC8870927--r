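test_that("metrics match hand-computed values", {
  y <- c(0, 1, 2)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(0, 0, 0)), -1.5)

  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(mae(c(0, 0), c(3, 4)), 3.5)
  expect_equal(rmse(y, y), 0)
  expect_equal(mae(y, y), 0)

  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_error(rmse(1:3, 1:4), "equal length")
  expect_error(mae(numeric(0), numeric(0)), "at least one")
  expect_error(rmse(c(1, NA), c(1, 2)), "finite")
})

test_that("metrics agree with explicit-loop oracles on random inputs", {
  loop_r2 <- function(y, yh) {
    ss_res <- 0; ss_tot <- 0; yb <- sum(y) / length(y)
    for (i in seq_along(y)) {
      ss_res <- ss_res + (y[i] - yh[i])^2
      ss_tot <- ss_tot + (y[i] - yb)^2
    }
    1 - ss_res / ss_tot
  }
  loop_rmse <- function(y, yh) {
    s <- 0
    for (i in seq_along(y)) s <- s + (y[i] - yh[i])^2
    sqrt(s / length(y))
  }
  loop_mae <- function(y, yh) {
    s <- 0
    for (i in seq_along(y)) s <- s + abs(y[i] - yh[i])
    s / length(y)
  }
  set.seed(17)
  for (case in 1:1000) {
    n <- sample(2:40, 1)
    y <- rnorm(n)
    yh <- y + rnorm(n, 0, runif(1, 0, 2))
    expect_equal(r_squared(y, yh), loop_r2(y, yh), tolerance = 1e-12)
    expect_equal(rmse(y, yh), loop_rmse(y, yh), tolerance = 1e-12)
    expect_equal(mae(y, yh), loop_mae(y, yh), tolerance = 1e-12)
    expect_gte(rmse(y, yh), mae(y, yh) - 1e-12)
  }
})

test_that("percent scale is a pure rescaling and R-squared is invariant", {
  set.seed(23)
  y <- runif(50, 0, 0.6)
  yh <- y + rnorm(50, 0, 0.03)
  rep_f <- metrics_report(y, yh, scale = "fraction")
  rep_p <- metrics_report(y, yh, scale = "percent")
  expect_equal(rep_p$rmse, 100 * rep_f$rmse)
  expect_equal(rep_p$mae, 100 * rep_f$mae)
  expect_equal(rep_p$r2, rep_f$r2)
  expect_equal(rep_p$rmse, rmse(100 * y, 100 * yh))
})

test_that("evaluate_model builds the right inputs per model family", {
  ds <- tiny_dataset(seed = 31, n_days = 2, reps = 2)
  sp <- split_by_day(ds, 1)
  sv <- build_sv_matrix(sp$train)

  # a perfect oracle scores (1, 0, 0)
  oracle <- structure(list(labels = NULL), class = "label_oracle")
  registerS3method("predict", "label_oracle",
                   function(object, newdata, ...) {
                     build_sv_matrix(sp$test)$labels
                   })
  rep <- evaluate_model(oracle, sp$test)
  expect_equal(rep$r2, 1)
  expect_equal(rep$rmse, 0)
  expect_equal(rep$mae, 0)
  expect_equal(rep$n, 10 * length(sp$test))
  expect_equal(rep$granularity, "row")

  # per-sample granularity averages the 10 rows of each sample
  rfit <- fit_rfr(sv$rows, sv$labels, rfr_params(seed = 1))
  rep_row <- evaluate_model(rfit, sp$test, granularity = "row")
  rep_ps <- evaluate_model(rfit, sp$test, granularity = "per_sample")
  expect_equal(rep_ps$n, length(sp$test))
  expect_equal(rep_row$n, 10 * length(sp$test))

  sv_te <- build_sv_matrix(sp$test)
  pred_rows <- predict(rfit, sv_te$rows)
  by_sample <- tapply(pred_rows,
                      factor(sv_te$sample_index,
                             levels = unique(sv_te$sample_index)), mean)
  y_s <- sv_te$labels[!duplicated(sv_te$sample_index)]
  expect_equal(rep_ps$mae, 100 * mae(y_s, as.numeric(by_sample)))

  # convolutional models are always scored per sample
  cnn <- build_1dcnn(seed = 1)
  rep_cnn <- evaluate_model(cnn, sp$test)
  expect_equal(rep_cnn$granularity, "per_sample")
  expect_equal(rep_cnn$n, length(sp$test))
})

test_that("PCA projection matches a covariance eigendecomposition", {
  set.seed(41)
  # 20 rows standing for 2 samples x 10 time points
  rows <- matrix(rnorm(200, sd = rep(c(3, 1), each = 100)), 20, 10)
  sv <- structure(list(rows = rows,
                       labels = rep(c(0, 0.1), each = 10),
                       sample_index = rep(c("a", "b"), each = 10)),
                  class = "sv_matrix")
  p <- pca_projection(sv, n_components = 3, per_proportion = 1,
                      subset_seed = 1)
  ev <- eigen(cov(rows), symmetric = TRUE)$values
  # prcomp divides by n-1 as cov() does
  expect_equal(p$explained, ev / sum(ev), tolerance = 1e-8)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_true(all(p$explained >= 0))
  expect_equal(sum(p$explained), 1)

  # reconstruction from all components reproduces the centered data
  recon <- p$fit$x %*% t(p$fit$rotation)
  centered <- scale(rows, center = TRUE, scale = FALSE)
  expect_lt(max(abs(recon - centered)), 1e-8)

  expect_error(pca_projection(sv, n_components = 11), "exceeds")
})

test_that("PCA subsetting draws the configured design", {
  ds <- full_design(seed = 1)
  sv <- build_sv_matrix(subset_dataset(ds, sessions = "A"))
  p <- pca_projection(sv, n_components = 3, per_proportion = 9,
                      subset_seed = 2)
  expect_length(p$sample_ids, 63)
  expect_equal(nrow(p$scores), 630)
  # data varying along one direction: first component dominates
  one <- structure(list(rows = cbind(rnorm(30, sd = 5),
                                     matrix(0, 30, 9)),
                        labels = rep(0, 30),
                        sample_index = rep(sprintf("x%d", 1:3), each = 10)),
                   class = "sv_matrix")
  p1 <- pca_projection(one, n_components = 1, per_proportion = 3,
                       subset_seed = 1)
  expect_gt(p1$explained[1], 1 - 1e-12)
})
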
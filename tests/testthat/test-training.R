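# Training uses a reduced problem size (a 2-4 day simulated design and a
# few dozen epochs) so the whole file runs in seconds; the full 10-day
# protocol is exercised in test-acceptance.R.

train_fixture <- function(seed = 1, n_days = 4) {
  ds <- tiny_dataset(seed = seed, n_days = n_days, reps = 1)
  to_multichannel(ds)
}

test_that("training is deterministic given the seed", {
  mc <- train_fixture()
  hy <- train_hyper(batch_size = 7, n_epochs = 30, seed = 9)
  m1 <- build_1dcnn(seed = 2)
  h1 <- train_1dcnn(m1, mc, hy)
  m2 <- build_1dcnn(seed = 2)
  h2 <- train_1dcnn(m2, mc, hy)
  expect_identical(h1$loss, h2$loss)
  expect_identical(predict(m1, mc), predict(m2, mc))
  expect_length(h1$loss, 30)
  expect_true(all(is.finite(h1$loss)))
  # checkpoints at the cadence plus the final epoch
  expect_identical(names(h1$checkpoints), c("20", "30"))
})

test_that("compiled and reference engines agree", {
  mc <- train_fixture()
  hy <- train_hyper(batch_size = 7, n_epochs = 8, seed = 4)
  m1 <- build_1dcnn(seed = 3)
  h1 <- train_1dcnn(m1, mc, hy, engine = "reference")
  m2 <- build_1dcnn(seed = 3)
  h2 <- train_1dcnn(m2, mc, hy, engine = "compiled")
  expect_equal(h1$loss, h2$loss, tolerance = 1e-12)
  expect_equal(predict(m1, mc), predict(m2, mc), tolerance = 1e-12)
})

test_that("zero learning rate leaves the loss exactly constant", {
  mc <- train_fixture()
  n <- length(mc$labels)
  # full-batch updates so batch statistics are identical every epoch
  hy <- train_hyper(batch_size = n, n_epochs = 5, initial_lr = 0, seed = 1)
  h <- train_1dcnn(build_1dcnn(seed = 1), mc, hy)
  # constant up to floating-point summation order over the shuffled batch
  expect_equal(h$loss, rep(h$loss[1], 5), tolerance = 1e-12)
})

test_that("checkpoint restore reproduces forward outputs exactly", {
  mc <- train_fixture()
  m <- build_1dcnn(seed = 5)
  h <- train_1dcnn(m, mc, train_hyper(batch_size = 7, n_epochs = 40,
                                      seed = 5))
  p_final <- predict(m, mc)
  restore_checkpoint(h, 20)
  p20a <- predict(m, mc)
  restore_checkpoint(h, 40)
  expect_equal(predict(m, mc), p_final, tolerance = 1e-12)
  restore_checkpoint(h, 20)
  expect_identical(predict(m, mc), p20a)
  expect_error(restore_checkpoint(h, 33), "available")
})

test_that("convergence-epoch selection follows its plateau rule", {
  # constant history: first epoch with a full smoothing window
  expect_equal(select_convergence_epoch(rep(1, 200), window = 50), 50L)

  # steep decrease, then exactly flat from epoch 50
  loss <- c(seq(100, 1, length.out = 49), rep(1, 151))
  e <- select_convergence_epoch(loss, window = 50)
  expect_gte(e, 50L)
  expect_lte(e, 100L)

  # selected epoch is non-increasing in rel_tol
  set.seed(8)
  noisy <- exp(-seq(0, 5, length.out = 300)) + abs(rnorm(300, 0, 0.01))
  es <- vapply(c(0.005, 0.02, 0.1, 0.5),
               function(tol) select_convergence_epoch(noisy, rel_tol = tol),
               integer(1))
  expect_true(all(diff(es) <= 0))

  expect_error(select_convergence_epoch(c(1, NA, 1), window = 2),
               "non-finite")
  expect_error(select_convergence_epoch(rep(1, 10), window = 50),
               "shorter")
})

test_that("grid search evaluates the whole grid and breaks ties in order", {
  set.seed(71)
  X <- matrix(runif(60 * 10), 60)
  y <- X[, 1] * 0.5
  one <- grid_search_cv("svr", list(C = 10, gamma = 0.1), X, y, seed = 1)
  expect_equal(one$best, list(C = 10, gamma = 0.1))
  expect_equal(nrow(one$table), 1)

  cv <- grid_search_cv("svr", svr_grid(), X, y, seed = 1)
  expect_equal(nrow(cv$table), 48)
  expect_true(all(c("mean_mse", "fold1", "fold2", "fold3") %in%
                    names(cv$table)))
  expect_equal(cv$best_mse, min(cv$table$mean_mse))

  # enumeration-order invariance of the optimum value; ties (e.g. the
  # saturated-C plateau of the SVR) are broken by first-in-grid order
  rev_cv <- grid_search_cv("svr", lapply(svr_grid(), rev), X, y, seed = 1)
  expect_equal(rev_cv$best_mse, cv$best_mse)
  first_min <- which(cv$table$mean_mse == min(cv$table$mean_mse))[1]
  expect_equal(cv$best, as.list(cv$table[first_min, c("C", "gamma")]))

  expect_error(grid_search_cv("svr", list(), X, y), "empty grid")
})

test_that("grid search recovers a planted tree depth against underfitting", {
  picks <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 150
    X <- matrix(runif(n * 6), n)
    leaf <- 4 * (X[, 1] > 0.5) + 2 * (X[, 2] > 0.5) + (X[, 3] > 0.5)
    y <- 3 * leaf + rnorm(n, 0, 0.5)
    cv <- grid_search_cv("rfr", list(max_depth = c(1, 2, 3),
                                     min_samples_split = 7),
                         X, y, seed = seed)
    cv$best$max_depth
  }, numeric(1))
  expect_gte(sum(picks == 3), 16)
})

test_that("assemble_hybrid freezes the selected checkpoint and fits 128-wide", {
  mc <- train_fixture(seed = 12, n_days = 4)
  m <- build_1dcnn(seed = 12)
  h <- train_1dcnn(m, mc, train_hyper(batch_size = 7, n_epochs = 60,
                                      seed = 12))
  expect_error(assemble_hybrid(h, mc, epoch = 13), "checkpoint")

  hy <- assemble_hybrid(h, mc, epoch = 60,
                        grid = list(max_depth = c(3, 5),
                                    min_samples_split = c(7, 14)),
                        seed = 12)
  expect_s3_class(hy, "enose_hybrid")
  expect_equal(length(hy$forest$feature_names), 128)
  expect_length(predict(hy, mc), length(mc$labels))
})

test_that("the forest head does not trail the dense head on training data", {
  wins <- 0L
  for (seed in 1:5) {
    ds <- tiny_dataset(seed = seed, n_days = 3, reps = 2)
    mc <- to_multichannel(ds)
    m <- build_1dcnn(seed = seed)
    h <- train_1dcnn(m, mc, train_hyper(batch_size = 14, n_epochs = 200,
                                        seed = seed))
    restore_checkpoint(h, 200)
    mae_head <- mae(mc$labels, predict(m, mc))
    hy <- assemble_hybrid(h, mc, epoch = 200,
                          grid = list(max_depth = c(5, 9),
                                      min_samples_split = c(2, 7)),
                          seed = seed)
    mae_hybrid <- mae(mc$labels, predict(hy, mc))
    if (mae_hybrid <= mae_head) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
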
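test_that("write/read round-trips a dataset exactly", {
  ds <- tiny_dataset(seed = 3, n_days = 1, reps = 1)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(length(back), length(ds))
  expect_identical(dataset_meta(back)$sample_id, dataset_meta(ds)$sample_id)
  expect_identical(dataset_meta(back)$day, dataset_meta(ds)$day)
  expect_identical(dataset_meta(back)$session, dataset_meta(ds)$session)
  expect_equal(dataset_meta(back)$proportion, dataset_meta(ds)$proportion)
  for (i in seq_along(ds$samples)) {
    expect_lt(max(abs(back$samples[[i]]$curves - ds$samples[[i]]$curves)),
              1e-9)
  }
  # reader is order-stable
  again <- read_dataset(dir)
  expect_identical(dataset_meta(again), dataset_meta(back))
})

test_that("empty dataset writes header-only files that read back empty", {
  dir <- withr::local_tempdir()
  write_dataset(enose_dataset(list()), dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(length(read_dataset(dir)), 0L)
})

test_that("reader rejects malformed files with informative errors", {
  ds <- tiny_dataset(seed = 4, n_days = 1, reps = 1)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)

  # missing manifest column
  man <- read.csv(file.path(dir, "manifest.csv"))
  write.csv(man[, setdiff(names(man), "day")],
            file.path(dir, "manifest.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), "day")
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)

  # truncated curve block (99 time points)
  cur <- read.csv(file.path(dir, "curves.csv"))
  sid <- man$sample_id[1]
  drop <- which(cur$sample_id == sid & cur$t_s == 100)
  write.csv(cur[-drop, ], file.path(dir, "curves.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), "99 time points")

  # non-positive ratio names the sample and time index
  bad <- cur
  bad[bad$sample_id == sid & bad$t_s == 5, "W3C"] <- 0
  write.csv(bad, file.path(dir, "curves.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), "t=5.*W3C")
})

test_that("validate_sample reports each violated invariant with location", {
  ds <- clean_dataset()
  good <- ds$samples[[1]]
  expect_length(validate_sample(good), 0)

  bad <- good
  bad$curves[5, 3] <- 0
  issues <- validate_sample(bad)
  expect_length(issues, 1)
  expect_match(issues, "t=5")
  expect_match(issues, "W3C")

  off <- good
  off$proportion <- 0.35
  expect_length(validate_sample(off), 0)
  expect_match(validate_sample(off, design_conformant = TRUE), "off the")

  short <- good
  short$curves <- good$curves[1:99, ]
  expect_match(validate_sample(short), "100 x 10")
})

test_that("dataset constructor enforces unique ids and shared sensors", {
  ds <- tiny_dataset(seed = 5, n_days = 1, reps = 1)
  expect_error(enose_dataset(ds$samples[c(1, 1)]), "duplicate sample_id")
  # duplicates smuggled past the constructor are refused before write
  dup <- ds
  dup$samples <- ds$samples[c(1, 1)]
  expect_error(write_dataset(dup, withr::local_tempdir()),
               "duplicate sample_id")
  s2 <- ds$samples[[2]]
  s2$sensor_names <- rev(s2$sensor_names)
  colnames(s2$curves) <- s2$sensor_names
  expect_error(enose_dataset(list(ds$samples[[1]], s2)),
               "share sensor_names")
})

test_that("subset_dataset filters by metadata and preserves order", {
  ds <- tiny_dataset(seed = 6, n_days = 3, sessions = c("A", "B"))
  a <- subset_dataset(ds, sessions = "A")
  expect_true(all(dataset_meta(a)$session == "A"))
  d12 <- subset_dataset(ds, days = 1:2)
  expect_true(all(dataset_meta(d12)$day <= 2))
  expect_identical(dataset_meta(subset_dataset(ds))$sample_id,
                   dataset_meta(ds)$sample_id)
})
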
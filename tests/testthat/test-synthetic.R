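test_that("default sensor bank matches the array layout and kinetics", {
  bank <- default_sensor_bank()
  expect_length(bank, 10)
  expect_identical(vapply(bank, `[[`, character(1), "name"),
                   default_sensor_names())
  # cross-sensitive but not identical
  loadings <- lapply(bank, `[[`, "amplitude_loadings")
  for (i in 1:9) for (j in (i + 1):10) {
    expect_false(identical(loadings[[i]], loadings[[j]]))
  }
  # every curve reaches >= 99% of its asymptote by 90 s
  taus <- vapply(bank, `[[`, numeric(1), "saturation_tau")
  expect_true(all(1 - exp(-90 / taus) >= 0.99))
})

test_that("simulate_curve follows its closed form", {
  # zero amplitude: constant baseline
  flat <- sensor_model("flat", loadings = c(0, 0, 0), tau = 20,
                       noise_sd = 0)
  expect_equal(simulate_curve(flat, 0.3), rep(1, 100))

  # A = 2 (single loading on the constant base factor), tau = 20, t = 100
  s <- sensor_model("s", loadings = c(2, 0, 0), tau = 20, noise_sd = 0)
  y <- simulate_curve(s, 0.5)
  expect_equal(y[100], 1 + 2 * (1 - exp(-5)), tolerance = 1e-9)

  # strictly monotone rise for positive amplitude, no noise
  expect_true(all(diff(y) > 0))

  # negative direction mirrors below baseline
  sn <- sensor_model("sn", loadings = c(0.5, 0, 0), tau = 20,
                     noise_sd = 0, direction = -1)
  expect_true(all(simulate_curve(sn, 0) < 1))

  expect_error(simulate_curve(s, 1.2), "\\[0, 1\\]")
  expect_error(simulate_curve(s, -0.1), "\\[0, 1\\]")

  # non-positive values are clipped with a warning
  deep <- sensor_model("deep", loadings = c(5, 0, 0), tau = 5,
                       noise_sd = 0, direction = -1)
  expect_warning(yc <- simulate_curve(deep, 0), "clipped")
  expect_true(all(yc > 0))
})

test_that("simulate_dataset reproduces the study design and is seeded", {
  full <- full_design(seed = 1)
  expect_equal(length(full), 420L)
  meta <- dataset_meta(full)
  expect_equal(sort(unique(meta$day)), 1:10)
  expect_setequal(unique(meta$session), c("A", "B"))
  expect_equal(sum(meta$session == "A"), 210L)

  one_day <- tiny_dataset(seed = 2, n_days = 1, sessions = "A", reps = 3)
  expect_equal(length(one_day), 21L)

  again <- simulate_dataset(study_design(seed = 1))
  expect_equal(again$samples[[17]]$curves, full$samples[[17]]$curves)
  expect_identical(dataset_meta(again), meta)

  # every sample satisfies the structural invariants
  issues <- unlist(lapply(full$samples, validate_sample,
                          design_conformant = TRUE))
  expect_length(issues, 0)
})

test_that("noise-free stable values are strictly monotone in proportion", {
  ds <- clean_dataset(n_days = 1, reps = 1)  # 7 proportions, no drift
  meta <- dataset_meta(ds)
  ord <- order(meta$proportion)
  sv_means <- t(vapply(ds$samples[ord],
                       function(s) colMeans(extract_stable_values(s)),
                       numeric(10)))
  n_monotone <- sum(apply(sv_means, 2, function(col) {
    all(diff(col) > 0) || all(diff(col) < 0)
  }))
  expect_gte(n_monotone, 8)
})

test_that("plateau noise has the configured scale", {
  sensor <- sensor_model("s", loadings = c(1, 0.5, 0.2), tau = 18,
                         noise_sd = 0.02)
  set.seed(99)
  sds <- replicate(1000, sd(simulate_curve(sensor, 0.3)[91:100]))
  expect_gt(mean(sds), 0.02 / 2)
  expect_lt(mean(sds), 0.02 * 2)
})

test_that("pure vs most-adulterated samples separate on one stable value", {
  ds <- full_design(seed = 1)
  meta <- dataset_meta(ds)
  sv_w5s <- vapply(ds$samples,
                   function(s) mean(extract_stable_values(s)[, "W5S"]),
                   numeric(1))
  expect_gt(min(sv_w5s[meta$proportion == 0.6]),
            max(sv_w5s[meta$proportion == 0]))
})

test_that("sensor bank round-trips through YAML", {
  bank <- default_sensor_bank(noise_sd = 0.05)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sensor_bank(bank, path)
  back <- read_sensor_bank(path)
  expect_equal(lapply(back, unclass), lapply(bank, unclass),
               tolerance = 1e-12)
})
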
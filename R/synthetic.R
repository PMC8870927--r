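#' Sensor response model
#'
#' Describes one MOS sensor of the simulated array.  The sensor responds to
#' `length(amplitude_loadings)` latent volatile factors; its response curve
#' is a saturating exponential above (direction `+1`) or below (`-1`) the
#' G/G0 baseline of 1, with additive Gaussian measurement noise:
#'
#'   `curve(t) = baseline + direction * A * (1 - exp(-t / tau)) + eps_t`
#'
#' where `A` is the amplitude produced by the latent factor intensities
#' (see [simulate_curve()]) and `eps_t ~ N(0, noise_sd^2)`.
#'
#' @param name Sensor name.
#' @param loadings Nonnegative loadings on the latent volatile factors.
#' @param tau Saturation time constant in seconds (> 0).
#' @param noise_sd Measurement noise SD in ratio units (>= 0).
#' @param direction `+1` (response above baseline) or `-1` (below).
#' @param baseline Ratio at zero gas, 1 by construction of G/G0.
#' @return Object of class `sensor_model`.
#' @export
sensor_model <- function(name, loadings, tau, noise_sd = 0.02,
                         direction = 1, baseline = 1) {
  stopifnot(tau > 0, noise_sd >= 0, direction %in% c(-1, 1))
  structure(list(name = name, baseline = baseline,
                 amplitude_loadings = as.numeric(loadings),
                 saturation_tau = tau, noise_sd = noise_sd,
                 direction = direction),
            class = "sensor_model")
}

#' Default bank of 10 simulated MOS sensors
#'
#' Loadings on three latent volatile factors (a base meat-volatile factor,
#' an adulterant-linear factor and an adulterant-saturating factor) encode
#' the cross-sensitivity of the array: sensors are mutually correlated but
#' none are identical, and the three conductivity-decreasing sensors (W1C,
#' W3C, W5C) respond below baseline as real PEN3 arrays do.  Time constants
#' lie in \[15, 19.5\] s so every noise-free curve reaches at least 99
#' percent of its asymptote by 90 s, matching the observed plateau after
#' 90 s.
#'
#' @param noise_sd Measurement noise SD applied to every sensor.
#' @return List of 10 [sensor_model()] objects in canonical array order.
#' @export
default_sensor_bank <- function(noise_sd = 0.02) {
  # Loadings are (base meat volatiles, adulterant-linear,
  # adulterant-saturating); the adulterant-linear term dominates for the
  # strong sensors, since the proportion signal rides on the change in the
  # volatile mix rather than on the constant beef background.
  spec <- list(
    list("W1C", c(0.10, 0.30, 0.06), 16.0, -1),
    list("W5S", c(0.80, 2.50, 0.50), 18.0, +1),
    list("W3C", c(0.08, 0.22, 0.05), 15.5, -1),
    list("W6S", c(0.05, 0.12, 0.03), 17.0, +1),
    list("W5C", c(0.07, 0.20, 0.04), 16.5, -1),
    list("W1S", c(0.40, 1.50, 0.30), 19.0, +1),
    list("W1W", c(0.60, 2.00, 0.40), 18.5, +1),
    list("W2S", c(0.30, 1.00, 0.20), 17.5, +1),
    list("W2W", c(0.50, 1.60, 0.35), 18.0, +1),
    list("W3S", c(0.06, 0.15, 0.04), 16.0, +1)
  )
  lapply(spec, function(s) {
    sensor_model(name = s[[1]], loadings = s[[2]], tau = s[[3]],
                 noise_sd = noise_sd, direction = s[[4]])
  })
}

#' Latent volatile-factor intensities for an adulterated proportion
#'
#' Factor 1 is the base meat-volatile level (constant), factor 2 grows
#' linearly with the adulterant proportion and factor 3 grows as its square
#' root (a mild saturating nonlinearity).  All three are monotone
#' non-decreasing in the proportion, which makes every sensor's stable
#' value strictly monotone in the proportion.
#'
#' @param proportion Fraction in \[0, 1\].
#' @return Numeric vector of 3 intensities.
#' @export
factor_intensities <- function(proportion) {
  c(1, proportion, sqrt(proportion))
}

#' Simulate one sensor response curve
#'
#' Evaluates the saturating-exponential response of a [sensor_model()] at
#' seconds 1..100, using the current RNG state for the measurement noise.
#' The amplitude is `A = sum(loadings * intensities * (1 + day_effect))`
#' with intensities from [factor_intensities()]; `day_effect` perturbs the
#' factor intensities multiplicatively to emulate inter-day drift.  Values
#' that would be non-positive are clipped to a small positive floor with a
#' warning (ratios are physically positive).
#'
#' @param sensor A `sensor_model`.
#' @param proportion Adulterated proportion, fraction in \[0, 1\].
#' @param day_effect Numeric vector (one entry per latent factor) of
#'   relative intensity shifts; `c(0, 0, 0)` means no drift.
#' @param t Time points in seconds (default 1..100).
#' @return Numeric vector of G/G0 ratios, one per time point.
#' @export
simulate_curve <- function(sensor, proportion, day_effect = c(0, 0, 0),
                           t = 1:100) {
  if (!is.finite(proportion) || proportion < 0 || proportion > 1) {
    stop("proportion must lie in [0, 1], got ", format(proportion),
         call. = FALSE)
  }
  g <- factor_intensities(proportion)
  amp <- sum(sensor$amplitude_loadings * g * (1 + day_effect))
  y <- sensor$baseline +
    sensor$direction * amp * (1 - exp(-t / sensor$saturation_tau))
  if (sensor$noise_sd > 0) {
    y <- y + stats::rnorm(length(t), 0, sensor$noise_sd)
  }
  if (any(y <= 0)) {
    warning("clipped ", sum(y <= 0), " non-positive ratio value(s) for ",
            sensor$name, call. = FALSE)
    y[y <= 0] <- 1e-3
  }
  y
}

#' Study design for simulation
#'
#' @param n_days Number of measurement days.
#' @param sessions Subset of `c("A", "B")` (morning/afternoon sessions).
#' @param proportions Adulterated proportions as fractions.
#' @param samples_per Samples per proportion per day per session.
#' @param seed Integer seed driving the whole simulation.
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_days = 10, sessions = c("A", "B"),
                         proportions = seq(0, 0.6, by = 0.1),
                         samples_per = 3, seed = 1) {
  stopifnot(n_days >= 1, samples_per >= 1, length(sessions) >= 1,
            all(sessions %in% c("A", "B")),
            all(proportions >= 0 & proportions <= 1))
  structure(list(n_days = as.integer(n_days), sessions = sessions,
                 proportions = proportions,
                 samples_per = as.integer(samples_per),
                 seed = as.integer(seed)),
            class = "study_design")
}

# Deterministic seed mixing (kept below 2^31); exact in double arithmetic.
mix_seed <- function(seed, ...) {
  m <- 2147483629
  x <- (as.numeric(seed) %% m)
  for (v in c(...)) {
    x <- (x * 48271 + as.numeric(v) * 7919 + 1) %% m
  }
  as.integer(x)
}

#' Simulate a full E-nose dataset
#'
#' Replicates the study layout of `design`: for every (day, session) a
#' latent day effect is drawn once and shared by all samples measured in
#' that session, then each sample's 10 curves are simulated with
#' [simulate_curve()].  The day effect has a component shared across the
#' three volatile factors (global intensity drift: sample mass, headspace
#' equilibration, temperature) plus a smaller independent per-factor
#' component.  Seeding is hierarchical (seed, then per day/session, then
#' per sample), so the same global seed always yields the identical
#' dataset and any (day, session) block is reproducible on its own.
#'
#' @param design A [study_design()].
#' @param bank Sensor bank, default [default_sensor_bank()].
#' @param drift_shared_sd SD of the factor-shared day drift (relative).
#' @param drift_factor_sd SD of the per-factor day drift (relative).
#' @return An [enose_dataset()] with
#'   `n_days * length(sessions) * length(proportions) * samples_per`
#'   samples.
#' @export
simulate_dataset <- function(design, bank = default_sensor_bank(),
                             drift_shared_sd = 0.05,
                             drift_factor_sd = 0.02) {
  stopifnot(inherits(design, "study_design"))
  n_factors <- length(bank[[1L]]$amplitude_loadings)
  sensor_names <- vapply(bank, `[[`, character(1), "name")
  samples <- list()
  k <- 0L
  for (day in seq_len(design$n_days)) {
    for (si in seq_along(design$sessions)) {
      sess <- design$sessions[si]
      dseed <- mix_seed(design$seed, day, si)
      set.seed(dseed)
      day_effect <- stats::rnorm(1, 0, drift_shared_sd) +
        stats::rnorm(n_factors, 0, drift_factor_sd)
      idx <- 0L
      for (p in design$proportions) {
        for (rep in seq_len(design$samples_per)) {
          idx <- idx + 1L
          set.seed(mix_seed(dseed, idx))
          cv <- vapply(bank, simulate_curve, numeric(100),
                       proportion = p, day_effect = day_effect)
          k <- k + 1L
          samples[[k]] <- enose_sample(
            curves = cv, proportion = p, day = day, session = sess,
            sample_id = sprintf("d%02d%s_p%02.0f_r%d", day, sess,
                                100 * p, rep),
            sensor_names = sensor_names)
        }
      }
    }
  }
  enose_dataset(samples, design = design)
}

#' Serialize / read a sensor bank as YAML
#'
#' @param bank List of [sensor_model()] objects.
#' @param path YAML file path.
#' @return `write_sensor_bank` returns `path` invisibly; `read_sensor_bank`
#'   returns the sensor bank.
#' @export
write_sensor_bank <- function(bank, path) {
  yaml::write_yaml(lapply(bank, unclass), path)
  invisible(path)
}

#' @rdname write_sensor_bank
#' @export
read_sensor_bank <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s) {
    sensor_model(name = s$name, loadings = s$amplitude_loadings,
                 tau = s$saturation_tau, noise_sd = s$noise_sd,
                 direction = s$direction, baseline = s$baseline)
  })
}
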
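# Shared fixtures, built in code.  tiny_dataset() is a small simulated
# study (cheap); full_design() is the complete 10-day x 2-session layout,
# memoised because several files need its bookkeeping.

tiny_dataset <- function(seed = 1, n_days = 2, sessions = "A",
                         reps = 1, noise_sd = 0.02) {
  simulate_dataset(
    study_design(n_days = n_days, sessions = sessions,
                 samples_per = reps, seed = seed),
    bank = default_sensor_bank(noise_sd = noise_sd))
}

.fixture_env <- new.env()

full_design <- function(seed = 1) {
  key <- paste0("full_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_dataset(study_design(seed = seed))
  }
  .fixture_env[[key]]
}

# A noise- and drift-free simulator for deterministic feature checks.
clean_dataset <- function(seed = 1, n_days = 1, sessions = "A", reps = 1) {
  simulate_dataset(
    study_design(n_days = n_days, sessions = sessions, samples_per = reps,
                 seed = seed),
    bank = default_sensor_bank(noise_sd = 0),
    drift_shared_sd = 0, drift_factor_sd = 0)
}

# Hand-made sample with arbitrary curves (bypasses simulation).
manual_sample <- function(curves, proportion = 0.1, day = 1,
                          session = "A", sample_id = "s1") {
  enose_sample(curves = curves, proportion = proportion, day = day,
               session = session, sample_id = sample_id)
}
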
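#' Configuration of a full model-comparison experiment
#'
#' Experiment "A" trains on the first 7 of 10 days of the morning session
#' (147 training / 63 test samples, batch size 49); experiment "B" trains
#' on the first 3 days of the afternoon session (63 / 147, batch size 21).
#' All other protocol constants come from the package defaults and can be
#' overridden.
#'
#' @param experiment `"A"` or `"B"`, or `NULL` to set fields manually.
#' @param seed Global seed (simulation, training, grid search).
#' @param train_days,batch_size,session Override the per-experiment
#'   defaults.
#' @param n_epochs Training epochs for the convolutional model.
#' @param noise_sd Simulator measurement-noise SD.
#' @param models Subset of `c("svr", "rfr", "bpnn", "1dcnn", "1dcnn-rfr")`.
#' @param granularity Evaluation granularity for stable-value models.
#' @param outdir Optional output directory for CSV reports.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("A", "B"), seed = 1L,
                              train_days = NULL, batch_size = NULL,
                              session = NULL, n_epochs = 1100L,
                              noise_sd = 0.02,
                              models = c("svr", "rfr", "bpnn", "1dcnn",
                                         "1dcnn-rfr"),
                              granularity = "row", outdir = NULL) {
  experiment <- match.arg(experiment)
  known <- c("svr", "rfr", "bpnn", "1dcnn", "1dcnn-rfr")
  bad <- setdiff(models, known)
  if (length(bad)) {
    stop("unknown model name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    experiment = experiment,
    seed = as.integer(seed),
    train_days = if (is.null(train_days)) {
      if (experiment == "A") 7L else 3L
    } else as.integer(train_days),
    batch_size = if (is.null(batch_size)) {
      if (experiment == "A") 49L else 21L
    } else as.integer(batch_size),
    session = if (is.null(session)) {
      if (experiment == "A") "A" else "B"
    } else session,
    n_epochs = as.integer(n_epochs),
    noise_sd = noise_sd,
    models = models,
    granularity = granularity,
    outdir = outdir
  ), class = "experiment_config")
}

#' Run a full five-model comparison experiment
#'
#' Simulates the complete study design (10 days x 2 sessions x 7
#' proportions x 3 replicates) with the configured seed, keeps the
#' configured session, splits by day, trains every requested model with
#' the standard protocol (3-fold grid search for the SVR and forest, SGD
#' for the networks, convergence-checkpoint selection and frozen-backbone
#' forest for the hybrid), and evaluates all of them on the held-out days.
#'
#' @param config An [experiment_config()].
#' @param dataset Optional pre-built [enose_dataset()] (e.g. real data);
#'   when supplied the simulation step is skipped and the configured
#'   session filter is still applied.
#' @return List with `metrics` (one row per model: R2, RMSE_pct, MAE_pct),
#'   `selected` (chosen hyperparameters per model), `history` (CNN loss),
#'   `predictions` (per-model predicted vs actual on the test set) and the
#'   `config`.  If `config$outdir` is set, CSV reports are written there.
#' @export
run_experiment <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(dataset)) {
    design <- study_design(seed = config$seed)
    dataset <- simulate_dataset(
      design, bank = default_sensor_bank(noise_sd = config$noise_sd))
  }
  ds <- subset_dataset(dataset, sessions = config$session)
  sp <- split_by_day(ds, config$train_days)
  sv_tr <- build_sv_matrix(sp$train)
  mc_tr <- to_multichannel(sp$train)
  mc_te <- to_multichannel(sp$test)

  metrics <- list()
  selected <- list()
  predictions <- list()
  history <- NULL

  eval_and_record <- function(name, model) {
    rep <- evaluate_model(model, sp$test, granularity = config$granularity)
    metrics[[name]] <<- data.frame(
      model = name, R2 = rep$r2, RMSE_pct = rep$rmse, MAE_pct = rep$mae,
      granularity = rep$granularity, stringsAsFactors = FALSE)
    if (inherits(model, c("enose_cnn", "enose_hybrid"))) {
      predictions[[name]] <<- data.frame(
        model = name, sample_id = mc_te$sample_index,
        actual = mc_te$labels, predicted = predict(model, mc_te),
        stringsAsFactors = FALSE)
    } else {
      sv_te <- build_sv_matrix(sp$test)
      predictions[[name]] <<- data.frame(
        model = name, sample_id = sv_te$sample_index,
        actual = sv_te$labels, predicted = predict(model, sv_te$rows),
        stringsAsFactors = FALSE)
    }
  }

  if ("svr" %in% config$models) {
    cv <- grid_search_cv("svr", svr_grid(), sv_tr$rows, sv_tr$labels,
                         seed = config$seed)
    fit <- fit_svr(sv_tr$rows, sv_tr$labels,
                   svr_params(C = cv$best$C, gamma = cv$best$gamma))
    selected$svr <- cv$best
    eval_and_record("svr", fit)
  }
  if ("rfr" %in% config$models) {
    cv <- grid_search_cv("rfr", rfr_grid(), sv_tr$rows, sv_tr$labels,
                         seed = config$seed)
    fit <- fit_rfr(sv_tr$rows, sv_tr$labels,
                   rfr_params(max_depth = cv$best$max_depth,
                              min_samples_split = cv$best$min_samples_split,
                              seed = config$seed))
    selected$rfr <- cv$best
    eval_and_record("rfr", fit)
  }
  if ("bpnn" %in% config$models) {
    fit <- fit_bpnn(sv_tr$rows, sv_tr$labels, seed = config$seed)
    selected$bpnn <- list(topology = "10-21-1")
    eval_and_record("bpnn", fit)
  }
  need_cnn <- any(c("1dcnn", "1dcnn-rfr") %in% config$models)
  if (need_cnn) {
    cnn <- build_1dcnn(seed = config$seed)
    hyper <- train_hyper(batch_size = config$batch_size,
                         n_epochs = config$n_epochs, seed = config$seed)
    history <- train_1dcnn(cnn, mc_tr, hyper)
    conv_epoch <- select_convergence_epoch(history)
    ck <- nearest_checkpoint(history, conv_epoch)
    selected$`1dcnn` <- list(convergence_epoch = conv_epoch,
                             checkpoint_epoch = ck)
    if ("1dcnn" %in% config$models) {
      restore_checkpoint(history, ck)
      eval_and_record("1dcnn", cnn)
    }
    if ("1dcnn-rfr" %in% config$models) {
      hybrid <- assemble_hybrid(history, mc_tr, epoch = ck,
                                seed = config$seed)
      selected$`1dcnn-rfr` <- c(list(epoch = hybrid$epoch),
                                hybrid$cv$best)
      eval_and_record("1dcnn-rfr", hybrid)
    }
  }

  metrics <- do.call(rbind, metrics[config$models])
  rownames(metrics) <- NULL
  predictions <- do.call(rbind, predictions[config$models])
  rownames(predictions) <- NULL
  out <- list(metrics = metrics, selected = selected,
              history = history, predictions = predictions,
              config = config)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(metrics, file.path(config$outdir, "metrics.csv"))
    data.table::fwrite(predictions,
                       file.path(config$outdir, "predictions.csv"))
    if (!is.null(history)) {
      data.table::fwrite(
        data.frame(epoch = seq_along(history$loss), loss = history$loss),
        file.path(config$outdir, "training_loss.csv"))
    }
    yaml::write_yaml(
      c(unclass(config)[setdiff(names(unclass(config)), "outdir")],
        list(selected = lapply(selected, lapply, as.character))),
      file.path(config$outdir, "experiment.yaml"))
  }
  out
}
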
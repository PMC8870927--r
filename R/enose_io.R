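#' Default PEN3-style sensor names
#'
#' Column order of the 10-sensor MOS array, used as the canonical sensor
#' ordering throughout the package.
#'
#' @return Character vector of length 10.
#' @export
default_sensor_names <- function() {
  c("W1C", "W5S", "W3C", "W6S", "W5C", "W1S", "W1W", "W2S", "W2W", "W3S")
}

#' Construct a single E-nose measurement
#'
#' An `enose_sample` holds one measurement: a 100 x 10 matrix of
#' conductivity ratios (G/G0, one row per second, one column per sensor)
#' plus the adulterated proportion (a fraction in \[0, 1\]) and the
#' measurement metadata (day, session).
#'
#' @param curves Numeric matrix, 100 time points x 10 sensors, all entries
#'   positive and finite.
#' @param proportion Adulterated proportion as a fraction (e.g. `0.3` for
#'   30 percent pork in minced beef).
#' @param day Measurement day, integer >= 1.
#' @param session Measurement session, `"A"` (morning) or `"B"`
#'   (afternoon).
#' @param sample_id Unique sample identifier string.
#' @param sensor_names Ordered sensor names matching the columns of
#'   `curves`; defaults to [default_sensor_names()].
#' @return An object of class `enose_sample`.
#' @seealso [validate_sample()], [enose_dataset()]
#' @export
enose_sample <- function(curves, proportion, day, session, sample_id,
                         sensor_names = default_sensor_names()) {
  curves <- as.matrix(curves)
  storage.mode(curves) <- "double"
  colnames(curves) <- sensor_names
  x <- structure(
    list(
      sample_id = as.character(sample_id),
      day = as.integer(day),
      session = as.character(session),
      proportion = as.numeric(proportion),
      curves = curves,
      sensor_names = as.character(sensor_names)
    ),
    class = "enose_sample"
  )
  issues <- validate_sample(x)
  if (length(issues)) {
    stop("invalid enose_sample: ", paste(issues, collapse = "; "),
         call. = FALSE)
  }
  x
}

#' Validate an E-nose sample
#'
#' Checks every structural invariant of an [enose_sample()] and returns the
#' violations as a character vector instead of raising errors, so callers
#' can report all problems at once.  An empty vector means the sample is
#' valid.
#'
#' @param sample An `enose_sample` (or a bare list with the same fields).
#' @param design_conformant If `TRUE`, additionally require the proportion
#'   to sit on the 7-level design grid 0, 0.1, ..., 0.6.
#' @return Character vector of issue descriptions (empty if valid).
#' @export
validate_sample <- function(sample, design_conformant = FALSE) {
  issues <- character()
  cv <- sample$curves
  if (!is.matrix(cv) || nrow(cv) != 100L || ncol(cv) != 10L) {
    issues <- c(issues, sprintf(
      "dimensions: curves must be 100 x 10, got %s x %s (sample %s)",
      if (is.matrix(cv)) nrow(cv) else "?",
      if (is.matrix(cv)) ncol(cv) else "?",
      sample$sample_id))
  } else {
    bad <- which(!is.finite(cv) | cv <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      for (i in seq_len(min(nrow(bad), 5L))) {
        issues <- c(issues, sprintf(
          "positivity: curves[t=%d, sensor %d (%s)] = %s is not a positive finite ratio (sample %s)",
          bad[i, 1L], bad[i, 2L],
          sample$sensor_names[bad[i, 2L]], format(cv[bad[i, 1L], bad[i, 2L]]),
          sample$sample_id))
      }
      if (nrow(bad) > 5L) {
        issues <- c(issues, sprintf("positivity: ... and %d more cells",
                                    nrow(bad) - 5L))
      }
    }
  }
  sn <- sample$sensor_names
  if (length(sn) != 10L || anyDuplicated(sn)) {
    issues <- c(issues,
                "sensor_names: must be 10 unique names")
  } else if (is.matrix(cv) && !is.null(colnames(cv)) &&
             !identical(colnames(cv), sn)) {
    issues <- c(issues,
                "sensor_names: do not match curve column order")
  }
  if (!length(sample$day) || is.na(sample$day) || sample$day < 1L) {
    issues <- c(issues, sprintf("day: must be an integer >= 1 (sample %s)",
                                sample$sample_id))
  }
  if (!sample$session %in% c("A", "B")) {
    issues <- c(issues, sprintf("session: must be \"A\" or \"B\", got \"%s\"",
                                sample$session))
  }
  p <- sample$proportion
  if (!length(p) || !is.finite(p) || p < 0 || p > 1) {
    issues <- c(issues, sprintf("proportion: must lie in [0, 1] (sample %s)",
                                sample$sample_id))
  } else if (design_conformant &&
             min(abs(p - seq(0, 0.6, by = 0.1))) > 1e-9) {
    issues <- c(issues, sprintf(
      "proportion: %s is off the design grid {0, 0.1, ..., 0.6} (sample %s)",
      format(p), sample$sample_id))
  }
  issues
}

#' Construct an E-nose dataset
#'
#' An ordered collection of [enose_sample()] objects sharing one sensor
#' array, optionally carrying the study design that generated it.
#'
#' @param samples List of `enose_sample` objects.
#' @param design Optional [study_design()] describing the sampling layout.
#' @return Object of class `enose_dataset`.
#' @export
enose_dataset <- function(samples, design = NULL) {
  stopifnot(is.list(samples))
  if (length(samples)) {
    ok <- vapply(samples, inherits, logical(1), "enose_sample")
    if (!all(ok)) stop("all elements must be enose_sample objects",
                       call. = FALSE)
    ids <- vapply(samples, `[[`, character(1), "sample_id")
    if (anyDuplicated(ids)) {
      stop("duplicate sample_id: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "),
           call. = FALSE)
    }
    sn <- samples[[1L]]$sensor_names
    same <- vapply(samples, function(s) identical(s$sensor_names, sn),
                   logical(1))
    if (!all(same)) stop("all samples must share sensor_names", call. = FALSE)
  }
  structure(list(samples = samples, design = design),
            class = "enose_dataset")
}

#' @export
length.enose_dataset <- function(x) length(x$samples)

#' @export
`[.enose_dataset` <- function(x, i) {
  enose_dataset(x$samples[i], design = x$design)
}

#' @export
print.enose_dataset <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<enose_dataset> %d samples\n", n))
  if (n) {
    meta <- dataset_meta(x)
    cat(sprintf("  days %s, sessions {%s}, proportions {%s}\n",
                paste(range(meta$day), collapse = "-"),
                paste(sort(unique(meta$session)), collapse = ", "),
                paste(format(sort(unique(meta$proportion))), collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.enose_sample <- function(x, ...) {
  cat(sprintf(
    "<enose_sample> %s: day %d session %s, proportion %.0f%%, 100 x 10 curves\n",
    x$sample_id, x$day, x$session, 100 * x$proportion))
  invisible(x)
}

#' Per-sample metadata of a dataset
#'
#' @param dataset An `enose_dataset`.
#' @return A data.frame with columns `sample_id`, `day`, `session`,
#'   `proportion` (fraction), one row per sample, in dataset order.
#' @export
dataset_meta <- function(dataset) {
  stopifnot(inherits(dataset, "enose_dataset"))
  data.frame(
    sample_id = vapply(dataset$samples, `[[`, character(1), "sample_id"),
    day = vapply(dataset$samples, `[[`, integer(1), "day"),
    session = vapply(dataset$samples, `[[`, character(1), "session"),
    proportion = vapply(dataset$samples, `[[`, numeric(1), "proportion"),
    stringsAsFactors = FALSE
  )
}

#' Subset a dataset by metadata
#'
#' @param dataset An `enose_dataset`.
#' @param days,sessions,proportions Optional vectors of values to keep.
#' @return The filtered `enose_dataset` (original order preserved).
#' @export
subset_dataset <- function(dataset, days = NULL, sessions = NULL,
                           proportions = NULL) {
  meta <- dataset_meta(dataset)
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(days)) keep <- keep & meta$day %in% days
  if (!is.null(sessions)) keep <- keep & meta$session %in% sessions
  if (!is.null(proportions)) {
    keep <- keep & vapply(meta$proportion,
                          function(p) min(abs(p - proportions)) < 1e-9,
                          logical(1))
  }
  dataset[which(keep)]
}

manifest_cols <- c("sample_id", "day", "session", "proportion_percent")

curve_paths <- function(path) {
  if (dir.exists(path)) {
    list(manifest = file.path(path, "manifest.csv"),
         curves = file.path(path, "curves.csv"))
  } else {
    list(manifest = path,
         curves = file.path(dirname(path),
                            sub("manifest", "curves", basename(path))))
  }
}

#' Read an E-nose dataset from CSV files
#'
#' Expects the pair of files written by [write_dataset()]: a manifest CSV
#' (`sample_id, day, session, proportion_percent`) and a long-format curves
#' CSV (`sample_id, t_s`, then the 10 sensor columns, 100 rows per sample
#' with `t_s` running 1..100 seconds).  Proportions are percent on disk and
#' fractions in memory; the conversion happens only here.
#'
#' @param path Either a directory containing `manifest.csv` and
#'   `curves.csv`, or the path of the manifest file itself (the curves file
#'   is then found beside it).
#' @return An [enose_dataset()], samples in manifest row order.
#' @export
read_dataset <- function(path) {
  fp <- curve_paths(path)
  if (!file.exists(fp$manifest)) {
    stop("manifest file not found: ", fp$manifest, call. = FALSE)
  }
  if (!file.exists(fp$curves)) {
    stop("curves file not found: ", fp$curves, call. = FALSE)
  }
  man <- data.table::fread(fp$manifest, colClasses = list(
    character = "sample_id"))
  missing_m <- setdiff(manifest_cols, names(man))
  if (length(missing_m)) {
    stop("manifest is missing column(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  cur <- data.table::fread(fp$curves, colClasses = list(
    character = "sample_id"))
  sensor_names <- setdiff(names(cur), c("sample_id", "t_s"))
  missing_c <- setdiff(c("sample_id", "t_s"), names(cur))
  if (length(missing_c)) {
    stop("curves file is missing column(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  if (length(sensor_names) != 10L) {
    stop("curves file must have 10 sensor columns, found ",
         length(sensor_names), call. = FALSE)
  }
  cur_split <- split(cur, by = "sample_id", sorted = FALSE)
  samples <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sid <- man$sample_id[i]
    blk <- cur_split[[sid]]
    if (is.null(blk)) {
      stop("no curve rows for sample ", sid, call. = FALSE)
    }
    if (nrow(blk) != 100L) {
      stop(sprintf("sample %s has %d time points, expected 100",
                   sid, nrow(blk)), call. = FALSE)
    }
    blk <- blk[order(blk$t_s), ]
    if (!identical(as.integer(blk$t_s), 1:100)) {
      stop(sprintf("sample %s: t_s must be the integers 1..100", sid),
           call. = FALSE)
    }
    cv <- as.matrix(blk[, sensor_names, with = FALSE])
    bad <- which(!is.finite(cv) | cv <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "sample %s: non-positive ratio at t=%d, sensor %s",
        sid, bad[1L, 1L], sensor_names[bad[1L, 2L]]), call. = FALSE)
    }
    samples[[i]] <- enose_sample(
      curves = cv,
      proportion = man$proportion_percent[i] / 100,
      day = man$day[i],
      session = man$session[i],
      sample_id = sid,
      sensor_names = sensor_names
    )
  }
  enose_dataset(samples)
}

#' Write an E-nose dataset to CSV files
#'
#' Writes `manifest.csv` and `curves.csv` (see [read_dataset()] for the
#' layout) into `path`, creating it if needed.  Proportions are stored as
#' percent.  `read_dataset(write_dataset(d))` round-trips ids, labels and
#' metadata exactly and curve values to float-printing precision.
#'
#' @param dataset An `enose_dataset`.
#' @param path Output directory.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "enose_dataset"))
  if (length(dataset)) {
    ids <- dataset_meta(dataset)$sample_id
    if (anyDuplicated(ids)) {
      stop("refusing to write dataset with duplicate sample_id",
           call. = FALSE)
    }
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fp <- curve_paths(path)
  meta <- if (length(dataset)) dataset_meta(dataset) else
    data.frame(sample_id = character(), day = integer(),
               session = character(), proportion = numeric())
  man <- data.frame(sample_id = meta$sample_id, day = meta$day,
                    session = meta$session,
                    proportion_percent = 100 * meta$proportion)
  data.table::fwrite(man, fp$manifest)
  if (length(dataset)) {
    blocks <- lapply(dataset$samples, function(s) {
      data.table::data.table(sample_id = s$sample_id, t_s = 1:100,
                             s$curves)
    })
    cur <- data.table::rbindlist(blocks)
  } else {
    cur <- data.table::data.table(sample_id = character(), t_s = integer())
    for (sn in default_sensor_names()) cur[[sn]] <- numeric()
  }
  data.table::fwrite(cur, fp$curves)
  invisible(fp)
}
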
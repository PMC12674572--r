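#' Read a raw triaxial recording from delimited text
#'
#' Expects a header `time,x,y,z` with time in seconds (or as a 0/1-based
#' sample index) and acceleration in g. Reading is gzip-transparent. The
#' sampling rate is inferred from the timestamps and validated against
#' `fs` when both are available; a mismatch above 1 % is an error.
#'
#' @param path Path to a CSV/TSV file (optionally gzipped).
#' @param fs Expected sampling rate in Hz; required when `time` is a sample
#'   index, otherwise optional cross-check.
#' @return A [raw_signal()].
#' @export
read_raw_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("time", "x", "y", "z"), names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  for (col in c("time", "x", "y", "z")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("%s: non-finite value in column '%s' at data row %d",
                   path, col, bad[1L]), call. = FALSE)
    }
  }
  dt <- diff(df$time)
  bad <- which(dt <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("%s: non-monotone time at data row %d", path, bad[1L] + 1L),
         call. = FALSE)
  }
  step <- stats::median(dt)
  # integer steps of 1 mean the time column is a sample index
  is_index <- isTRUE(all.equal(step, 1)) && !is.null(fs) && fs != 1
  fs_obs <- if (is_index) fs else 1 / step
  if (!is.null(fs) && !is_index && abs(fs_obs - fs) / fs > 0.01) {
    stop(sprintf("%s: timestamps imply %.3f Hz but config says %g Hz (> 1%% off)",
                 path, fs_obs, fs), call. = FALSE)
  }
  t0 <- if (is_index) df$time[1L] / fs else df$time[1L]
  raw_signal(df$x, df$y, df$z, fs = if (is.null(fs)) fs_obs else fs, t0 = t0)
}

#' Write a raw signal as CSV
#'
#' @param signal A [raw_signal()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_raw_csv <- function(signal, path) {
  t <- signal$t0 + (seq_len(signal$n) - 1) / signal$fs
  readr::write_csv(tibble::tibble(time = t, x = signal$x, y = signal$y,
                                  z = signal$z), path)
  invisible(path)
}

#' Write / read a cohort table
#'
#' Long-format CSV with columns participant, location, condition, category,
#' metric, second, value; the interchange format between the metric core
#' and the statistical pipeline.
#'
#' @param cohort A cohort table.
#' @param path File path.
#' @return `write_cohort_csv` returns the path invisibly; `read_cohort_csv`
#'   returns the validated cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  check_cohort(cohort)
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_cohort(cohort)
  cohort
}

write_matrix_csv <- function(m, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(m)), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(series = rownames(m)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Run the end-to-end study pipeline
#'
#' Orchestrates the full workflow in the study's order: simulate (or load)
#' the cohort, trim and truncate, group into categories, then compute
#' descriptives, between-person variance, the full correlation matrix,
#' all pairwise conversion models and intensity cut-points, writing each
#' result as CSV plus a machine-readable run report. Outputs are
#' deterministic functions of (config, seed): identical runs produce
#' byte-identical files.
#'
#' @param cfg A [cohort_config()] (its `seed` governs the simulation), or
#'   `NULL` when `cohort` is supplied.
#' @param outdir Output directory, created if needed.
#' @param cohort Optional pre-assembled cohort table; when supplied the
#'   simulation step is skipped.
#' @param profiles,filt,count_cfg,trim_s,mapping Passed to [build_cohort()].
#' @param intensity_labels Category-to-intensity-class mapping for
#'   cut-point calibration.
#' @return Invisibly, a list with the computed tables and the paths written.
#' @export
run_end_to_end <- function(cfg = cohort_config(), outdir, cohort = NULL,
                           profiles = activity_profiles(),
                           filt = filter_spec(), count_cfg = count_config(),
                           trim_s = 5, mapping = NULL,
                           intensity_labels = default_intensity_labels()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) {
    cohort <- build_cohort(cfg, profiles, filt, count_cfg, trim_s, mapping)
  } else {
    check_cohort(cohort)
  }
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  desc <- step("descriptives", descriptive_table(cohort))
  bp <- step("between_person", between_person_variance(cohort))
  cm <- step("correlations", correlation_matrix(cohort))
  conv <- step("conversions", conversion_table(cohort))
  cuts <- step("cutpoints", calibrate_cutpoints(cohort, intensity_labels))
  paths <- list(
    cohort = file.path(outdir, "cohort.csv"),
    descriptives = file.path(outdir, "descriptives.csv"),
    between_person = file.path(outdir, "between_person.csv"),
    correlations = file.path(outdir, "correlations.csv"),
    conversions = file.path(outdir, "conversions.csv"),
    cutpoints = file.path(outdir, "cutpoints.csv"),
    report = file.path(outdir, "run_report.json")
  )
  write_cohort_csv(cohort, paths$cohort)
  readr::write_csv(desc, paths$descriptives)
  readr::write_csv(bp$cell_sd, paths$between_person)
  write_matrix_csv(cm, paths$correlations)
  readr::write_csv(conv, paths$conversions)
  readr::write_csv(cuts, paths$cutpoints)
  report <- list(
    package = "accelharmony",
    version = as.character(utils::packageVersion("accelharmony")),
    seed = if (!is.null(cfg)) cfg$seed else NA,
    config = if (!is.null(cfg)) unclass(cfg) else "external cohort",
    filter = unclass(filt), counts = unclass(count_cfg), trim_s = trim_s,
    n_seconds = nrow(cohort) / length(unique(cohort$metric)),
    intensity_labels = as.list(intensity_labels)
  )
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(cohort = cohort, descriptives = desc, between_person = bp,
                 correlations = cm, conversions = conv, cutpoints = cuts,
                 paths = paths))
}
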
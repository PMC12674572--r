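#' Trim the unstable start and end of a condition recording
#'
#' The first and last seconds of each activity condition contain start-up and
#' wind-down movement (and, for filtered metrics, filter transients), so the
#' analysis excludes the first and last `trim_s` epochs of every condition.
#'
#' @param series An [epoch_series()] of one-second epochs.
#' @param trim_s Seconds to drop at each end (default 5).
#' @return The trimmed [epoch_series()], `2 * trim_s` epochs shorter.
#' @export
trim_condition <- function(series, trim_s = 5) {
  stopifnot(inherits(series, "epoch_series"))
  n <- length(series$values)
  if (n <= 2 * trim_s) {
    stop(sprintf(
      "condition '%s' too short to trim: %d epochs <= 2 x %d",
      series$condition, n, trim_s), call. = FALSE)
  }
  keep <- seq.int(trim_s + 1L, n - trim_s)
  epoch_series(series$values[keep], series$metric, series$location,
               series$epoch_len, series$second_index[keep], series$condition)
}

#' Truncate a group of series to a common length
#'
#' Participants perform each condition a few seconds longer than the minimum;
#' all series of one condition are cut to the shortest length in the group,
#' keeping the earliest epochs, so that every participant contributes the
#' same number of seconds.
#'
#' @param group A list of [epoch_series()] for one condition.
#' @return A list of series, all of the minimum length.
#' @export
truncate_to_common_length <- function(group) {
  if (length(group) == 0L) stop("empty series group", call. = FALSE)
  stopifnot(all(vapply(group, inherits, logical(1), "epoch_series")))
  lens <- vapply(group, length, integer(1))
  if (any(lens == 0L)) stop("empty series in group", call. = FALSE)
  m <- min(lens)
  lapply(group, function(s) {
    keep <- seq_len(m)
    epoch_series(s$values[keep], s$metric, s$location, s$epoch_len,
                 s$second_index[keep], s$condition)
  })
}

#' Map condition identifiers to superordinate activity categories
#'
#' The 32 protocol conditions are grouped into eight superordinate
#' categories (lying, sitting, standing, adl, climbing_stairs, walking,
#' jogging, cycling). The mapping ships as an editable YAML resource; see
#' [default_category_mapping()].
#'
#' @param condition_id Character vector of condition identifiers.
#' @param mapping Named character vector or list, condition -> category.
#' @return Character vector of category labels.
#' @export
assign_categories <- function(condition_id, mapping = default_category_mapping()) {
  mapping <- unlist(mapping)
  missing <- setdiff(unique(condition_id), names(mapping))
  if (length(missing) > 0L) {
    stop(sprintf("no category mapping for condition(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  cats <- unname(mapping[condition_id])
  bad <- setdiff(unique(cats), accel_categories())
  if (length(bad) > 0L) {
    stop(sprintf("mapping targets unknown categories: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cats
}

#' Default condition-to-category mapping
#'
#' Reads the packaged 32-entry mapping from conditions (modelled on a
#' structured laboratory protocol of standardized and semi-standardized
#' activities) to the eight superordinate categories.
#'
#' @param path Optional path to an alternative YAML mapping.
#' @return Named character vector, condition -> category.
#' @export
default_category_mapping <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "condition_categories.yaml",
                        package = "accelharmony", mustWork = TRUE)
  }
  unlist(yaml::read_yaml(path))
}

check_cohort <- function(cohort) {
  needed <- c("participant", "location", "condition", "category",
              "metric", "second", "value")
  miss <- setdiff(needed, names(cohort))
  if (length(miss) > 0L) {
    stop(sprintf("cohort table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(cohort$value))) {
    stop("cohort table contains missing or non-finite values", call. = FALSE)
  }
  invisible(cohort)
}

#' Category descriptives per sensor location and metric
#'
#' Mean and standard deviation of the second-level values for every
#' (location, category, metric) cell. `mode = "pooled"` (default) pools all
#' seconds of all participants, matching the second-level resolution of the
#' correlation analysis; `mode = "participant_means"` first averages within
#' participant and then summarises the participant means. The standard
#' deviation uses the sample (n - 1) denominator throughout.
#'
#' @param cohort A cohort table (long format, see [build_cohort()]).
#' @param mode `"pooled"` or `"participant_means"`.
#' @return A tibble with columns location, category, metric, mean, sd, n.
#' @export
descriptive_table <- function(cohort, mode = c("pooled", "participant_means")) {
  mode <- match.arg(mode)
  check_cohort(cohort)
  if (mode == "participant_means") {
    cohort <- cohort |>
      dplyr::group_by(.data$location, .data$category, .data$metric,
                      .data$participant) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  cohort |>
    dplyr::group_by(.data$location, .data$category, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}

#' Between-person variance per location, category and metric
#'
#' Computes each participant's mean value per (location, category, metric)
#' cell, then the sample standard deviation of those participant means — the
#' quantity visualised by per-category boxplots in placement-comparison
#' studies. Also returns, per (location, metric), the average of those
#' standard deviations over categories, used to rank locations by
#' between-person spread.
#'
#' @param cohort A cohort table.
#' @return A list with `cell_sd` (location, category, metric,
#'   between_person_sd, n_participants), `participant_means` (the underlying
#'   per-participant means, for boxplots) and `location_mean_sd` (location,
#'   metric, mean_between_person_sd).
#' @export
between_person_variance <- function(cohort) {
  check_cohort(cohort)
  pm <- cohort |>
    dplyr::group_by(.data$location, .data$category, .data$metric,
                    .data$participant) |>
    dplyr::summarise(participant_mean = mean(.data$value), .groups = "drop")
  cell <- pm |>
    dplyr::group_by(.data$location, .data$category, .data$metric) |>
    dplyr::summarise(between_person_sd = stats::sd(.data$participant_mean),
                     n_participants = dplyr::n(), .groups = "drop")
  if (any(cell$n_participants < 2L)) {
    warning("cells with a single participant have undefined between-person sd",
            call. = FALSE)
  }
  loc <- cell |>
    dplyr::group_by(.data$location, .data$metric) |>
    dplyr::summarise(mean_between_person_sd = mean(.data$between_person_sd),
                     .groups = "drop")
  list(cell_sd = cell, participant_means = pm, location_mean_sd = loc)
}

cohort_wide <- function(cohort) {
  check_cohort(cohort)
  wide <- cohort |>
    dplyr::mutate(series = paste(.data$metric, .data$location, sep = ".")) |>
    dplyr::select("participant", "condition", "second", "series", "value") |>
    tidyr::pivot_wider(names_from = "series", values_from = "value")
  series_cols <- setdiff(names(wide), c("participant", "condition", "second"))
  if (anyNA(wide[series_cols])) {
    stop(paste("cohort series are not second-aligned across locations and",
               "metrics: some (participant, condition, second) keys lack",
               "values for every series"), call. = FALSE)
  }
  wide
}

series_label_order <- function(metrics, locations) {
  as.vector(t(outer(metrics, locations, paste, sep = ".")))
}

#' Pearson correlation matrix over all metric-by-location series
#'
#' Aligns the second-level values of every (metric, location) series by
#' (participant, condition, second) and computes all pairwise Pearson
#' correlations over the pooled seconds of all participants and conditions.
#' With 4 metrics and 6 locations this is the 24 x 24 matrix with 276
#' unique off-diagonal pairs.
#'
#' @param cohort A cohort table.
#' @return A symmetric correlation matrix of class `correlation_matrix` with
#'   `"METRIC.location"` dimnames, ordered metric-major (metric blocks, each
#'   in location order).
#' @export
correlation_matrix <- function(cohort) {
  wide <- cohort_wide(cohort)
  series_cols <- setdiff(names(wide), c("participant", "condition", "second"))
  metrics <- intersect(accel_metrics(), unique(cohort$metric))
  locations <- intersect(accel_locations(), unique(cohort$location))
  ord <- intersect(series_label_order(metrics, locations), series_cols)
  m <- as.matrix(wide[ord])
  zero_var <- apply(m, 2L, stats::sd) == 0
  if (any(zero_var)) {
    warning(sprintf("zero-variance series reported as missing: %s",
                    paste(ord[zero_var], collapse = ", ")), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(m))
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  diag(r) <- ifelse(zero_var, NA_real_, 1)
  class(r) <- c("correlation_matrix", class(r))
  r
}

#' Ordinary least-squares conversion model between two series
#'
#' Fits `target = slope * source + intercept` by OLS over second-aligned
#' values, the linear conversion model used to translate values between
#' metrics or wearing positions.
#'
#' @param source,target Numeric vectors of equal length (>= 3), or
#'   [epoch_series()] objects.
#' @return An object of class `conversion_model`: slope, intercept, r, r2, n.
#' @export
fit_conversion <- function(source, target) {
  if (inherits(source, "epoch_series")) source <- source$values
  if (inherits(target, "epoch_series")) target <- target$values
  if (length(source) != length(target)) {
    stop("source and target must be aligned to equal length", call. = FALSE)
  }
  if (length(source) < 3L) stop("need at least 3 aligned seconds", call. = FALSE)
  if (stats::sd(source) == 0) {
    stop("zero-variance source series: conversion slope undefined", call. = FALSE)
  }
  fit <- stats::lm(target ~ source)
  r <- if (stats::sd(target) == 0) NA_real_ else stats::cor(source, target)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = r, r2 = if (is.na(r)) NA_real_ else r^2,
                 n = length(source)),
            class = "conversion_model")
}

#' @export
print.conversion_model <- function(x, ...) {
  cat(sprintf("<conversion_model> y = %.4g x + %.4g  (r = %.3f, r2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r, x$r2, x$n))
  invisible(x)
}

#' All pairwise conversion models of a cohort
#'
#' Fits [fit_conversion()] for every unordered pair of (metric, location)
#' series (276 pairs for the full 4 x 6 design).
#'
#' @param cohort A cohort table.
#' @return A tibble with one row per pair: source, target, slope, intercept,
#'   r, r2, n.
#' @export
conversion_table <- function(cohort) {
  wide <- cohort_wide(cohort)
  metrics <- intersect(accel_metrics(), unique(cohort$metric))
  locations <- intersect(accel_locations(), unique(cohort$location))
  ord <- intersect(series_label_order(metrics, locations), names(wide))
  pairs <- utils::combn(ord, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    src <- pairs[1L, i]; tgt <- pairs[2L, i]
    cm <- fit_conversion(wide[[src]], wide[[tgt]])
    tibble::tibble(source = src, target = tgt, slope = cm$slope,
                   intercept = cm$intercept, r = cm$r, r2 = cm$r2, n = cm$n)
  })
  dplyr::bind_rows(rows)
}

#' Default intensity-zone labelling of the activity categories
#'
#' A four-zone labelling used for cut-point calibration: sedentary
#' (lying, sitting), light (standing, adl), moderate (climbing stairs,
#' walking, cycling) and vigorous (jogging). Zones are ordered by intensity.
#'
#' @return Named character vector, category -> intensity class.
#' @export
default_intensity_labels <- function() {
  c(lying = "sedentary", sitting = "sedentary",
    standing = "light", adl = "light",
    climbing_stairs = "moderate", walking = "moderate", cycling = "moderate",
    jogging = "vigorous")
}

#' Intensity cut-points per metric and sensor location
#'
#' For every (metric, location) series, calibrates a threshold between each
#' adjacent pair of intensity classes by maximizing Youden's J
#' (sensitivity + specificity - 1) over the pooled second-level values, the
#' field-standard ROC approach to intensity cut-point calibration. A
#' boundary whose best J is below `reliable_j` is flagged unreliable (the
#' two classes are essentially unseparated there).
#'
#' @param cohort A cohort table.
#' @param intensity_labels Named character vector, category -> class; class
#'   order of increasing intensity is taken from the order of first
#'   appearance (default [default_intensity_labels()]).
#' @param class_order Optional explicit ordering of the intensity classes.
#' @param reliable_j Minimum Youden's J for a boundary to be flagged
#'   reliable (default 0.1).
#' @return A tibble with columns metric, location, boundary (e.g.
#'   "sedentary|light"), threshold, sensitivity, specificity, j, reliable.
#' @export
calibrate_cutpoints <- function(cohort,
                                intensity_labels = default_intensity_labels(),
                                class_order = NULL, reliable_j = 0.1) {
  check_cohort(cohort)
  miss <- setdiff(unique(cohort$category), names(intensity_labels))
  if (length(miss) > 0L) {
    stop(sprintf("no intensity class for category(ies): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (is.null(class_order)) class_order <- unique(unname(intensity_labels))
  present <- class_order[class_order %in%
                           unname(intensity_labels[unique(cohort$category)])]
  if (length(present) < 2L) {
    stop("need at least two intensity classes with data", call. = FALSE)
  }
  cohort$class <- factor(unname(intensity_labels[cohort$category]),
                         levels = present)
  cells <- cohort |> dplyr::distinct(.data$metric, .data$location)
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    met <- cells$metric[i]; loc <- cells$location[i]
    sub <- cohort[cohort$metric == met & cohort$location == loc, ]
    for (k in seq_len(length(present) - 1L)) {
      lo <- present[k]; hi <- present[k + 1L]
      v_lo <- sub$value[sub$class == lo]
      v_hi <- sub$value[sub$class == hi]
      if (length(v_lo) == 0L || length(v_hi) == 0L) {
        stop(sprintf("intensity class '%s' has no seconds for %s at %s",
                     if (length(v_lo) == 0L) lo else hi, met, loc),
             call. = FALSE)
      }
      roc <- pROC::roc(response = c(rep(0L, length(v_lo)), rep(1L, length(v_hi))),
                       predictor = c(v_lo, v_hi), direction = "<",
                       quiet = TRUE)
      best <- pROC::coords(roc, "best", best.method = "youden",
                           ret = c("threshold", "sensitivity", "specificity"),
                           transpose = FALSE)
      best <- best[1L, , drop = FALSE] # ties: keep the first optimum
      sens <- as.numeric(best$sensitivity)
      spec <- as.numeric(best$specificity)
      j <- sens + spec - 1
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metric = met, location = loc,
        boundary = paste(lo, hi, sep = "|"),
        threshold = as.numeric(best$threshold), sensitivity = sens,
        specificity = spec, j = j, reliable = j >= reliable_j)
    }
  }
  out <- dplyr::bind_rows(rows)
  # non-monotone thresholds across boundaries indicate overlapping zones
  bad <- out |>
    dplyr::group_by(.data$metric, .data$location) |>
    dplyr::summarise(ok = !is.unsorted(.data$threshold, strictly = TRUE),
                     .groups = "drop")
  if (any(!bad$ok)) {
    warning("non-increasing cut-points across intensity boundaries for: ",
            paste(sprintf("%s@%s", bad$metric[!bad$ok], bad$location[!bad$ok]),
                  collapse = ", "), call. = FALSE)
  }
  out
}
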
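#' Load the packaged reference tables
#'
#' The package ships the published reference results of the six-position,
#' four-metric laboratory comparison as two plain CSV resources: the
#' category means/SDs per location and metric (192 cells), and the lower
#' triangle of the 24 x 24 Pearson correlation matrix over all
#' (metric, location) series (276 pairs). The correlation triangle is
#' mirrored to a full symmetric matrix with unit diagonal on load.
#'
#' @return An object of class `reference_tables`: a list with `table1`
#'   (tibble: location, category, metric, mean, sd) and `table2` (24 x 24
#'   symmetric matrix with `"METRIC.location"` dimnames).
#' @export
reference_tables <- function() {
  p1 <- system.file("extdata", "table1_reference.csv",
                    package = "accelharmony", mustWork = TRUE)
  p2 <- system.file("extdata", "table2_reference.csv",
                    package = "accelharmony", mustWork = TRUE)
  t1 <- readr::read_csv(p1, show_col_types = FALSE)
  long <- readr::read_csv(p2, show_col_types = FALSE)
  stopifnot(nrow(t1) == 192L, nrow(long) == 276L)
  labels <- series_label_order(accel_metrics(), accel_locations())
  m <- matrix(NA_real_, 24L, 24L, dimnames = list(labels, labels))
  a <- paste(long$metric_a, long$location_a, sep = ".")
  b <- paste(long$metric_b, long$location_b, sep = ".")
  m[cbind(a, b)] <- long$r
  m[cbind(b, a)] <- long$r
  diag(m) <- 1
  stopifnot(!anyNA(m), all(m >= 0 & m <= 1))
  structure(list(table1 = t1, table2 = m), class = "reference_tables")
}

#' @export
print.reference_tables <- function(x, ...) {
  cat("<reference_tables> 192 mean/sd cells; 24 x 24 correlation matrix\n")
  invisible(x)
}

#' Look up a reference category mean and SD
#'
#' @param ref A [reference_tables()] object.
#' @param location,category,metric Labels (see [accel_locations()] etc.).
#' @return A list with elements `mean` and `sd`, in the metric's units
#'   (mg, or counts per minute for CPM).
#' @export
lookup_mean <- function(ref, location, category, metric) {
  stopifnot(inherits(ref, "reference_tables"))
  location <- match_label(location, accel_locations(), "location")
  category <- match_label(category, accel_categories(), "category")
  metric <- match_label(metric, accel_metrics(), "metric")
  row <- ref$table1[ref$table1$location == location &
                      ref$table1$category == category &
                      ref$table1$metric == metric, ]
  stopifnot(nrow(row) == 1L)
  list(mean = row$mean, sd = row$sd)
}

#' Ratio of two category means at one location and metric
#'
#' The ratio of category means (e.g. jogging over cycling) differs between
#' wearing positions and between metrics, which is why comparing raw means
#' across placements or metrics misleads; this helper reproduces those
#' ratios from the packaged means.
#'
#' @param ref A [reference_tables()] object.
#' @param location,metric Labels.
#' @param category_a,category_b Numerator and denominator categories.
#' @param digits Optional half-up rounding of the result (e.g. 1 for the
#'   one-decimal presentation).
#' @return The ratio `mean_a / mean_b`.
#' @export
activity_ratio <- function(ref, location, metric, category_a, category_b,
                           digits = NULL) {
  a <- lookup_mean(ref, location, category_a, metric)$mean
  b <- lookup_mean(ref, location, category_b, metric)$mean
  if (b == 0) stop("denominator category mean is zero: ratio undefined",
                   call. = FALSE)
  out <- a / b
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

within_metric_pairs <- function(ref, metric) {
  idx <- grep(paste0("^", metric, "\\."), rownames(ref$table2))
  sub <- ref$table2[idx, idx]
  sub[lower.tri(sub)]
}

#' Average within-metric between-location correlation
#'
#' Mean of the 15 location-pair correlations of one metric (or of the 45
#' pairs pooled over several metrics), the summary used to compare how
#' consistently each metric transfers across wearing positions.
#'
#' @param ref A [reference_tables()] object.
#' @param metrics One metric label or a vector of metric labels to pool.
#' @param digits Optional half-up rounding of the result.
#' @return The mean correlation.
#' @export
within_metric_between_location_mean_r <- function(ref, metrics, digits = NULL) {
  stopifnot(inherits(ref, "reference_tables"))
  for (m in metrics) match_label(m, accel_metrics(), "metric")
  vals <- unlist(lapply(metrics, within_metric_pairs, ref = ref))
  out <- mean(vals)
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Extreme correlation pairs
#'
#' Finds the smallest or largest correlation either between different
#' locations within the same metric (60 pairs: 15 location pairs x 4
#' metrics) or between different metrics at the same location (36 pairs:
#' 6 metric pairs x 6 locations). Ties at the stored two-decimal precision
#' are all returned.
#'
#' @param ref A [reference_tables()] object.
#' @param scope `"within_metric_between_location"` or
#'   `"between_metric_within_location"`.
#' @param which `"min"` or `"max"`.
#' @return A tibble with columns series_a, series_b, r (one row per tied
#'   extreme pair).
#' @export
extreme_pair <- function(ref,
                         scope = c("within_metric_between_location",
                                   "between_metric_within_location"),
                         which = c("min", "max")) {
  stopifnot(inherits(ref, "reference_tables"))
  scope <- match.arg(scope)
  which <- match.arg(which)
  labels <- rownames(ref$table2)
  met <- sub("\\..*$", "", labels)
  loc <- sub("^.*\\.", "", labels)
  pairs <- utils::combn(seq_along(labels), 2L)
  keep <- if (scope == "within_metric_between_location") {
    met[pairs[1L, ]] == met[pairs[2L, ]]
  } else {
    loc[pairs[1L, ]] == loc[pairs[2L, ]]
  }
  pairs <- pairs[, keep, drop = FALSE]
  r <- ref$table2[cbind(pairs[1L, ], pairs[2L, ])]
  target <- if (which == "min") min(r) else max(r)
  hit <- which(abs(r - target) < 1e-12)
  tibble::tibble(series_a = labels[pairs[1L, hit]],
                 series_b = labels[pairs[2L, hit]],
                 r = r[hit])
}

#' Look up one reference correlation
#'
#' @param ref A [reference_tables()] object.
#' @param metric_a,location_a,metric_b,location_b Labels of the two series.
#' @return The stored correlation.
#' @export
lookup_r <- function(ref, metric_a, location_a, metric_b, location_b) {
  stopifnot(inherits(ref, "reference_tables"))
  a <- paste(match_label(metric_a, accel_metrics(), "metric"),
             match_label(location_a, accel_locations(), "location"), sep = ".")
  b <- paste(match_label(metric_b, accel_metrics(), "metric"),
             match_label(location_b, accel_locations(), "location"), sep = ".")
  ref$table2[a, b]
}
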
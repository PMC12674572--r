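#' Label vocabularies shared across the package
#'
#' The four intensity metrics, six wearing locations and eight superordinate
#' activity categories used throughout the pipeline and the packaged
#' reference tables. Locations are listed in the reference-table ordering
#' (ankle, chest, hip, thigh, upper_arm, wrist) so that correlation-matrix
#' axes line up with the published layout.
#'
#' @return A character vector of labels.
#' @export
accel_metrics <- function() c("MAI", "ENMO", "MAD", "CPM")

#' @rdname accel_metrics
#' @export
accel_locations <- function() {
  c("ankle", "chest", "hip", "thigh", "upper_arm", "wrist")
}

#' @rdname accel_metrics
#' @export
accel_categories <- function() {
  c("lying", "sitting", "standing", "adl", "climbing_stairs",
    "walking", "jogging", "cycling")
}

match_label <- function(x, choices, what) {
  if (length(x) != 1L || !x %in% choices) {
    stop(sprintf("unknown %s '%s'; valid values: %s",
                 what, paste(x, collapse = ","),
                 paste(choices, collapse = ", ")), call. = FALSE)
  }
  x
}

# half-up decimal rounding at the printed precision (base round() is
# round-half-even, which disagrees with how the tables were typeset)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
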
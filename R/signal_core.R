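#' Raw triaxial acceleration signal
#'
#' Container for a uniformly sampled triaxial accelerometer stream in units
#' of g. The sensors emulated here record at a nominal 64 Hz over a +/- 16 g
#' range; samples outside that range or non-finite samples are rejected at
#' construction.
#'
#' @param x,y,z Numeric vectors of equal length: acceleration along the three
#'   body-fixed axes, in g.
#' @param fs Sampling rate in Hz (default 64).
#' @param t0 Start time in seconds (default 0).
#' @return An object of class `raw_signal` with fields `x`, `y`, `z`, `fs`,
#'   `t0` and `n` (sample count).
#' @export
raw_signal <- function(x, y, z, fs = 64, t0 = 0) {
  if (length(y) != length(x) || length(z) != length(x)) {
    stop("axis vectors x, y, z must have identical length", call. = FALSE)
  }
  if (length(x) < 1L) stop("signal must contain at least one sample", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(x), is.finite(y), is.finite(z))) {
    stop("all samples must be finite", call. = FALSE)
  }
  if (max(abs(x), abs(y), abs(z)) > 16) {
    stop("samples exceed the +/- 16 g device range", call. = FALSE)
  }
  structure(
    list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
         fs = as.numeric(fs), t0 = as.numeric(t0), n = length(x)),
    class = "raw_signal"
  )
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<raw_signal> %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              x$n, x$fs, x$n / x$fs, x$t0))
  invisible(x)
}

#' Duration of a raw signal in seconds
#' @param signal A [raw_signal()].
#' @return Duration in seconds.
#' @export
signal_duration <- function(signal) signal$n / signal$fs

#' Per-second metric series
#'
#' One metric stream for one (participant, location, condition) recording,
#' aggregated over half-open epochs `[k, k+1)` seconds. Values are mg for
#' MAI/ENMO/MAD and counts (or counts per minute after [counts_to_cpm()])
#' for the count metric.
#'
#' @param values Non-negative numeric vector, one value per epoch.
#' @param metric Metric label, e.g. `"MAD"` or `"counts"`.
#' @param location Optional wearing-location label.
#' @param epoch_len Epoch length in seconds (default 1).
#' @param second_index Integer epoch offsets; defaults to `0:(n-1)`.
#' @param condition Optional condition identifier (used in error messages).
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(values, metric, location = NA_character_,
                         epoch_len = 1, second_index = NULL,
                         condition = NA_character_) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("epoch values must be finite", call. = FALSE)
  if (any(values < -1e-12)) stop("epoch values must be non-negative", call. = FALSE)
  values[values < 0] <- 0
  if (is.null(second_index)) second_index <- seq_along(values) - 1L
  stopifnot(length(second_index) == length(values))
  structure(
    list(values = values, metric = metric, location = location,
         epoch_len = epoch_len, second_index = as.integer(second_index),
         condition = condition),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %s%s: %d epochs of %g s, mean %.2f\n",
              x$metric,
              if (is.na(x$location)) "" else paste0(" @ ", x$location),
              length(x$values), x$epoch_len, mean(x$values)))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$values)

#' Band-pass filter specification for the movement-intensity metric
#'
#' The movement acceleration intensity (MAI) metric removes gravity and
#' non-movement content with a Butterworth band-pass of 0.25-11 Hz before
#' taking the vector norm. `order` is the analogue prototype order, so the
#' resulting band-pass has `2 * order` poles. The filter is applied causally
#' by default, matching stream processing; `phase = "zero_phase"` applies it
#' forward-backward instead.
#'
#' @param low_hz,high_hz Corner frequencies in Hz.
#' @param order Butterworth prototype order (>= 1).
#' @param phase `"causal"` or `"zero_phase"`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.25, high_hz = 11, order = 4,
                        phase = c("causal", "zero_phase")) {
  phase <- match.arg(phase)
  if (!(low_hz > 0 && high_hz > low_hz)) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  structure(list(kind = "butterworth_bandpass", low_hz = low_hz,
                 high_hz = high_hz, order = as.integer(order), phase = phase),
            class = "filter_spec")
}

#' Activity-count algorithm configuration
#'
#' Constants of the count pipeline: polyphase resampling to `resample_hz`,
#' band-pass over the human-movement band, clipping at `peak_g`, rectified
#' dead-band at `deadband_g`, quantization by a signed `adc_bits`-bit
#' converter over `[-peak_g, peak_g]`, and conversion of quantization levels
#' beyond `deadband_levels` into counts.
#'
#' @param resample_hz Target rate for the count computation (no upsampling).
#' @param band_low_hz,band_high_hz Band-pass corners in Hz.
#' @param band_order Butterworth prototype order of the count band-pass.
#' @param peak_g Clip magnitude in g.
#' @param deadband_g Rectified threshold in g; smaller values are zeroed.
#' @param adc_bits ADC resolution in bits (8-16).
#' @param deadband_levels Quantization-level threshold; each level beyond it
#'   contributes one count.
#' @return An object of class `count_config`.
#' @export
count_config <- function(resample_hz = 30, band_low_hz = 0.29,
                         band_high_hz = 1.63, band_order = 2,
                         peak_g = 2.13, deadband_g = 0.068,
                         adc_bits = 12L, deadband_levels = 128L) {
  if (!(peak_g > deadband_g && deadband_g >= 0)) {
    stop("need peak_g > deadband_g >= 0", call. = FALSE)
  }
  if (!(adc_bits >= 8 && adc_bits <= 16)) stop("adc_bits must be in 8..16", call. = FALSE)
  if (deadband_levels < 0) stop("deadband_levels must be >= 0", call. = FALSE)
  if (!(band_low_hz > 0 && band_high_hz > band_low_hz)) {
    stop("need 0 < band_low_hz < band_high_hz", call. = FALSE)
  }
  structure(list(resample_hz = resample_hz, band_low_hz = band_low_hz,
                 band_high_hz = band_high_hz, band_order = as.integer(band_order),
                 peak_g = peak_g, deadband_g = deadband_g,
                 adc_bits = as.integer(adc_bits),
                 deadband_levels = as.integer(deadband_levels)),
            class = "count_config")
}

#' Per-sample vector magnitude of a triaxial signal
#'
#' @param signal A [raw_signal()].
#' @return Numeric vector `sqrt(x^2 + y^2 + z^2)`, in g, one value per sample.
#' @export
vector_magnitude <- function(signal) {
  stopifnot(inherits(signal, "raw_signal"))
  sqrt(signal$x^2 + signal$y^2 + signal$z^2)
}

# mean (or other fn) over complete half-open epochs; trailing partial epoch
# is dropped. spe (samples per epoch) must be an integer count.
epoch_aggregate <- function(v, fs, epoch_len, fun = mean) {
  if (epoch_len <= 0) stop("epoch_len must be positive", call. = FALSE)
  spe <- fs * epoch_len
  if (abs(spe - round(spe)) > 1e-9) {
    stop("fs * epoch_len must be an integer number of samples", call. = FALSE)
  }
  spe <- as.integer(round(spe))
  n_epochs <- length(v) %/% spe
  if (n_epochs < 1L) stop("signal shorter than one epoch", call. = FALSE)
  m <- matrix(v[seq_len(n_epochs * spe)], nrow = spe)
  apply(m, 2L, fun)
}

check_epochable <- function(signal, epoch_len) {
  if (epoch_len <= 0) stop("epoch_len must be positive", call. = FALSE)
  if (signal_duration(signal) < epoch_len) {
    stop("signal duration is shorter than one epoch", call. = FALSE)
  }
}

apply_bandpass <- function(v, fs, low_hz, high_hz, order, phase = "causal") {
  if (high_hz >= fs / 2) {
    stop("filter corner frequencies must be below the Nyquist rate", call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  if (phase == "zero_phase") {
    as.numeric(signal::filtfilt(bf, v))
  } else {
    as.numeric(signal::filter(bf, v))
  }
}

#' Movement acceleration intensity (MAI) per epoch
#'
#' Band-pass filters each axis (Butterworth, default 0.25-11 Hz) to strip
#' gravity and non-movement content, takes the per-sample Euclidean norm of
#' the filtered axes, averages within each epoch and scales to mg.
#'
#' @param signal A [raw_signal()].
#' @param filt A [filter_spec()].
#' @param epoch_len Epoch length in seconds.
#' @param location Optional location label carried into the result.
#' @param condition Optional condition label carried into the result.
#' @return An [epoch_series()] with metric `"MAI"`, values in mg.
#' @export
compute_mai <- function(signal, filt = filter_spec(), epoch_len = 1,
                        location = NA_character_, condition = NA_character_) {
  stopifnot(inherits(signal, "raw_signal"), inherits(filt, "filter_spec"))
  check_epochable(signal, epoch_len)
  fx <- apply_bandpass(signal$x, signal$fs, filt$low_hz, filt$high_hz,
                       filt$order, filt$phase)
  fy <- apply_bandpass(signal$y, signal$fs, filt$low_hz, filt$high_hz,
                       filt$order, filt$phase)
  fz <- apply_bandpass(signal$z, signal$fs, filt$low_hz, filt$high_hz,
                       filt$order, filt$phase)
  norm <- sqrt(fx^2 + fy^2 + fz^2)
  vals <- epoch_aggregate(norm, signal$fs, epoch_len) * 1000
  epoch_series(vals, "MAI", location, epoch_len, condition = condition)
}

#' Euclidean norm minus one (ENMO) per epoch
#'
#' Subtracts 1 g from the per-sample vector magnitude, clips negatives to
#' zero, averages within each epoch and scales to mg.
#'
#' @inheritParams compute_mai
#' @return An [epoch_series()] with metric `"ENMO"`, values in mg.
#' @export
compute_enmo <- function(signal, epoch_len = 1, location = NA_character_,
                         condition = NA_character_) {
  stopifnot(inherits(signal, "raw_signal"))
  check_epochable(signal, epoch_len)
  v <- pmax(vector_magnitude(signal) - 1, 0)
  vals <- epoch_aggregate(v, signal$fs, epoch_len) * 1000
  epoch_series(vals, "ENMO", location, epoch_len, condition = condition)
}

#' Mean amplitude deviation (MAD) per epoch
#'
#' Removes the static (gravity) component by subtracting the epoch mean of
#' the vector magnitude, averages the absolute deviations within the epoch
#' and scales to mg.
#'
#' @inheritParams compute_mai
#' @return An [epoch_series()] with metric `"MAD"`, values in mg.
#' @export
compute_mad <- function(signal, epoch_len = 1, location = NA_character_,
                        condition = NA_character_) {
  stopifnot(inherits(signal, "raw_signal"))
  check_epochable(signal, epoch_len)
  r <- vector_magnitude(signal)
  vals <- epoch_aggregate(r, signal$fs, epoch_len,
                          fun = function(w) mean(abs(w - mean(w)))) * 1000
  epoch_series(vals, "MAD", location, epoch_len, condition = condition)
}

# reduce a rate ratio to small integers for polyphase resampling
rational_ratio <- function(p_hz, q_hz, scale = 1000) {
  p <- round(p_hz * scale); q <- round(q_hz * scale)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p = p / d, q = q / d)
}

#' Activity counts per epoch
#'
#' Emulates the ActiGraph-lineage count algorithm: each axis is resampled to
#' `cfg$resample_hz`, band-pass filtered over the human-movement band,
#' clipped to `+/- peak_g`, rectified, dead-banded, quantized by a signed
#' 12-bit converter over `[-peak_g, peak_g]`, and every quantization level
#' beyond `deadband_levels` becomes one count; per-sample counts are summed
#' within each epoch. Vector-magnitude counts combine the three per-axis
#' epoch counts by Euclidean norm.
#'
#' @param signal A [raw_signal()].
#' @param cfg A [count_config()].
#' @param epoch_len Epoch length in seconds.
#' @param location,condition Optional labels carried into the result.
#' @return An [epoch_series()] with metric `"counts"` holding the
#'   vector-magnitude counts; per-axis integer epoch counts are attached as
#'   the `axis_counts` attribute (matrix with columns x, y, z).
#' @export
compute_counts <- function(signal, cfg = count_config(), epoch_len = 1,
                           location = NA_character_, condition = NA_character_) {
  stopifnot(inherits(signal, "raw_signal"), inherits(cfg, "count_config"))
  check_epochable(signal, epoch_len)
  if (cfg$resample_hz > signal$fs) {
    stop("resample_hz exceeds the signal rate; upsampling is not supported",
         call. = FALSE)
  }
  lsb <- cfg$peak_g / 2^(cfg$adc_bits - 1)
  per_axis <- function(v) {
    if (cfg$resample_hz < signal$fs) {
      pq <- rational_ratio(cfg$resample_hz, signal$fs)
      n_out <- floor(length(v) * pq[["p"]] / pq[["q"]])
      v <- as.numeric(signal::resample(v, pq[["p"]], pq[["q"]]))[seq_len(n_out)]
    }
    v <- apply_bandpass(v, cfg$resample_hz, cfg$band_low_hz, cfg$band_high_hz,
                        cfg$band_order)
    v <- pmin(pmax(v, -cfg$peak_g), cfg$peak_g)
    v <- abs(v)
    v[v < cfg$deadband_g] <- 0
    levels <- floor(v / lsb)
    counts <- pmax(levels - cfg$deadband_levels, 0)
    epoch_aggregate(counts, cfg$resample_hz, epoch_len, fun = sum)
  }
  cx <- per_axis(signal$x)
  cy <- per_axis(signal$y)
  cz <- per_axis(signal$z)
  vm <- sqrt(cx^2 + cy^2 + cz^2)
  out <- epoch_series(vm, "counts", location, epoch_len, condition = condition)
  attr(out, "axis_counts") <- cbind(x = cx, y = cy, z = cz)
  out
}

#' Rescale per-second counts to counts per minute
#'
#' @param epoch_counts An [epoch_series()] of per-second counts.
#' @param mode `"per_second"` rescales each second-level value by 60 (used
#'   for second-resolution correlations); `"per_condition"` averages over
#'   the condition's epochs and multiplies by 60, returning one scalar (used
#'   for condition-level descriptives).
#' @return An [epoch_series()] with metric `"CPM"` (per_second mode) or a
#'   single number (per_condition mode).
#' @export
counts_to_cpm <- function(epoch_counts, mode = c("per_second", "per_condition")) {
  mode <- match.arg(mode)
  stopifnot(inherits(epoch_counts, "epoch_series"))
  if (epoch_counts$epoch_len != 1) {
    stop("counts_to_cpm expects one-second epochs", call. = FALSE)
  }
  if (length(epoch_counts$values) == 0L) {
    stop("empty count series: counts per minute undefined", call. = FALSE)
  }
  if (mode == "per_condition") {
    return(mean(epoch_counts$values) * 60)
  }
  epoch_series(epoch_counts$values * 60, "CPM", epoch_counts$location,
               epoch_len = 1, second_index = epoch_counts$second_index,
               condition = epoch_counts$condition)
}
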
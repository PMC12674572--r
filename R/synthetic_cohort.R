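#' Load activity-condition profiles
#'
#' Reads the YAML profile set that drives the synthetic cohort generator.
#' Each condition carries a superordinate category, a duration, a movement
#' fundamental frequency with harmonic weights, a per-axis noise SD, and,
#' per wearing location, a unit gravity-orientation vector and a periodic
#' movement amplitude in mg. The shipped default set of 12 conditions spans
#' all eight categories.
#'
#' @param path Optional path to an alternative YAML profile file.
#' @return A named list of profiles (class `activity_profiles`), one per
#'   condition id.
#' @export
activity_profiles <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_profiles.yaml",
                        package = "accelharmony", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)$conditions
  profs <- list()
  for (p in raw) {
    stopifnot(is.character(p$id), is.character(p$category))
    p$category <- match_label(p$category, accel_categories(), "category")
    if (!(p$fundamental_hz > 0 && p$fundamental_hz < 32)) {
      stop(sprintf("profile '%s': fundamental_hz must be in (0, 32)", p$id),
           call. = FALSE)
    }
    for (loc in names(p$gravity)) {
      g <- as.numeric(p$gravity[[loc]])
      if (length(g) != 3L || abs(sqrt(sum(g^2)) - 1) > 1e-6) {
        stop(sprintf("profile '%s': gravity orientation at %s is not a unit vector",
                     p$id, loc), call. = FALSE)
      }
      p$gravity[[loc]] <- g
    }
    if (any(unlist(p$amplitude_mg) < 0)) {
      stop(sprintf("profile '%s': amplitudes must be >= 0", p$id), call. = FALSE)
    }
    profs[[p$id]] <- p
  }
  structure(profs, class = "activity_profiles")
}

#' Cohort generator configuration
#'
#' Shapes the synthetic cohort: participant count, conditions, locations
#' and the between-person variability model. Between-person variability is
#' one lognormal amplitude multiplier per (participant, category), with a
#' per-category sigma; defaults give the largest spread to upper-body-driven
#' categories (adl, standing, jogging), where individual movement style
#' differs most, and near-none to lying.
#'
#' @param n_participants Number of participants (default 20).
#' @param conditions Character vector of condition ids (default: all in the
#'   profile set).
#' @param locations Wearing locations (default all six).
#' @param between_person_sd Either a single lognormal sigma or a named
#'   per-category vector.
#' @param duration_s Optional override of every condition's duration, in
#'   seconds (profiles' own durations used when `NULL`).
#' @param fs Sampling rate in Hz (default 64).
#' @param seed Integer seed governing all randomness.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 20, conditions = NULL,
                          locations = accel_locations(),
                          between_person_sd = c(
                            lying = 0.05, sitting = 0.08, standing = 0.25,
                            adl = 0.25, climbing_stairs = 0.12, walking = 0.10,
                            jogging = 0.25, cycling = 0.15),
                          duration_s = NULL, fs = 64, seed = 1) {
  if (n_participants < 1) stop("need n_participants >= 1", call. = FALSE)
  if (!is.null(duration_s) && duration_s < 30) {
    stop("condition durations must be >= 30 s to survive trimming", call. = FALSE)
  }
  for (l in locations) match_label(l, accel_locations(), "location")
  if (length(between_person_sd) > 1L) {
    miss <- setdiff(accel_categories(), names(between_person_sd))
    if (length(miss) > 0L) {
      stop(sprintf("between_person_sd lacks categories: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(n_participants = as.integer(n_participants),
                 conditions = conditions, locations = locations,
                 between_person_sd = between_person_sd,
                 duration_s = duration_s, fs = fs, seed = as.integer(seed)),
            class = "cohort_config")
}

# deterministic substream seed from a base seed and mixed keys; strings are
# hashed by their code points. Stays below 2^31.
substream_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (k in list(...)) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    h <- (h * 69069 + as.numeric(k)) %% 2147483647
  }
  as.integer(h)
}

category_sigma <- function(cfg, category) {
  s <- cfg$between_person_sd
  if (length(s) == 1L && is.null(names(s))) return(unname(s))
  unname(s[[category]])
}

unit_perp <- function(g) {
  e <- c(0, 1, 0)
  if (abs(sum(g * e)) > 0.99) e <- c(0, 0, 1)
  v <- e - sum(g * e) * g
  v / sqrt(sum(v^2))
}

#' Simulate one condition recording at one location
#'
#' Generates a 64 Hz triaxial signal as gravity (1 g along the profile's
#' orientation) plus a harmonic movement component along a fixed axis with
#' both a gravity-aligned and an orthogonal part, plus white Gaussian noise
#' per axis. Phases and noise are drawn from R's current RNG state, so the
#' output is deterministic under a fixed seed.
#'
#' @param profile One element of [activity_profiles()].
#' @param location Wearing-location label.
#' @param duration_s Duration in seconds (default: the profile's).
#' @param participant_multiplier Amplitude multiplier for between-person
#'   variability (default 1).
#' @param fs Sampling rate in Hz.
#' @param phases Optional harmonic phases in radians (drawn uniformly from
#'   the current RNG when `NULL`).
#' @return A [raw_signal()].
#' @export
simulate_condition <- function(profile, location, duration_s = NULL,
                               participant_multiplier = 1, fs = 64,
                               phases = NULL) {
  location <- match_label(location, accel_locations(), "location")
  if (is.null(duration_s)) duration_s <- profile$duration_s
  if (duration_s < 1) stop("duration must be >= 1 s", call. = FALSE)
  g <- as.numeric(profile$gravity[[location]])
  if (length(g) != 3L || abs(sqrt(sum(g^2)) - 1) > 1e-6) {
    stop("gravity orientation is not a unit vector", call. = FALSE)
  }
  A <- profile$amplitude_mg[[location]] / 1000
  f <- profile$fundamental_hz
  w <- unlist(profile$harmonics)
  k <- as.numeric(names(w))
  if (is.null(phases)) phases <- stats::runif(length(w), 0, 2 * pi)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  m <- numeric(n)
  for (i in seq_along(w)) {
    m <- m + w[i] * sin(2 * pi * k[i] * f * t + phases[i])
  }
  m <- participant_multiplier * A * m
  axis <- 0.6 * g + 0.8 * unit_perp(g)
  sd_g <- profile$noise_sd_mg / 1000
  clip <- function(v) pmin(pmax(v, -16), 16)
  raw_signal(
    x = clip(g[1] + m * axis[1] + stats::rnorm(n, 0, sd_g)),
    y = clip(g[2] + m * axis[2] + stats::rnorm(n, 0, sd_g)),
    z = clip(g[3] + m * axis[3] + stats::rnorm(n, 0, sd_g)),
    fs = fs
  )
}

cohort_plan <- function(cfg, profiles) {
  conds <- cfg$conditions
  if (is.null(conds)) conds <- names(profiles)
  miss <- setdiff(conds, names(profiles))
  if (length(miss) > 0L) {
    stop(sprintf("no profile for condition(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  conds
}

participant_multipliers <- function(cfg, profiles, conds) {
  cats <- unique(vapply(profiles[conds], `[[`, character(1), "category"))
  out <- expand.grid(participant = seq_len(cfg$n_participants),
                     category = cats, stringsAsFactors = FALSE)
  out$multiplier <- vapply(seq_len(nrow(out)), function(i) {
    sig <- category_sigma(cfg, out$category[i])
    if (sig == 0) return(1)
    withr::with_seed(
      substream_seed(cfg$seed, out$participant[i], out$category[i], 2L),
      stats::rlnorm(1, meanlog = -sig^2 / 2, sdlog = sig))
  }, numeric(1))
  out
}

#' Simulate a full synthetic cohort
#'
#' Generates one raw triaxial signal per (participant, condition, location)
#' together with a ground-truth manifest recording every multiplier and
#' profile parameter, for parameter-recovery tests. Every signal comes from
#' its own reproducible RNG substream keyed by (seed, participant,
#' condition, location), so results are independent of iteration order and
#' of which subset is generated. Harmonic phases are shared across locations
#' within a (participant, condition), mimicking one underlying movement
#' observed at several attachment sites.
#'
#' For large cohorts prefer [build_cohort()], which converts each signal to
#' metrics immediately instead of holding all raw signals in memory.
#'
#' @param cfg A [cohort_config()].
#' @param profiles An [activity_profiles()] set covering `cfg$conditions`.
#' @return A list with `signals` (nested list
#'   `[[participant]][[condition]][[location]]` of [raw_signal()]) and
#'   `manifest` (tibble of ground-truth parameters).
#' @export
simulate_cohort <- function(cfg, profiles = activity_profiles()) {
  stopifnot(inherits(cfg, "cohort_config"))
  conds <- cohort_plan(cfg, profiles)
  mult <- participant_multipliers(cfg, profiles, conds)
  signals <- list()
  manifest <- list()
  for (p in seq_len(cfg$n_participants)) {
    pname <- sprintf("P%02d", p)
    signals[[pname]] <- list()
    for (cond in conds) {
      prof <- profiles[[cond]]
      m_i <- mult$multiplier[mult$participant == p &
                               mult$category == prof$category]
      phases <- withr::with_seed(
        substream_seed(cfg$seed, p, cond, 1L),
        stats::runif(length(prof$harmonics), 0, 2 * pi))
      signals[[pname]][[cond]] <- list()
      for (loc in cfg$locations) {
        sig <- withr::with_seed(
          substream_seed(cfg$seed, p, cond, loc, 3L),
          simulate_condition(prof, loc, cfg$duration_s, m_i, cfg$fs,
                             phases = phases))
        signals[[pname]][[cond]][[loc]] <- sig
        manifest[[length(manifest) + 1L]] <- tibble::tibble(
          participant = pname, condition = cond, location = loc,
          category = prof$category, multiplier = m_i,
          amplitude_mg = prof$amplitude_mg[[loc]],
          fundamental_hz = prof$fundamental_hz,
          duration_s = if (is.null(cfg$duration_s)) prof$duration_s else cfg$duration_s,
          noise_sd_mg = prof$noise_sd_mg)
      }
    }
  }
  list(signals = signals, manifest = dplyr::bind_rows(manifest))
}

#' Aligned linear pair with known ground truth
#'
#' Seeded generator of two aligned second-level series with
#' `target = a * source + b + noise`, used as an oracle input for
#' conversion-model recovery tests.
#'
#' @param a,b True slope and intercept.
#' @param noise_sd SD of the Gaussian noise on the target.
#' @param n_seconds Number of aligned seconds (>= 10).
#' @param seed Integer seed.
#' @param source_range Range of the uniformly drawn source values.
#' @return A tibble with columns second, source, target.
#' @export
linear_pair_cohort <- function(a, b, noise_sd, n_seconds, seed,
                               source_range = c(0, 500)) {
  if (n_seconds < 10) stop("need n_seconds >= 10", call. = FALSE)
  withr::with_seed(seed, {
    source <- stats::runif(n_seconds, source_range[1], source_range[2])
    target <- a * source + b + stats::rnorm(n_seconds, 0, noise_sd)
  })
  tibble::tibble(second = seq_len(n_seconds) - 1L, source = source,
                 target = target)
}

#' Aligned saturating (nonlinear) pair
#'
#' Seeded generator of a Michaelis-Menten-style saturating relationship
#' `target = vmax * source / (k + source) + noise`, emulating a count-like
#' metric that compresses high intensities relative to an amplitude metric.
#'
#' @param vmax Saturation plateau.
#' @param k Half-saturation point, same units as source.
#' @param noise_sd SD of the Gaussian noise on the target.
#' @param n_seconds Number of aligned seconds.
#' @param seed Integer seed.
#' @param source_range Range of the uniformly drawn source values.
#' @return A tibble with columns second, source, target.
#' @export
saturating_pair_cohort <- function(vmax, k, noise_sd, n_seconds, seed,
                                   source_range = c(0, 500)) {
  withr::with_seed(seed, {
    source <- stats::runif(n_seconds, source_range[1], source_range[2])
    target <- vmax * source / (k + source) +
      stats::rnorm(n_seconds, 0, noise_sd)
  })
  tibble::tibble(second = seq_len(n_seconds) - 1L, source = source,
                 target = target)
}
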
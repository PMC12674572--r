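#' All four metrics for one raw signal
#'
#' Computes MAI, ENMO, MAD and per-second CPM (vector-magnitude counts
#' rescaled by 60) for one recording, at one-second epochs.
#'
#' @param signal A [raw_signal()].
#' @param filt A [filter_spec()] for the MAI band-pass.
#' @param count_cfg A [count_config()].
#' @param location,condition Labels carried into the series.
#' @return A named list of four [epoch_series()]: MAI, ENMO, MAD, CPM.
#' @export
signal_metrics <- function(signal, filt = filter_spec(),
                           count_cfg = count_config(),
                           location = NA_character_,
                           condition = NA_character_) {
  counts <- compute_counts(signal, count_cfg, 1, location, condition)
  list(
    MAI = compute_mai(signal, filt, 1, location, condition),
    ENMO = compute_enmo(signal, 1, location, condition),
    MAD = compute_mad(signal, 1, location, condition),
    CPM = counts_to_cpm(counts, "per_second")
  )
}

series_rows <- function(s, participant, category) {
  tibble::tibble(participant = participant, location = s$location,
                 condition = s$condition, category = category,
                 metric = s$metric, second = s$second_index,
                 value = s$values)
}

#' Build a second-level cohort table from a synthetic cohort
#'
#' Runs the full ingestion pipeline over a simulated cohort: for every
#' (participant, condition, location), simulate the raw 64 Hz signal,
#' compute the four metrics at one-second resolution, drop the first and
#' last `trim_s` seconds of each condition, truncate every condition to a
#' common length across participants, and attach superordinate activity
#' categories. Raw signals are converted one at a time and discarded, so
#' memory stays proportional to the epoch-level output.
#'
#' @param cfg A [cohort_config()].
#' @param profiles An [activity_profiles()] set.
#' @param filt A [filter_spec()] for MAI.
#' @param count_cfg A [count_config()].
#' @param trim_s Seconds trimmed from each end of every condition.
#' @param mapping Condition-to-category mapping (default: categories taken
#'   from the profiles themselves).
#' @return A cohort table: tibble with columns participant, location,
#'   condition, category, metric, second, value.
#' @export
build_cohort <- function(cfg, profiles = activity_profiles(),
                         filt = filter_spec(), count_cfg = count_config(),
                         trim_s = 5, mapping = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  conds <- cohort_plan(cfg, profiles)
  mult <- participant_multipliers(cfg, profiles, conds)
  chunks <- list()
  for (p in seq_len(cfg$n_participants)) {
    pname <- sprintf("P%02d", p)
    for (cond in conds) {
      prof <- profiles[[cond]]
      category <- if (is.null(mapping)) prof$category else {
        assign_categories(cond, mapping)
      }
      m_i <- mult$multiplier[mult$participant == p &
                               mult$category == prof$category]
      phases <- withr::with_seed(
        substream_seed(cfg$seed, p, cond, 1L),
        stats::runif(length(prof$harmonics), 0, 2 * pi))
      for (loc in cfg$locations) {
        sig <- withr::with_seed(
          substream_seed(cfg$seed, p, cond, loc, 3L),
          simulate_condition(prof, loc, cfg$duration_s, m_i, cfg$fs,
                             phases = phases))
        mets <- signal_metrics(sig, filt, count_cfg, loc, cond)
        mets <- lapply(mets, trim_condition, trim_s = trim_s)
        chunks[[length(chunks) + 1L]] <- dplyr::bind_rows(
          lapply(mets, series_rows, participant = pname, category = category))
      }
    }
  }
  cohort <- dplyr::bind_rows(chunks)
  truncate_cohort(cohort)
}

#' Truncate a cohort table to a common length per condition
#'
#' Cuts every (participant, location, metric) stream of one condition to
#' the minimum number of seconds observed for that condition, keeping the
#' earliest epochs, so all participants contribute equally.
#'
#' @param cohort A cohort table.
#' @return The truncated cohort table.
#' @export
truncate_cohort <- function(cohort) {
  check_cohort(cohort)
  lens <- cohort |>
    dplyr::group_by(.data$condition, .data$participant, .data$location,
                    .data$metric) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_min = min(.data$n), .groups = "drop")
  cohort |>
    dplyr::left_join(lens, by = "condition") |>
    dplyr::group_by(.data$condition, .data$participant, .data$location,
                    .data$metric) |>
    dplyr::arrange(.data$second, .by_group = TRUE) |>
    dplyr::filter(dplyr::row_number() <= .data$n_min) |>
    dplyr::ungroup() |>
    dplyr::select(-"n_min")
}
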
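#' Trial- and participant-level exclusion criteria
#'
#' The conventional rules: exclude trials with more than 15% missing samples
#' (strictly greater), trials with no keywords correct (pupil dilation is
#' uninformative at the intelligibility floor), and participants left with
#' fewer than 80% valid trials (strictly less). Unusable traces (flagged by
#' preprocessing) stand in for trials an analyst would have discarded on
#' visual inspection; a manual exclusion list can supplement them.
#'
#' @param max_missing_frac Missing-fraction threshold (exclusive).
#' @param exclude_zero_correct Exclude zero-keyword trials from pupil
#'   analyses (default `TRUE`). Behavioral intelligibility scoring always
#'   keeps scorable trials.
#' @param min_valid_participant_frac Minimum fraction of valid scorable
#'   trials to retain a participant (exclusive lower bound).
#' @return An `exclusion_criteria` list.
#' @export
exclusion_criteria <- function(max_missing_frac = 0.15,
                               exclude_zero_correct = TRUE,
                               min_valid_participant_frac = 0.80) {
  stopifnot(
    max_missing_frac >= 0, max_missing_frac <= 1,
    min_valid_participant_frac >= 0, min_valid_participant_frac <= 1,
    is.logical(exclude_zero_correct)
  )
  structure(
    list(
      max_missing_frac = max_missing_frac,
      exclude_zero_correct = exclude_zero_correct,
      min_valid_participant_frac = min_valid_participant_frac
    ),
    class = "exclusion_criteria"
  )
}

#' Apply trial-level exclusion rules
#'
#' Joins trial records with preprocessing QC and decides each trial with
#' exactly one primary reason, testing rules in a fixed order:
#' unusable trace, then missing fraction, then zero keywords correct (then
#' any manual exclusion). Familiarization trials are not scorable and are
#' dropped before deciding.
#'
#' @param trials Trial table (`participant_id, block_id, trial_index,
#'   speech_type, snr_db, keywords_correct`, optional `familiarization`).
#' @param qc QC tibble from [preprocess_trials()] (same keys, plus
#'   `missing_frac`, `usable`, `reason`).
#' @param criteria An [exclusion_criteria()].
#' @param manual_exclusions Optional tibble (`participant_id, block_id,
#'   trial_index, reason`) of analyst-flagged trials.
#' @return An `exclusion_report`: per-trial decisions tibble with `excluded`
#'   and `exclusion_reason`. Summaries via [summarize_exclusions()].
#' @export
exclude_trials <- function(trials, qc, criteria = exclusion_criteria(),
                           manual_exclusions = NULL) {
  keys <- c("participant_id", "block_id", "trial_index")
  if ("familiarization" %in% names(trials)) {
    trials <- dplyr::filter(trials, !.data$familiarization)
  }
  qc_cols <- c(keys, "missing_frac", "usable", "reason")
  if (!all(qc_cols %in% names(qc))) {
    stop_pupilgca("`qc` must carry missing_frac, usable and reason per trial")
  }
  joined <- left_join(
    trials, rename(qc[, qc_cols], trace_reason = "reason"), by = keys
  )
  if (anyNA(joined$usable)) {
    stop_pupilgca("QC metrics missing for some trials")
  }
  manual <- rep(FALSE, nrow(joined))
  if (!is.null(manual_exclusions)) {
    mk <- paste(joined$participant_id, joined$block_id, joined$trial_index)
    ek <- paste(manual_exclusions$participant_id, manual_exclusions$block_id,
                manual_exclusions$trial_index)
    manual <- mk %in% ek
  }
  decisions <- joined |>
    mutate(
      exclusion_reason = dplyr::case_when(
        !.data$usable ~ paste0("unusable-trace: ", .data$trace_reason),
        .data$missing_frac > criteria$max_missing_frac ~ "missing-fraction",
        criteria$exclude_zero_correct & .data$keywords_correct == 0 ~ "zero-correct",
        manual ~ "manual",
        TRUE ~ ""
      ),
      excluded = .data$exclusion_reason != ""
    )
  structure(
    list(decisions = decisions, criteria = criteria,
         excluded_participants = character(0)),
    class = "exclusion_report"
  )
}

#' Apply the participant-level exclusion rule
#'
#' Removes every participant whose fraction of valid (retained) scorable
#' trials is strictly below the criterion; all their trials are marked
#' excluded with reason `participant-excluded`.
#'
#' @param report An `exclusion_report` from [exclude_trials()].
#' @param criteria An [exclusion_criteria()].
#' @return The updated `exclusion_report` with `excluded_participants`.
#' @export
exclude_participants <- function(report, criteria = report$criteria) {
  frac <- report$decisions |>
    group_by(.data$participant_id) |>
    summarise(valid_frac = mean(!.data$excluded), .groups = "drop")
  dropped <- frac$participant_id[frac$valid_frac < criteria$min_valid_participant_frac]
  report$decisions <- report$decisions |>
    mutate(
      exclusion_reason = dplyr::if_else(
        .data$participant_id %in% dropped & !.data$excluded,
        "participant-excluded", .data$exclusion_reason
      ),
      excluded = .data$excluded | .data$participant_id %in% dropped
    )
  report$excluded_participants <- dropped
  report$participant_valid_frac <- frac
  report
}

#' Summarize an exclusion report by SNR
#'
#' @param report An `exclusion_report`.
#' @return A tibble: `snr_db`, `n_trials`, `n_excluded`, `pct_excluded`.
#' @export
summarize_exclusions <- function(report) {
  report$decisions |>
    group_by(.data$snr_db) |>
    summarise(
      n_trials = n(),
      n_excluded = sum(.data$excluded),
      pct_excluded = 100 * mean(.data$excluded),
      .groups = "drop"
    )
}

#' Trials retained for pupil analysis
#'
#' @param report An `exclusion_report`.
#' @return The decision rows with `excluded == FALSE`.
#' @export
retained_trials <- function(report) {
  dplyr::filter(report$decisions, !.data$excluded)
}

#' @export
print.exclusion_report <- function(x, ...) {
  s <- summarize_exclusions(x)
  cat("Exclusion report:", nrow(x$decisions), "scorable trials\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  SNR %+g dB: %d/%d excluded (%.1f%%)\n",
      s$snr_db[i], s$n_excluded[i], s$n_trials[i], s$pct_excluded[i]
    ))
  }
  if (length(x$excluded_participants)) {
    cat("  participants excluded:",
        paste(x$excluded_participants, collapse = ", "), "\n")
  }
  invisible(x)
}
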
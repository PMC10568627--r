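#' Preprocessing parameters
#'
#' The calibration chain's tunables, with the conventional defaults:
#' downsample to 50 Hz, flag samples more than 2 SD below the trial mean,
#' interpolate each missing run on a window from 5 samples before to 8
#' samples after the run, baseline over the 1 s preceding sentence onset,
#' analyze 0 to 4.5 s after onset, smooth with a 5-point moving average.
#'
#' @param target_rate Target sampling rate, Hz.
#' @param sd_threshold Artifact threshold in trial SDs below the trial mean.
#' @param interp_pre,interp_post Valid-sample support window around each
#'   missing run, in samples before / after the run.
#' @param baseline_window Half-open baseline window `[a, b)`, seconds.
#' @param analysis_window Closed analysis window `[a, b]`, seconds.
#' @param smooth_points Moving-average length (odd; 1 disables smoothing).
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(target_rate = 50,
                              sd_threshold = 2.0,
                              interp_pre = 5L,
                              interp_post = 8L,
                              baseline_window = c(-1.0, 0.0),
                              analysis_window = c(0.0, 4.5),
                              smooth_points = 5L) {
  stopifnot(
    target_rate > 0, sd_threshold > 0,
    is_count(interp_pre) && interp_pre >= 1,
    is_count(interp_post) && interp_post >= 1,
    length(baseline_window) == 2, diff(baseline_window) > 0,
    length(analysis_window) == 2, diff(analysis_window) > 0,
    is_count(smooth_points) && smooth_points >= 1
  )
  if (smooth_points %% 2 == 0) {
    stop_pupilgca("`smooth_points` must be odd")
  }
  structure(
    list(
      target_rate = target_rate, sd_threshold = sd_threshold,
      interp_pre = as.integer(interp_pre), interp_post = as.integer(interp_post),
      baseline_window = baseline_window, analysis_window = analysis_window,
      smooth_points = as.integer(smooth_points)
    ),
    class = "preprocess_params"
  )
}

#' Downsample one trial by block averaging
#'
#' Non-overlapping blocks of `factor = rate_hz / target_rate` samples are
#' reduced to their mean of valid samples; a block with fewer than half of
#' its samples valid becomes missing. Output timestamps are the block-start
#' times. The source rate must be an integer multiple of the target rate.
#'
#' @param t_s,pupil Sample times (s) and values (`NA` = missing).
#' @param rate_hz Source rate; `target_rate` the requested rate.
#' @param target_rate Target rate, Hz.
#' @return A list with `t_s` and `pupil` at the target rate.
#' @export
downsample <- function(t_s, pupil, rate_hz, target_rate = 50) {
  factor <- rate_hz / target_rate
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stop_pupilgca(sprintf(
      "source rate %.6g Hz is not an integer multiple of target %.6g Hz",
      rate_hz, target_rate
    ))
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(list(t_s = t_s, pupil = pupil))
  n_blocks <- length(pupil) %/% factor
  idx <- seq_len(n_blocks * factor)
  block <- rep(seq_len(n_blocks), each = factor)
  x <- pupil[idx]
  valid <- tapply(!is.na(x), block, sum)
  means <- tapply(x, block, function(v) mean(v, na.rm = TRUE))
  means[valid < factor / 2] <- NA_real_
  means[valid == 0] <- NA_real_
  list(
    t_s = t_s[seq(1, n_blocks * factor, by = factor)],
    pupil = as.numeric(means)
  )
}

#' Convert pupil area to diameter
#'
#' Tracker area counts (black-pixel counts) are converted to a
#' diameter-proportional scale by the circular-geometry map
#' \eqn{d = 2\sqrt{a/\pi}}; diameter input passes through unchanged. The
#' resulting pseudo-units cancel in the percent-dilation transform, which is
#' scale-free, so the conversion constant is irrelevant downstream.
#'
#' @param samples Numeric samples (`NA` = missing).
#' @param unit `"area"` or `"diameter"`.
#' @return Diameter-scale samples.
#' @export
area_to_diameter <- function(samples, unit = c("area", "diameter")) {
  unit <- match.arg(unit)
  if (unit == "diameter") return(samples)
  if (any(samples < 0, na.rm = TRUE)) {
    stop_pupilgca("negative area samples")
  }
  2 * sqrt(samples / pi)
}

#' Detect downward pupil artifacts
#'
#' Single-pass detector: using the trial's valid (non-missing) samples, a
#' sample more than `sd_threshold` standard deviations below the trial mean
#' is marked missing (blinks and partial occlusions shrink the apparent
#' pupil). Statistics are not re-estimated after flagging.
#'
#' @param samples Diameter-scale samples at the target rate.
#' @param sd_threshold Threshold in SD units (default 2).
#' @return A list: `mask` (logical, `TRUE` = missing, includes pre-existing
#'   missing), `usable`, `reason`.
#' @export
detect_artifacts <- function(samples, sd_threshold = 2.0) {
  valid <- !is.na(samples)
  if (sum(valid) < 4) {
    return(list(mask = rep(TRUE, length(samples)), usable = FALSE,
                reason = "detect_artifacts: no valid samples"))
  }
  mu <- mean(samples[valid])
  sigma <- sd(samples[valid])
  mask <- !valid | (samples < mu - sd_threshold * sigma & valid)
  mask[is.na(mask)] <- TRUE
  list(mask = mask, usable = TRUE, reason = "")
}

#' Interpolate missing runs with local least-squares lines
#'
#' For each maximal contiguous missing run, a least-squares line is fitted to
#' the valid samples inside the support window from `pre` samples before the
#' run to `post` samples after it, and evaluated at the missing positions.
#' A run touching the trace edge with no valid support on one side is filled
#' by extending the nearest valid value and flagged as an edge fill. Observed
#' samples are never altered.
#'
#' @param samples Numeric samples.
#' @param mask Logical missing mask aligned with `samples`.
#' @param pre,post Support-window extent in samples (defaults 5 and 8).
#' @return A list: `values` (filled trace), `interpolated` (logical),
#'   `edge` (logical, edge-extension fills), `usable`, `reason`.
#' @export
interpolate_missing <- function(samples, mask, pre = 5L, post = 8L) {
  n <- length(samples)
  stopifnot(length(mask) == n)
  out <- samples
  out[mask] <- NA_real_
  interpolated <- rep(FALSE, n)
  edge <- rep(FALSE, n)
  if (!any(mask)) {
    return(list(values = out, interpolated = interpolated, edge = edge,
                usable = TRUE, reason = ""))
  }
  if (all(mask)) {
    return(list(values = out, interpolated = interpolated, edge = edge,
                usable = FALSE,
                reason = "interpolate_missing: no valid samples"))
  }
  runs <- runs_of(mask)
  valid_idx <- which(!mask)
  for (r in seq_len(nrow(runs))) {
    a <- runs$start[r]
    b <- runs$end[r]
    lo <- max(1L, a - pre)
    hi <- min(n, b + post)
    sup <- valid_idx[valid_idx >= lo & valid_idx <= hi]
    has_left <- any(valid_idx < a)
    has_right <- any(valid_idx > b)
    miss <- a:b
    if (!has_left || !has_right) {
      # edge run: extend the nearest valid value
      nearest <- if (has_left) max(valid_idx[valid_idx < a]) else
        min(valid_idx[valid_idx > b])
      out[miss] <- samples[nearest]
      interpolated[miss] <- TRUE
      edge[miss] <- TRUE
      next
    }
    if (length(sup) < 2) {
      # support window starved (long run); widen to nearest valid neighbors
      sup <- c(max(valid_idx[valid_idx < a]), min(valid_idx[valid_idx > b]))
    }
    fit <- stats::lm.fit(cbind(1, sup), samples[sup])
    out[miss] <- fit$coefficients[1] + fit$coefficients[2] * miss
    interpolated[miss] <- TRUE
  }
  list(values = out, interpolated = interpolated, edge = edge,
       usable = TRUE, reason = "")
}

#' Baseline from the pre-onset window
#'
#' Mean of the (interpolated) samples in the half-open window
#' `[baseline_window[1], baseline_window[2])` — by default the one second
#' immediately preceding sentence onset.
#'
#' @param t_s,samples Times and interpolated samples.
#' @param original_mask Pre-interpolation missing mask, used for the QC
#'   missing fraction and the fully-missing check.
#' @param baseline_window Half-open window, seconds.
#' @return A list: `baseline`, `missing_frac` (pre-interpolation, within the
#'   window), `usable`, `reason`.
#' @export
compute_baseline <- function(t_s, samples, original_mask,
                             baseline_window = c(-1.0, 0.0)) {
  inw <- t_s >= baseline_window[1] & t_s < baseline_window[2]
  if (!any(inw)) {
    return(list(baseline = NA_real_, missing_frac = NA_real_, usable = FALSE,
                reason = "compute_baseline: window not covered"))
  }
  frac <- mean(original_mask[inw])
  if (all(original_mask[inw])) {
    return(list(baseline = NA_real_, missing_frac = 1, usable = FALSE,
                reason = "compute_baseline: window fully missing"))
  }
  b <- mean(samples[inw])
  if (!is.finite(b) || b <= 0) {
    return(list(baseline = b, missing_frac = frac, usable = FALSE,
                reason = "compute_baseline: non-positive baseline"))
  }
  list(baseline = b, missing_frac = frac, usable = TRUE, reason = "")
}

#' Event-related pupil dilation
#'
#' Percent change from baseline,
#' \eqn{ERPD(t) = (observation(t) - baseline)/baseline \times 100},
#' restricted to the analysis window (default 0 to 4.5 s after onset). The
#' transform is scale-free: rescaling the raw recording by any positive
#' constant leaves ERPD unchanged, which is what lets area-based and
#' millimeter-based recordings be analyzed identically.
#'
#' @param t_s,samples Times and interpolated diameter-scale samples.
#' @param baseline Positive baseline value.
#' @param analysis_window Closed window, seconds.
#' @return A list with `t_s` and `erpd` on the analysis grid.
#' @export
compute_erpd <- function(t_s, samples, baseline,
                         analysis_window = c(0.0, 4.5)) {
  if (!is.finite(baseline) || baseline <= 0) {
    stop_pupilgca("`baseline` must be positive")
  }
  inw <- t_s >= analysis_window[1] - 1e-12 & t_s <= analysis_window[2] + 1e-12
  list(
    t_s = t_s[inw],
    erpd = (samples[inw] - baseline) / baseline * 100
  )
}

#' Centered moving-average smoothing
#'
#' Length-preserving moving average of odd width; at the edges the window is
#' truncated symmetrically to the available neighbors, so constants and the
#' interior of affine traces pass through unchanged.
#'
#' @param x Numeric vector.
#' @param smooth_points Odd window length (1 = identity).
#' @return Smoothed vector, same length.
#' @export
smooth_ma <- function(x, smooth_points = 5L) {
  if (smooth_points %% 2 == 0 || smooth_points < 1) {
    stop_pupilgca("`smooth_points` must be odd and >= 1")
  }
  if (smooth_points == 1L) return(x)
  h <- (smooth_points - 1L) %/% 2L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(h, i - 1L, n - i)
    out[i] <- mean(x[(i - k):(i + k)])
  }
  out
}

#' Preprocess one trial to its dilation curve
#'
#' The full calibration chain, in order: downsample to the target rate,
#' convert area to diameter, detect downward artifacts (2 SD rule),
#' interpolate missing runs, compute the pre-onset baseline, transform to
#' percent dilation over the analysis window, smooth. Any stage can flag the
#' trial unusable; the failing stage is named in the reason.
#'
#' @param t_s,pupil One trial's times and raw samples.
#' @param unit `"area"` or `"diameter"`.
#' @param rate_hz Source sampling rate.
#' @param params A [preprocess_params()].
#' @return A list: `erpd` (tibble `t_s`, `erpd` or `NULL`), `qc` (one-row
#'   tibble: `baseline`, `missing_frac`, `edge_filled`, `usable`, `reason`).
#' @export
preprocess_trial <- function(t_s, pupil, unit, rate_hz,
                             params = preprocess_params()) {
  fail <- function(reason, missing_frac = NA_real_, baseline = NA_real_) {
    list(erpd = NULL, qc = tibble(
      baseline = baseline, missing_frac = missing_frac,
      edge_filled = FALSE, usable = FALSE, reason = reason
    ))
  }
  ds <- downsample(t_s, pupil, rate_hz, params$target_rate)
  d <- area_to_diameter(ds$pupil, unit)
  det <- detect_artifacts(d, params$sd_threshold)
  if (!det$usable) return(fail(det$reason, missing_frac = 1))
  # QC missing fraction: pre-interpolation, over baseline + analysis windows
  qc_win <- (ds$t_s >= params$baseline_window[1] & ds$t_s < params$baseline_window[2]) |
    (ds$t_s >= params$analysis_window[1] - 1e-12 &
       ds$t_s <= params$analysis_window[2] + 1e-12)
  missing_frac <- mean(det$mask[qc_win])
  itp <- interpolate_missing(d, det$mask, params$interp_pre, params$interp_post)
  if (!itp$usable) return(fail(itp$reason, missing_frac))
  bl <- compute_baseline(ds$t_s, itp$values, det$mask, params$baseline_window)
  if (!bl$usable) return(fail(bl$reason, missing_frac))
  er <- compute_erpd(ds$t_s, itp$values, bl$baseline, params$analysis_window)
  sm <- smooth_ma(er$erpd, params$smooth_points)
  list(
    erpd = tibble(t_s = er$t_s, erpd = sm),
    qc = tibble(
      baseline = bl$baseline, missing_frac = missing_frac,
      edge_filled = any(itp$edge), usable = TRUE, reason = ""
    )
  )
}

#' Preprocess a long table of trials
#'
#' Data-frame-first wrapper over [preprocess_trial()]: takes the long trace
#' tibble (as produced by [read_pupil_traces()] or
#' [simulate_experiment()]`$traces`) and returns one row per trial with QC
#' metrics and the dilation curve as a nested list-column.
#'
#' @param traces Long sample tibble; `unit` and `rate_hz` default to its
#'   attributes.
#' @param params A [preprocess_params()].
#' @param unit,rate_hz Overrides for the trace metadata.
#' @return A tibble, one row per trial: trial keys, `baseline`,
#'   `missing_frac`, `edge_filled`, `usable`, `reason`, and `erpd`
#'   (list-column of tibbles `t_s`, `erpd`). Use [erpd_long()] to unnest.
#' @export
preprocess_trials <- function(traces, params = preprocess_params(),
                              unit = NULL, rate_hz = NULL) {
  unit <- unit %||% attr(traces, "unit")
  rate_hz <- rate_hz %||% attr(traces, "rate_hz")
  if (is.null(unit) || is.null(rate_hz)) {
    stop_pupilgca("`unit` and `rate_hz` must be supplied or present as attributes")
  }
  flags <- attr(traces, "flags")
  keys <- c("participant_id", "block_id", "trial_index", "speech_type", "snr_db")
  groups <- traces |>
    group_by(across(all_of(keys))) |>
    tidyr::nest() |>
    ungroup()
  if (!is.null(flags)) {
    groups <- left_join(groups, flags[, c(keys, "usable", "reason")], by = keys)
  } else {
    groups$usable <- TRUE
    groups$reason <- ""
  }
  res <- purrr::pmap(
    list(groups$data, groups$usable, groups$reason),
    function(d, ok, why) {
      if (!ok) {
        return(list(erpd = NULL, qc = tibble(
          baseline = NA_real_, missing_frac = NA_real_,
          edge_filled = FALSE, usable = FALSE,
          reason = paste0("trace: ", why)
        )))
      }
      preprocess_trial(d$t_s, d$pupil, unit, rate_hz, params)
    }
  )
  qc <- dplyr::bind_rows(purrr::map(res, "qc"))
  out <- dplyr::bind_cols(groups[, keys], qc)
  out$erpd <- purrr::map(res, "erpd")
  out
}

#' Unnest preprocessed trials into a long dilation table
#'
#' @param preprocessed Output of [preprocess_trials()].
#' @param usable_only Keep only usable trials (default `TRUE`).
#' @return Long tibble: trial keys, `t_s`, `erpd`.
#' @export
erpd_long <- function(preprocessed, usable_only = TRUE) {
  x <- preprocessed
  if (usable_only) x <- dplyr::filter(x, .data$usable)
  x |>
    select(-"baseline", -"missing_frac", -"edge_filled", -"usable", -"reason") |>
    tidyr::unnest("erpd")
}
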
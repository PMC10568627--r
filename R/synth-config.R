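#' Configuration for a synthetic listening-effort experiment
#'
#' Defines the design and generative parameters of a simulated
#' speech-in-noise pupillometry experiment: one block per speech type x SNR
#' per participant, each trial a masked sentence with the masker starting
#' `pre_onset` seconds before sentence onset and stopping `post_offset`
#' seconds after sentence offset. Pupil traces follow condition-dependent
#' cubic dilation curves (on the orthogonal basis over the analysis window)
#' with per-participant random effects, AR(1) sample noise and blink
#' dropouts; keyword scores are binomial draws from per-speech-type logistic
#' psychometric functions of SNR; block effort ratings are inversely related
#' to intelligibility.
#'
#' @param n_participants Number of simulated listeners.
#' @param speech_types Ordered speech-type labels. The natural, unmodified
#'   voice ("plain") is the conventional reference level.
#' @param snrs Signal-to-noise ratios in dB, one block per speech type x SNR.
#'   Overridden by `mode`.
#' @param mode `"exp1"` (adverse SNRs -1, -3, -5 dB) or `"exp2"`
#'   (+20, +5, -1 dB); `NULL` leaves `snrs` as given.
#' @param trials_per_block Scored sentences per block.
#' @param familiarization_per_block Unscored lead-in sentences per block;
#'   listed in the trial table with `familiarization = TRUE`, no trace.
#' @param sampling_rate Trace sampling rate in Hz.
#' @param sentence_duration Nominal sentence length in seconds; each trial's
#'   realized duration is jittered by `duration_jitter` (uniform, relative).
#' @param pre_onset Masker lead before sentence onset, seconds (also the
#'   available baseline span).
#' @param post_offset Masker tail after sentence offset, seconds.
#' @param fixed_effects Data frame with columns `speech_type`, `b0`..`b3`:
#'   per-condition coefficients on the orthogonal cubic basis, in ERPD
#'   percent units (`b0` is the mean dilation over the analysis window).
#' @param re_cov 4x4 symmetric positive semi-definite covariance of the
#'   per-participant random deviations from `b0`..`b3`.
#' @param noise_sd Marginal SD of the AR(1) sample noise, ERPD percent.
#' @param ar_coef AR(1) coefficient in `[0, 1)`.
#' @param blink_rate Expected blinks per trial (Poisson).
#' @param blink_dur Mean dropout run length per blink, seconds.
#' @param baseline_mean,baseline_sd Across-participant mean and SD of the raw
#'   baseline pupil level (arbitrary units).
#' @param psychometric Data frame with columns `speech_type`, `midpoint`
#'   (dB SNR at 50% keyword probability) and `slope` (dB) of the logistic
#'   psychometric function \eqn{p = 1/(1 + e^{-(SNR - m)/s})}.
#' @param effort_gain Gain mapping `1 - mean block keyword probability` onto
#'   the 0-10 effort rating scale.
#' @param effort_noise_sd SD of Gaussian rating noise, rating units.
#' @param duration_jitter Relative half-width of the uniform sentence-duration
#'   jitter (0.1 = +/-10%).
#' @param pupil_unit `"area"` (tracker counts, converted downstream) or
#'   `"diameter"`.
#' @param analysis_window Analysis window in seconds from sentence onset.
#' @param seed Integer RNG seed; identical configs give identical datasets.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_participants = 24,
                         speech_types = c("plain", "Lombard", "SSDRC", "TTS"),
                         snrs = c(-1, -3, -5),
                         mode = NULL,
                         trials_per_block = 15,
                         familiarization_per_block = 5,
                         sampling_rate = 50,
                         sentence_duration = 2.0,
                         pre_onset = 2.0,
                         post_offset = 3.0,
                         fixed_effects = NULL,
                         re_cov = NULL,
                         noise_sd = 1.5,
                         ar_coef = 0.6,
                         blink_rate = 2,
                         blink_dur = 0.2,
                         baseline_mean = 1000,
                         baseline_sd = 150,
                         psychometric = NULL,
                         effort_gain = 10,
                         effort_noise_sd = 1,
                         duration_jitter = 0.1,
                         pupil_unit = c("area", "diameter"),
                         analysis_window = c(0, 4.5),
                         seed = 1L) {
  pupil_unit <- match.arg(pupil_unit)
  if (!is.null(mode)) {
    mode <- match.arg(mode, c("exp1", "exp2"))
    snrs <- if (mode == "exp1") c(-1, -3, -5) else c(20, 5, -1)
  }
  if (is.null(fixed_effects)) {
    fixed_effects <- default_fixed_effects(speech_types)
  }
  fixed_effects <- as_tibble(fixed_effects)
  req <- c("speech_type", "b0", "b1", "b2", "b3")
  if (!all(req %in% names(fixed_effects))) {
    stop_pupilgca("`fixed_effects` needs columns speech_type, b0..b3")
  }
  if (!all(speech_types %in% fixed_effects$speech_type)) {
    stop_pupilgca("`fixed_effects` must cover every speech type")
  }
  if (is.null(re_cov)) re_cov <- diag(c(4, 4, 2, 1))
  check_psd(re_cov, "re_cov")
  if (is.null(psychometric)) psychometric <- default_psychometric(speech_types)
  psychometric <- as_tibble(psychometric)
  if (!all(c("speech_type", "midpoint", "slope") %in% names(psychometric)) ||
      !all(speech_types %in% psychometric$speech_type)) {
    stop_pupilgca("`psychometric` needs speech_type, midpoint, slope for every speech type")
  }
  stopifnot(
    is_count(n_participants) && n_participants >= 1,
    length(speech_types) >= 1, length(snrs) >= 1,
    is_count(trials_per_block) && trials_per_block >= 1,
    is_count(familiarization_per_block) && familiarization_per_block >= 0,
    sampling_rate > 0, sentence_duration > 0,
    pre_onset > 0, post_offset >= 0,
    noise_sd >= 0, ar_coef >= 0 && ar_coef < 1,
    blink_rate >= 0, blink_dur >= 1 / sampling_rate,
    baseline_mean > 0, baseline_sd >= 0,
    effort_gain >= 0, effort_noise_sd >= 0,
    duration_jitter >= 0 && duration_jitter < 1,
    length(analysis_window) == 2, diff(analysis_window) > 0
  )
  # the analysis window must fit inside every jittered trial span
  min_span <- sentence_duration * (1 - duration_jitter) + post_offset
  if (analysis_window[2] > min_span) {
    stop_pupilgca(sprintf(
      "analysis window end (%.2f s) exceeds the shortest possible trial span (%.2f s)",
      analysis_window[2], min_span
    ))
  }
  if (analysis_window[1] < 0 || pre_onset < 1) {
    stop_pupilgca("trials must cover a 1-s baseline and a non-negative analysis start")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      speech_types = speech_types, snrs = snrs,
      trials_per_block = as.integer(trials_per_block),
      familiarization_per_block = as.integer(familiarization_per_block),
      sampling_rate = sampling_rate, sentence_duration = sentence_duration,
      pre_onset = pre_onset, post_offset = post_offset,
      fixed_effects = fixed_effects, re_cov = re_cov,
      noise_sd = noise_sd, ar_coef = ar_coef,
      blink_rate = blink_rate, blink_dur = blink_dur,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      psychometric = psychometric,
      effort_gain = effort_gain, effort_noise_sd = effort_noise_sd,
      duration_jitter = duration_jitter, pupil_unit = pupil_unit,
      analysis_window = analysis_window, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# Condition-dependent cubic curves in ERPD %, on the orthonormal basis.
# Plain natural speech sits between the intelligibility-enhanced styles
# (Lombard, SSDRC: smaller dilation, less effort) and synthetic TTS
# (largest dilation). b0 ordering: Lombard < SSDRC < plain < TTS.
default_fixed_effects <- function(speech_types) {
  defaults <- tibble(
    speech_type = c("plain", "Lombard", "SSDRC", "TTS"),
    b0 = c(9, 6, 6.5, 10.5),
    b1 = c(12, 9, 9.5, 13),
    b2 = c(-6, -4, -4.5, -6.5),
    b3 = c(-3, -2, -2, -3.5)
  )
  missing <- setdiff(speech_types, defaults$speech_type)
  if (length(missing)) {
    extra <- tibble(
      speech_type = missing,
      b0 = 8, b1 = 10, b2 = -5, b3 = -2.5
    )
    defaults <- bind_rows(defaults, extra)
  }
  defaults[defaults$speech_type %in% speech_types, , drop = FALSE]
}

# Logistic psychometric functions of SNR per speech style. Enhanced styles
# have lower midpoints (intelligible at worse SNR), TTS the highest.
default_psychometric <- function(speech_types) {
  defaults <- tibble(
    speech_type = c("plain", "Lombard", "SSDRC", "TTS"),
    midpoint = c(-5, -8, -7.5, -2),
    slope = c(2, 2, 2, 2)
  )
  missing <- setdiff(speech_types, defaults$speech_type)
  if (length(missing)) {
    defaults <- bind_rows(
      defaults,
      tibble(speech_type = missing, midpoint = -5, slope = 2)
    )
  }
  defaults[defaults$speech_type %in% speech_types, , drop = FALSE]
}

#' Keyword probability from the logistic psychometric function
#'
#' @param snr SNR in dB (vectorized).
#' @param midpoint SNR at 50% keyword probability, dB.
#' @param slope Psychometric slope parameter, dB.
#' @return Probability in `[0, 1]`.
#' @export
psychometric_p <- function(snr, midpoint, slope) {
  1 / (1 + exp(-(snr - midpoint) / slope))
}
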
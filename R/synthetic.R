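#' Latin-square block order
#'
#' Cyclic Latin square used to balance block order across listeners: row
#' `participant_index` of the square is the 0-based condition order for that
#' participant. Stacking the rows for participants `0 .. n_conditions - 1`
#' gives a Latin square (each condition once per row and per column);
#' `participant_index` is taken modulo `n_conditions`.
#'
#' @param n_conditions Number of conditions (blocks).
#' @param participant_index 0-based participant index.
#' @return Integer vector of 0-based condition indices.
#' @examples
#' latin_square_order(4, 0) # 0 1 2 3
#' latin_square_order(4, 1) # 1 2 3 0
#' @export
latin_square_order <- function(n_conditions, participant_index) {
  if (!is_count(n_conditions) || n_conditions < 1) {
    stop_pupilgca("`n_conditions` must be a positive integer")
  }
  if (!is_count(participant_index) || participant_index < 0) {
    stop_pupilgca("`participant_index` must be a non-negative integer")
  }
  i <- participant_index %% n_conditions
  as.integer((i + seq_len(n_conditions) - 1L) %% n_conditions)
}

#' Simulate a keyword score for one trial
#'
#' Binomial draw over the sentence's keywords (five per sentence in the
#' Harvard-sentence design, the maximum score).
#'
#' @param p_correct Per-keyword probability of a correct report.
#' @param n_keywords Keywords per sentence (default 5).
#' @return Integer count in `[0, n_keywords]`.
#' @export
simulate_behavior <- function(p_correct, n_keywords = 5) {
  if (!is.numeric(p_correct) || anyNA(p_correct) ||
      any(p_correct < 0) || any(p_correct > 1)) {
    stop_pupilgca("`p_correct` must lie in [0, 1]")
  }
  rbinom(length(p_correct), size = n_keywords, prob = p_correct)
}

# Stationary AR(1) noise with marginal SD `sd`.
ar1_noise <- function(n, sd, phi) {
  if (sd == 0 || n == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  if (n > 1) {
    e <- rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) x[i] <- phi * x[i - 1] + e[i - 1]
  }
  x
}

#' Simulate a complete listening-effort experiment
#'
#' Generates trial-epoched pupil traces and behavioral tables for every
#' participant under a `synth_config`, together with the ground truth used to
#' generate them. Each participant hears one block per speech type x SNR, in
#' cyclic Latin-square order; each scored trial yields a raw trace spanning
#' `[-pre_onset, duration + post_offset]` seconds around sentence onset. The
#' raw trace is `baseline_i * (1 + ERPD(t)/100)` where the event-related
#' dilation is a participant-specific cubic curve on the analysis window
#' (zero before onset, held at its end value after the window), plus AR(1)
#' noise; blinks first shrink 2-3 samples toward 40-70% of the local level
#' (partial occlusion) and then drop out as missing runs. Keyword scores are
#' binomial with logistic psychometric probabilities; block effort ratings
#' are a noisy, clipped, inverse-intelligibility link on the 0-10 scale.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_experiment`:
#'   `traces` (long tibble: participant_id, block_id, trial_index,
#'   speech_type, snr_db, t_s, pupil, with `unit` and `rate_hz` attributes),
#'   `trials` (one row per trial incl. familiarization flag and
#'   keywords_correct), `ratings` (one row per block), and `truth`
#'   (fixed effects, per-participant random effects, per-condition keyword
#'   probabilities, baselines, seed).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop_pupilgca("`config` must be created by synth_config()")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  rate <- config$sampling_rate
  aw <- config$analysis_window
  k_aw <- round(aw * rate)
  grid <- seq(k_aw[1], k_aw[2]) / rate
  basis <- orthogonal_poly_basis(grid, degree = 3)
  bmat <- cbind(1, as.matrix(basis[, c("t1", "t2", "t3")]))

  conds <- tidyr::crossing(
    speech_type = factor(config$speech_types, levels = config$speech_types),
    snr_db = config$snrs
  )
  conds$speech_type <- as.character(conds$speech_type)
  conds$condition <- seq_len(nrow(conds))
  conds <- left_join(conds, config$psychometric, by = "speech_type")
  conds$p_keyword <- psychometric_p(conds$snr_db, conds$midpoint, conds$slope)

  fe <- config$fixed_effects
  fe_mat <- as.matrix(fe[, c("b0", "b1", "b2", "b3")])
  rownames(fe_mat) <- fe$speech_type

  pid <- sprintf("P%02d", seq_len(config$n_participants))
  re <- MASS::mvrnorm(config$n_participants, mu = rep(0, 4), Sigma = config$re_cov)
  re <- matrix(re, ncol = 4)
  baselines <- abs(rnorm(config$n_participants, config$baseline_mean, config$baseline_sd))

  n_cond <- nrow(conds)
  traces <- vector("list", config$n_participants * n_cond)
  trials <- vector("list", config$n_participants * n_cond)
  ratings <- vector("list", config$n_participants * n_cond)
  slot <- 0L

  for (i in seq_len(config$n_participants)) {
    order0 <- latin_square_order(n_cond, i - 1L)
    for (pos in seq_len(n_cond)) {
      cond <- conds[order0[pos] + 1L, ]
      block_id <- sprintf("B%02d", pos)
      curve <- as.numeric(bmat %*% (fe_mat[cond$speech_type, ] + re[i, ]))
      blk <- simulate_block(config, curve, baselines[i], cond, rate, k_aw)
      blk$trials$participant_id <- pid[i]
      blk$trials$block_id <- block_id
      if (nrow(blk$trace)) {
        blk$trace$participant_id <- pid[i]
        blk$trace$block_id <- block_id
      }
      rating <- round(clamp(
        config$effort_gain * (1 - cond$p_keyword) +
          rnorm(1, 0, config$effort_noise_sd),
        0, 10
      ))
      slot <- slot + 1L
      traces[[slot]] <- blk$trace
      trials[[slot]] <- blk$trials
      ratings[[slot]] <- tibble(
        participant_id = pid[i], block_id = block_id,
        speech_type = cond$speech_type, snr_db = cond$snr_db,
        effort_rating = as.integer(rating)
      )
    }
  }

  trace_cols <- c(
    "participant_id", "block_id", "trial_index", "speech_type",
    "snr_db", "t_s", "pupil"
  )
  traces <- dplyr::bind_rows(traces)[, trace_cols]
  attr(traces, "unit") <- config$pupil_unit
  attr(traces, "rate_hz") <- rate
  attr(traces, "dialect") <- 1L
  trials <- dplyr::bind_rows(trials)[, c(
    "participant_id", "block_id", "trial_index", "speech_type", "snr_db",
    "familiarization", "keywords_correct"
  )]

  truth <- list(
    fixed_effects = fe,
    random_effects = tibble(
      participant_id = pid,
      b0 = re[, 1], b1 = re[, 2], b2 = re[, 3], b3 = re[, 4]
    ),
    condition_p = conds[, c("speech_type", "snr_db", "p_keyword")],
    baselines = tibble(participant_id = pid, baseline = baselines),
    analysis_grid = grid,
    seed = config$seed
  )
  structure(
    list(
      traces = traces, trials = trials,
      ratings = dplyr::bind_rows(ratings), truth = truth,
      config = config
    ),
    class = "synth_experiment"
  )
}

# One block: familiarization rows (no trace) then scored trials with traces.
simulate_block <- function(config, curve, baseline, cond, rate, k_aw) {
  n_fam <- config$familiarization_per_block
  n_tr <- config$trials_per_block
  trial_rows <- vector("list", n_fam + n_tr)
  trace_rows <- vector("list", n_tr)
  for (j in seq_len(n_fam)) {
    trial_rows[[j]] <- tibble(
      trial_index = j, speech_type = cond$speech_type, snr_db = cond$snr_db,
      familiarization = TRUE, keywords_correct = NA_integer_
    )
  }
  for (j in seq_len(n_tr)) {
    idx <- n_fam + j
    dur <- config$sentence_duration *
      (1 + runif(1, -config$duration_jitter, config$duration_jitter))
    kmin <- -round(config$pre_onset * rate)
    kmax <- floor((dur + config$post_offset) * rate + 1e-9)
    t_s <- seq(kmin, kmax) / rate
    k <- seq(kmin, kmax)
    erpd <- numeric(length(k))
    in_win <- k >= k_aw[1] & k <= k_aw[2]
    erpd[in_win] <- curve[k[in_win] - k_aw[1] + 1L]
    erpd[k > k_aw[2]] <- curve[length(curve)]
    erpd <- erpd + ar1_noise(length(k), config$noise_sd, config$ar_coef)
    diam <- baseline * (1 + erpd / 100)
    pupil <- if (config$pupil_unit == "area") pi * diam^2 / 4 else diam
    pupil <- insert_blinks(pupil, rate, config$blink_rate, config$blink_dur)
    trace_rows[[j]] <- tibble(
      trial_index = idx, speech_type = cond$speech_type, snr_db = cond$snr_db,
      t_s = t_s, pupil = pupil
    )
    trial_rows[[idx]] <- tibble(
      trial_index = idx, speech_type = cond$speech_type, snr_db = cond$snr_db,
      familiarization = FALSE,
      keywords_correct = simulate_behavior(cond$p_keyword, 5)
    )
  }
  list(trace = dplyr::bind_rows(trace_rows), trials = dplyr::bind_rows(trial_rows))
}

# Blink model: a short partial-occlusion dip (2-3 samples shrunk to 40-70%
# of the local level) immediately before a missing run whose length is
# exponential with mean `blink_dur` seconds.
insert_blinks <- function(pupil, rate, blink_rate, blink_dur) {
  n_blinks <- rpois(1, blink_rate)
  if (n_blinks == 0) return(pupil)
  n <- length(pupil)
  for (b in seq_len(n_blinks)) {
    len <- max(1L, as.integer(round(rexp(1, 1 / blink_dur) * rate)))
    # place the dropout run fully inside the trial
    start <- sample.int(max(1L, n - len + 1L), 1)
    dip_len <- sample(2:3, 1)
    dip_idx <- seq(start - dip_len, start - 1L)
    dip_idx <- dip_idx[dip_idx >= 1L]
    if (length(dip_idx)) {
      pupil[dip_idx] <- pupil[dip_idx] * runif(length(dip_idx), 0.4, 0.7)
    }
    miss_idx <- seq(start, min(n, start + len - 1L))
    pupil[miss_idx] <- NA_real_
  }
  pupil
}

#' Write a synthetic experiment to disk
#'
#' One trace file per participant in the epoch CSV dialect (see
#' [write_pupil_traces()]), plus `trials.csv`, `ratings.csv` and a
#' `truth.json` sidecar with the generating parameters.
#'
#' @param sim A `synth_experiment` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
write_experiment <- function(sim, dir) {
  if (!inherits(sim, "synth_experiment")) {
    stop_pupilgca("`sim` must come from simulate_experiment()")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (p in unique(sim$traces$participant_id)) {
    f <- file.path(dir, paste0("traces_", p, ".csv"))
    write_pupil_traces(
      dplyr::filter(sim$traces, .data$participant_id == p), f,
      unit = attr(sim$traces, "unit"), rate_hz = attr(sim$traces, "rate_hz")
    )
    files <- c(files, f)
  }
  trials_f <- file.path(dir, "trials.csv")
  ratings_f <- file.path(dir, "ratings.csv")
  readr::write_csv(sim$trials, trials_f)
  readr::write_csv(sim$ratings, ratings_f)
  truth_f <- file.path(dir, "truth.json")
  truth <- sim$truth
  truth$fixed_effects <- as.data.frame(truth$fixed_effects)
  truth$random_effects <- as.data.frame(truth$random_effects)
  truth$condition_p <- as.data.frame(truth$condition_p)
  truth$baselines <- as.data.frame(truth$baselines)
  jsonlite::write_json(truth, truth_f, digits = NA, auto_unbox = TRUE)
  invisible(c(files, trials_f, ratings_f, truth_f))
}
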
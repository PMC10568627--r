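#' Score a verbal response against sentence keywords
#'
#' Counts how many of the sentence's five preselected keywords appear in the
#' response: case-folded exact match after stripping punctuation, each
#' keyword credited at most once (duplicate keywords each need their own
#' matching token). Morphological variants are not credited.
#'
#' @param response_tokens Character vector of response words (or a single
#'   string, which is tokenized on non-word characters).
#' @param keywords The sentence's 5 keywords.
#' @return Integer count in `0..5`.
#' @export
score_keywords <- function(response_tokens, keywords) {
  if (length(keywords) != 5) {
    stop_pupilgca("exactly 5 keywords are required")
  }
  normalize <- function(x) {
    x <- tolower(x)
    x <- gsub("[^a-z0-9']+", " ", x)
    unlist(strsplit(trimws(x), "\\s+"))
  }
  tokens <- normalize(paste(response_tokens, collapse = " "))
  tokens <- tokens[nzchar(tokens)]
  keys <- vapply(keywords, function(k) normalize(k)[1], character(1))
  score <- 0L
  for (k in keys) {
    hit <- match(k, tokens)
    if (!is.na(hit)) {
      score <- score + 1L
      tokens <- tokens[-hit]
    }
  }
  score
}

#' Rationalized arcsine transform
#'
#' Studebaker's variance-stabilizing transform of a proportion correct
#' \eqn{x/n}: \eqn{\theta = \arcsin\sqrt{x/(n+1)} + \arcsin\sqrt{(x+1)/(n+1)}}
#' and \eqn{RAU = (146/\pi)\,\theta - 23}. RAU is approximately linear in
#' percent correct over the mid-range but remains well behaved at floor and
#' ceiling; it satisfies the complement identity
#' `rau(x, n) + rau(n - x, n) = 100`.
#'
#' @param x Number correct (vectorized).
#' @param n Number of items.
#' @return RAU values (roughly -23 to 123).
#' @export
rau_transform <- function(x, n) {
  if (any(n < 1) || any(x < 0 | x > n)) {
    stop_pupilgca("`x` must lie in [0, n], n >= 1")
  }
  theta <- asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))
  (146 / pi) * theta - 23
}

#' Repeated-measures correlation
#'
#' The common within-participant correlation between two repeatedly measured
#' variables, estimated by analysis of covariance: both variables share a
#' single slope while each participant keeps their own intercept. Writing
#' the ANCOVA fit `y ~ participant + x`, the correlation is
#' \eqn{r = \mathrm{sign}(b)\sqrt{SS_x/(SS_x + SS_{err})}} with error degrees
#' of freedom \eqn{df = N - k - 1} (N observations, k participants), and the
#' two-sided p-value comes from the t distribution on `df`.
#'
#' The estimate is invariant to adding any per-participant constant to
#' either variable: it measures the association within listeners, not the
#' between-listener association of their averages.
#'
#' @param data Data frame with one row per observation.
#' @param participant,x,y Columns (tidy-eval) holding the participant id and
#'   the two measures.
#' @return A one-row tibble: `r`, `df`, `p`, `n_obs`, `n_participants`.
#' @export
rmcorr_test <- function(data, participant, x, y) {
  pid <- factor(dplyr::pull(data, {{ participant }}))
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- stats::complete.cases(xv, yv, pid)
  pid <- droplevels(pid[keep]); xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  k <- nlevels(pid)
  if (k < 2 || any(table(pid) < 2)) {
    stop_pupilgca("need >= 2 participants with >= 2 observations each")
  }
  # within-participant centering; slope information requires variation in x
  xc <- xv - ave(xv, pid)
  if (all(abs(xc) < 1e-12)) {
    stop_pupilgca("`x` is constant within every participant")
  }
  fit <- lm(yv ~ pid + xv)
  # anova warns on numerically perfect fits (|r| = 1); harmless here
  a <- suppressWarnings(anova(fit))
  ss_x <- a["xv", "Sum Sq"]
  ss_err <- a["Residuals", "Sum Sq"]
  df <- a["Residuals", "Df"]
  if (df < 1) stop_pupilgca("not enough error degrees of freedom")
  slope <- coef(fit)[["xv"]]
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(r) * sqrt(df / (1 - r^2)), df)
  tibble(r = r, df = df, p = p, n_obs = n, n_participants = k)
}

#' Pearson correlation with t-based p-value
#'
#' Standard product-moment correlation for non-repeated measures (e.g. one
#' value per participant), as a tidy one-row tibble.
#'
#' @param data Data frame.
#' @param x,y Columns (tidy-eval).
#' @return A one-row tibble: `r`, `df`, `p`, `n`.
#' @export
pearson_cor <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- stats::complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) stop_pupilgca("need at least 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) stop_pupilgca("zero variance in x or y")
  ct <- stats::cor.test(xv, yv, method = "pearson")
  tibble(
    r = unname(ct$estimate), df = unname(ct$parameter),
    p = ct$p.value, n = length(xv)
  )
}

#' Per-condition behavioral summaries
#'
#' Mean percent keywords correct and mean effort rating per speech type x
#' SNR, with the participant as the unit of analysis: participant means are
#' computed first, then averaged across participants with their standard
#' error. Empty cells appear as `NA`, never zero. Familiarization trials are
#' dropped.
#'
#' @param trials Trial table with `keywords_correct` (0-5).
#' @param ratings Optional per-block effort-rating table.
#' @param n_keywords Keywords per sentence (default 5).
#' @return A tibble: `speech_type`, `snr_db`, `n_participants`,
#'   `pct_correct_mean`, `pct_correct_se`, and (with ratings)
#'   `effort_mean`, `effort_se`.
#' @export
condition_summary <- function(trials, ratings = NULL, n_keywords = 5) {
  if ("familiarization" %in% names(trials)) {
    trials <- dplyr::filter(trials, !.data$familiarization)
  }
  if (nrow(trials) == 0) stop_pupilgca("no scorable trials")
  per_part <- trials |>
    group_by(.data$speech_type, .data$snr_db, .data$participant_id) |>
    summarise(
      pct = 100 * mean(.data$keywords_correct) / n_keywords,
      .groups = "drop"
    )
  out <- per_part |>
    group_by(.data$speech_type, .data$snr_db) |>
    summarise(
      n_participants = n(),
      pct_correct_mean = mean(.data$pct),
      pct_correct_se = if (n() > 1) sd(.data$pct) / sqrt(n()) else 0,
      .groups = "drop"
    )
  if (!is.null(ratings)) {
    eff <- ratings |>
      group_by(.data$speech_type, .data$snr_db, .data$participant_id) |>
      summarise(eff = mean(.data$effort_rating), .groups = "drop") |>
      group_by(.data$speech_type, .data$snr_db) |>
      summarise(
        effort_mean = mean(.data$eff),
        effort_se = if (n() > 1) sd(.data$eff) / sqrt(n()) else 0,
        .groups = "drop"
      )
    out <- dplyr::full_join(out, eff, by = c("speech_type", "snr_db"))
  }
  arrange(out, .data$speech_type, dplyr::desc(.data$snr_db))
}

#' Per-participant cell scores in percent and RAU
#'
#' Aggregates keyword counts to the participant x speech type x SNR cell:
#' `x` = total keywords correct, `n` = keywords-per-sentence x trials in the
#' cell, plus `pct` and `rau` ([rau_transform()] applied to the cell
#' proportion). This is the response table for the behavioral mixed models.
#'
#' @inheritParams condition_summary
#' @return A tibble: `participant_id`, `speech_type`, `snr_db`, `x`, `n`,
#'   `pct`, `rau`.
#' @export
rau_cell_scores <- function(trials, n_keywords = 5) {
  if ("familiarization" %in% names(trials)) {
    trials <- dplyr::filter(trials, !.data$familiarization)
  }
  trials |>
    group_by(.data$participant_id, .data$speech_type, .data$snr_db) |>
    summarise(
      x = sum(.data$keywords_correct),
      n = n_keywords * n(),
      .groups = "drop"
    ) |>
    mutate(
      pct = 100 * .data$x / .data$n,
      rau = rau_transform(.data$x, .data$n)
    )
}
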
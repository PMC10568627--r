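#' Behavioral linear mixed model: SNR x speech type
#'
#' Models per-participant cell scores (intelligibility in RAU, or effort
#' ratings) with SNR and speech type as crossed categorical fixed effects
#' and a random per-participant intercept. The SNR x speech-type interaction
#' is tested two ways: primarily by a likelihood-ratio test between ML fits
#' with and without the interaction, and descriptively by the F statistic
#' with numerator df \eqn{(levels_{SNR}-1)(levels_{type}-1)} and a
#' containment denominator df \eqn{N - p - k + 1} (N cells, p fixed-effect
#' parameters, k participants).
#'
#' @param cell_scores One row per participant x speech type x SNR, e.g. from
#'   [rau_cell_scores()] (for `response = "rau"`) or a per-block rating
#'   table aggregated to cells (`response = "effort_rating"`).
#' @param response Response column name (`"rau"`, `"effort_rating"`, ...).
#' @param reference Reference speech type.
#' @return A `behavioral_lmm`: REML `lmerMod` (`fit`), tidy coefficients,
#'   `interaction` (one-row tibble: `chisq`, `df`, `p_lrt`, `F`, `df1`,
#'   `df2`, `p_f`), design metadata.
#' @export
fit_behavioral_lmm <- function(cell_scores, response = "rau",
                               reference = "plain") {
  needed <- c("participant_id", "speech_type", "snr_db", response)
  missing <- setdiff(needed, names(cell_scores))
  if (length(missing)) {
    stop_pupilgca(paste("cell_scores missing columns:", paste(missing, collapse = ", ")))
  }
  d <- as_tibble(cell_scores)
  lv <- unique(as.character(d$speech_type))
  if (reference %in% lv) lv <- c(reference, setdiff(lv, reference))
  d$speech_type <- factor(as.character(d$speech_type), levels = lv)
  d$snr_f <- factor(d$snr_db)
  d$participant_id <- factor(d$participant_id)
  d$.resp <- d[[response]]
  cell_n <- table(d$speech_type, d$snr_f)
  if (any(cell_n == 0)) stop_pupilgca("empty design cell(s)")
  if (sd(d$.resp) == 0) {
    # degenerate input: a constant response carries no interaction signal
    return(structure(
      list(
        fit = NULL, fit_ml = NULL,
        coefficients = tibble(
          term = "(Intercept)", estimate = d$.resp[1],
          std.error = 0, statistic = NA_real_, p.value = NA_real_
        ),
        response = response,
        interaction = tibble(
          chisq = 0,
          df = as.integer((nlevels(d$speech_type) - 1) * (nlevels(d$snr_f) - 1)),
          p_lrt = 1, F = 0,
          df1 = as.integer((nlevels(d$speech_type) - 1) * (nlevels(d$snr_f) - 1)),
          df2 = NA_integer_, p_f = 1
        ),
        anova = tibble(), n_obs = nrow(d),
        n_participants = nlevels(d$participant_id), data = d
      ),
      class = "behavioral_lmm"
    ))
  }

  fml_full <- .resp ~ speech_type * snr_f + (1 | participant_id)
  fml_add <- .resp ~ speech_type + snr_f + (1 | participant_id)
  fit <- suppressMessages(lme4::lmer(fml_full, data = d, REML = TRUE))
  fit_ml <- suppressMessages(lme4::lmer(fml_full, data = d, REML = FALSE))
  fit_add <- suppressMessages(lme4::lmer(fml_add, data = d, REML = FALSE))
  lrt_chisq <- max(0, 2 * (as.numeric(logLik(fit_ml)) - as.numeric(logLik(fit_add))))
  df1 <- (nlevels(d$speech_type) - 1) * (nlevels(d$snr_f) - 1)
  p_lrt <- pchisq(lrt_chisq, df1, lower.tail = FALSE)

  an <- anova(fit)
  f_int <- an["speech_type:snr_f", "F value"]
  n_obs <- nrow(d)
  p_fixed <- length(lme4::fixef(fit))
  k <- nlevels(d$participant_id)
  df2 <- n_obs - p_fixed - k + 1
  p_f <- pf(f_int, df1, df2, lower.tail = FALSE)

  sm <- summary(fit)$coefficients
  coefs <- tibble(
    term = rownames(sm), estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(2 * pnorm(-abs(sm[, "t value"])))
  )
  structure(
    list(
      fit = fit, fit_ml = fit_ml, coefficients = coefs,
      response = response,
      interaction = tibble(
        chisq = lrt_chisq, df = as.integer(df1), p_lrt = p_lrt,
        F = f_int, df1 = as.integer(df1), df2 = as.integer(df2), p_f = p_f
      ),
      anova = as_tibble(an, rownames = "term"),
      n_obs = n_obs, n_participants = k, data = d
    ),
    class = "behavioral_lmm"
  )
}

#' @export
print.behavioral_lmm <- function(x, ...) {
  cat("Behavioral LMM:", x$response,
      "~ speech_type * snr + (1 | participant)\n")
  cat(sprintf(
    "  interaction: chisq(%d) = %.2f, p = %.3g (LRT); F(%d, %d) = %.2f, p = %.3g\n",
    x$interaction$df, x$interaction$chisq, x$interaction$p_lrt,
    x$interaction$df1, x$interaction$df2, x$interaction$F, x$interaction$p_f
  ))
  invisible(x)
}

#' Tukey-adjusted pairwise speech-type contrasts
#'
#' Estimated marginal means for each speech type within each SNR, and all
#' pairwise speech-type differences with Tukey (studentized-range)
#' adjustment over the speech types. Degrees of freedom are asymptotic
#' (z statistics), consistent with the package's normal-approximation
#' inference.
#'
#' @param fit A `behavioral_lmm` from [fit_behavioral_lmm()].
#' @param adjust Multiplicity adjustment (default `"tukey"`).
#' @return A list of tibbles: `emmeans` (cell means) and `contrasts`
#'   (pairwise differences with adjusted p-values).
#' @export
emmeans_pairwise <- function(fit, adjust = "tukey") {
  if (!inherits(fit, "behavioral_lmm")) {
    stop_pupilgca("`fit` must come from fit_behavioral_lmm()")
  }
  emm <- emmeans::emmeans(
    fit$fit, ~ speech_type | snr_f,
    lmer.df = "asymptotic", data = fit$data
  )
  cons <- emmeans::contrast(emm, method = "pairwise", adjust = adjust)
  emm_tb <- as_tibble(as.data.frame(emm)) |>
    rename(snr_db = "snr_f") |>
    mutate(snr_db = as.numeric(as.character(.data$snr_db)))
  con_tb <- as_tibble(as.data.frame(cons)) |>
    rename(snr_db = "snr_f") |>
    mutate(snr_db = as.numeric(as.character(.data$snr_db)))
  list(emmeans = emm_tb, contrasts = con_tb)
}
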
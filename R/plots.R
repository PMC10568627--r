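#' Plot mean dilation curves by condition
#'
#' Across-participant mean event-related pupil dilation with a standard
#' error ribbon, one curve per speech type, faceted by SNR.
#'
#' @param erpd_long Long dilation table (`participant_id`, `speech_type`,
#'   `snr_db`, `t_s`, `erpd`).
#' @return A ggplot object.
#' @export
plot_erpd <- function(erpd_long) {
  summ <- erpd_long |>
    group_by(.data$speech_type, .data$snr_db, .data$t_s, .data$participant_id) |>
    summarise(erpd = mean(.data$erpd), .groups = "drop") |>
    group_by(.data$speech_type, .data$snr_db, .data$t_s) |>
    summarise(
      m = mean(.data$erpd),
      se = sd(.data$erpd) / sqrt(n()),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$t_s, y = .data$m,
    colour = .data$speech_type, fill = .data$speech_type
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$m - .data$se, ymax = .data$m + .data$se),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~snr_db, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "Time from sentence onset (s)", y = "ERPD (%)",
      colour = "Speech type", fill = "Speech type"
    ) +
    ggplot2::theme_minimal()
}

#' Plot observed and fitted growth curves
#'
#' Observed across-participant mean curves (points) with the fixed-effect
#' fitted curves (lines) of a growth-curve model.
#'
#' @param object A `gca_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gca_fit <- function(object, ...) {
  if (is.null(object$fit)) stop_pupilgca("cannot plot an unfitted model")
  d <- object$data
  d$fitted <- as.numeric(
    model.matrix(lme4::nobars(as.formula(object$formula)), d) %*%
      lme4::fixef(object$fit)
  )
  obs <- d |>
    group_by(.data$speech_type, .data$t_s) |>
    summarise(erpd = mean(.data$erpd), fitted = mean(.data$fitted),
              .groups = "drop")
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$t_s, colour = .data$speech_type)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$erpd), size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linewidth = 0.9) +
    ggplot2::labs(
      x = "Time from sentence onset (s)", y = "ERPD (%)",
      colour = "Speech type"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot behavioral condition summaries
#'
#' Mean percent correct (and, when present, mean effort rating) per speech
#' type across SNR, with standard error bars.
#'
#' @param summary_tbl Output of [condition_summary()].
#' @return A ggplot object.
#' @export
plot_condition_summary <- function(summary_tbl) {
  long <- summary_tbl |>
    tidyr::pivot_longer(
      cols = dplyr::any_of(c("pct_correct_mean", "effort_mean")),
      names_to = "measure", values_to = "mean"
    ) |>
    mutate(
      se = dplyr::if_else(
        .data$measure == "pct_correct_mean",
        .data$pct_correct_se,
        if ("effort_se" %in% names(summary_tbl)) .data$effort_se else NA_real_
      ),
      measure = dplyr::recode(.data$measure,
        pct_correct_mean = "Intelligibility (% correct)",
        effort_mean = "Effort rating (0-10)"
      )
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$snr_db, y = .data$mean, colour = .data$speech_type
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$se, ymax = .data$mean + .data$se
    )) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "SNR (dB)", y = NULL, colour = "Speech type") +
    ggplot2::theme_minimal()
}
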
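#' Pipeline run configuration
#'
#' A single object (optionally loaded from YAML via [read_run_config()])
#' controlling an end-to-end run. All the conventional analysis constants
#' (2 SD artifact threshold, 5/8-sample interpolation window, 15% and 80%
#' exclusion thresholds, 4.5 s analysis window, 5-point smoothing) live in
#' `preprocess` and `exclusion` and can be varied for sensitivity analyses.
#'
#' @param simulate Generate data from `synthetic` instead of reading files.
#' @param trace_paths,trial_table,rating_table Input paths (ignored when
#'   `simulate = TRUE`).
#' @param synthetic A [synth_config()] (or a list of its arguments).
#' @param preprocess A [preprocess_params()].
#' @param exclusion An [exclusion_criteria()].
#' @param covariates Candidate covariates for growth-curve model selection.
#' @param alpha LRT threshold for model selection.
#' @param seed Seed for the simulate path.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = TRUE,
                       trace_paths = NULL, trial_table = NULL,
                       rating_table = NULL,
                       synthetic = synth_config(),
                       preprocess = preprocess_params(),
                       exclusion = exclusion_criteria(),
                       covariates = character(0),
                       alpha = 0.05,
                       seed = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.list(synthetic) && !inherits(synthetic, "synth_config")) {
    synthetic <- do.call(synth_config, synthetic)
  }
  if (!is.null(seed)) synthetic$seed <- as.integer(seed)
  if (!simulate && is.null(trace_paths)) {
    stop_pupilgca("non-simulated runs need `trace_paths`")
  }
  structure(
    list(
      simulate = simulate, trace_paths = trace_paths,
      trial_table = trial_table, rating_table = rating_table,
      synthetic = synthetic, preprocess = preprocess,
      exclusion = exclusion, covariates = covariates, alpha = alpha
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file whose top-level keys mirror the [run_config()]
#'   arguments (`synthetic`, `preprocess`, `exclusion` as nested maps).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    simulate = y$simulate %||% TRUE,
    trace_paths = y$trace_paths, trial_table = y$trial_table,
    rating_table = y$rating_table,
    covariates = y$covariates %||% character(0),
    alpha = y$alpha %||% 0.05,
    seed = y$seed
  )
  if (!is.null(y$synthetic)) {
    syn <- y$synthetic
    if (!is.null(syn$re_cov)) syn$re_cov <- matrix(unlist(syn$re_cov), 4, 4)
    if (!is.null(syn$fixed_effects)) {
      syn$fixed_effects <- dplyr::bind_rows(syn$fixed_effects)
    }
    if (!is.null(syn$psychometric)) {
      syn$psychometric <- dplyr::bind_rows(syn$psychometric)
    }
    args$synthetic <- do.call(synth_config, syn)
  }
  if (!is.null(y$preprocess)) {
    args$preprocess <- do.call(preprocess_params, y$preprocess)
  }
  if (!is.null(y$exclusion)) {
    args$exclusion <- do.call(exclusion_criteria, y$exclusion)
  }
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' generate (or read) -> preprocess -> exclusions -> behavioral statistics
#' -> growth-curve models per SNR, with a reproducibility manifest. All
#' artifacts are returned in memory; pass `out_dir` to also write the CSV /
#' JSON bundle.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory for the artifact bundle.
#' @return A list of class `pipeline_result`: `erpd` (long table), `qc`,
#'   `exclusions` (report), `exclusion_summary`, `condition_summary`,
#'   `cell_scores`, `intelligibility_lmm`, `effort_lmm`, `contrasts`,
#'   `rmcorr` (intelligibility vs effort), `gca` (named list per SNR of
#'   `gca_selection`), `manifest`, and on the simulate path `truth`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_pupilgca(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }

  if (config$simulate) {
    sim <- stage("simulate", simulate_experiment(config$synthetic))
    traces <- sim$traces
    trials <- sim$trials
    ratings <- sim$ratings
    truth <- sim$truth
  } else {
    traces <- stage("read", read_pupil_traces(config$trace_paths))
    trials <- stage("read", read_trial_table(config$trial_table))
    ratings <- if (!is.null(config$rating_table)) {
      stage("read", read_rating_table(config$rating_table))
    }
    truth <- NULL
  }

  pp <- stage("preprocess", preprocess_trials(traces, config$preprocess))
  report <- stage("qc", {
    r <- exclude_trials(trials, pp, config$exclusion)
    exclude_participants(r, config$exclusion)
  })
  excl_summary <- summarize_exclusions(report)

  scorable <- if ("familiarization" %in% names(trials)) {
    dplyr::filter(trials, !.data$familiarization)
  } else trials
  cond_sum <- stage("behavioral", condition_summary(scorable, ratings))
  cells <- stage("behavioral", rau_cell_scores(scorable))
  # the SNR x speech-type models need a crossed design
  crossed <- length(unique(cells$snr_db)) >= 2 &&
    length(unique(cells$speech_type)) >= 2
  lmm_rau <- NULL
  contrasts <- NULL
  if (crossed) {
    lmm_rau <- stage("behavioral", fit_behavioral_lmm(cells, "rau"))
    contrasts <- stage("behavioral", emmeans_pairwise(lmm_rau))
  }
  lmm_eff <- NULL
  rm_res <- NULL
  if (!is.null(ratings)) {
    eff_cells <- ratings |>
      group_by(.data$participant_id, .data$speech_type, .data$snr_db) |>
      summarise(effort_rating = mean(.data$effort_rating), .groups = "drop")
    if (crossed) {
      lmm_eff <- stage("behavioral", fit_behavioral_lmm(eff_cells, "effort_rating"))
    }
    block_scores <- scorable |>
      group_by(.data$participant_id, .data$block_id) |>
      summarise(pct = 100 * mean(.data$keywords_correct) / 5, .groups = "drop")
    rm_data <- dplyr::inner_join(
      block_scores,
      ratings[, c("participant_id", "block_id", "effort_rating")],
      by = c("participant_id", "block_id")
    )
    rm_res <- stage(
      "behavioral",
      rmcorr_test(rm_data, "participant_id", "pct", "effort_rating")
    )
  }

  retained <- retained_trials(report)
  keys <- c("participant_id", "block_id", "trial_index")
  erpd <- erpd_long(pp) |>
    dplyr::semi_join(retained, by = keys)
  gca <- list()
  for (snr in sort(unique(erpd$snr_db), decreasing = TRUE)) {
    snr_data <- dplyr::filter(erpd, .data$snr_db == snr)
    gca[[paste0("snr_", snr)]] <- stage(
      paste0("gca@", snr, "dB"),
      select_model(snr_data, covariates = config$covariates,
                   alpha = config$alpha)
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pupilgca")),
    config_hash = rlang::hash(config),
    seed = if (config$simulate) config$synthetic$seed,
    n_trace_rows = nrow(traces),
    n_trials = nrow(trials),
    n_scorable = nrow(report$decisions),
    n_retained = nrow(retained),
    n_excluded = sum(report$decisions$excluded),
    excluded_participants = report$excluded_participants
  )

  res <- structure(
    list(
      erpd = erpd, qc = select(pp, -"erpd"), exclusions = report,
      exclusion_summary = excl_summary, condition_summary = cond_sum,
      cell_scores = cells, intelligibility_lmm = lmm_rau,
      effort_lmm = lmm_eff, contrasts = contrasts, rmcorr = rm_res,
      gca = gca, manifest = manifest, truth = truth
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_bundle(res, out_dir)
  res
}

# CSV/JSON artifact bundle for a pipeline result.
write_pipeline_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_erpd_long(res$erpd, file.path(out_dir, "erpd_long.csv"))
  readr::write_csv(res$qc, file.path(out_dir, "qc.csv"))
  readr::write_csv(res$exclusions$decisions, file.path(out_dir, "exclusions.csv"))
  readr::write_csv(res$exclusion_summary, file.path(out_dir, "exclusion_summary.csv"))
  readr::write_csv(res$condition_summary, file.path(out_dir, "condition_summary.csv"))
  readr::write_csv(res$cell_scores, file.path(out_dir, "cell_scores.csv"))
  if (!is.null(res$contrasts)) {
    readr::write_csv(res$contrasts$contrasts, file.path(out_dir, "contrasts.csv"))
  }
  if (!is.null(res$rmcorr)) {
    readr::write_csv(res$rmcorr, file.path(out_dir, "correlations.csv"))
  }
  gca_coefs <- purrr::imap(res$gca, function(g, nm) {
    mutate(tidy(g$fit), model = nm, formula = g$formula)
  })
  readr::write_csv(dplyr::bind_rows(gca_coefs), file.path(out_dir, "gca_coefficients.csv"))
  ladders <- purrr::imap(res$gca, ~ mutate(.x$ladder, model = .y))
  readr::write_csv(dplyr::bind_rows(ladders), file.path(out_dir, "gca_ladder.csv"))
  jsonlite::write_json(
    res$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("Pipeline result:", m$n_scorable, "scorable trials ->", m$n_retained,
      "retained,", m$n_excluded, "excluded\n")
  if (!is.null(x$rmcorr)) {
    cat(sprintf(
      "  rmcorr(intelligibility, effort): r = %.3f, df = %d, p = %.3g\n",
      x$rmcorr$r, x$rmcorr$df, x$rmcorr$p
    ))
  }
  cat("  GCA models:", paste(names(x$gca), collapse = ", "), "\n")
  invisible(x)
}
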
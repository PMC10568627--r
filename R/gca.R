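#' Growth-curve model formulas
#'
#' Builds the mixed-model formula for a cubic growth-curve analysis in the
#' package's mini-grammar. The full shape is
#' `erpd ~ (t1+t2+t3)*speech_type + (t1+t2+t3|participant_id)`; covariates
#' enter the fixed part the same way (`(t1+t2+t3)*covariate`). Lowering
#' `max_interaction_order` drops the highest polynomial x factor
#' interactions, giving the documented non-convergence fallbacks: order 2 is
#' `erpd ~ (t1+t2+t3) + speech_type + t1:speech_type + t2:speech_type +
#' (t1+t2+t3|participant_id)`.
#'
#' @param factor_name Name of the condition factor (default `speech_type`).
#' @param covariates Character vector of covariate column names.
#' @param degree Polynomial degree (default 3).
#' @param max_interaction_order Highest polynomial order interacting with
#'   the factor (`degree` = full model).
#' @param response,participant Response and grouping column names.
#' @return A string in the mini-grammar, parseable by [stats::as.formula()].
#' @export
gca_formula <- function(factor_name = "speech_type",
                        covariates = character(0),
                        degree = 3,
                        max_interaction_order = degree,
                        response = "erpd",
                        participant = "participant_id") {
  poly_terms <- paste0("t", seq_len(degree))
  poly_sum <- paste(poly_terms, collapse = "+")
  rhs <- if (is.null(factor_name)) {
    poly_sum
  } else if (max_interaction_order >= degree) {
    sprintf("(%s)*%s", poly_sum, factor_name)
  } else {
    ints <- if (max_interaction_order >= 1) {
      paste0("t", seq_len(max_interaction_order), ":", factor_name)
    } else character(0)
    paste(c(sprintf("(%s)", poly_sum), factor_name, ints), collapse = "+")
  }
  for (cv in covariates) {
    rhs <- paste0(rhs, sprintf("+(%s)*%s", poly_sum, cv))
  }
  sprintf("%s~%s+(%s|%s)", response, rhs, poly_sum, participant)
}

# Average trials to one curve per participant x condition (x covariates),
# then attach the orthogonal basis columns.
prepare_gca_data <- function(erpd_long, factor_name = "speech_type",
                             covariates = character(0), degree = 3,
                             reference = "plain") {
  needed <- c("participant_id", factor_name, "t_s", "erpd", covariates)
  missing <- setdiff(needed, names(erpd_long))
  if (length(missing)) {
    stop_pupilgca(paste("erpd data missing columns:", paste(missing, collapse = ", ")))
  }
  cells <- erpd_long |>
    group_by(across(all_of(c("participant_id", factor_name, covariates, "t_s")))) |>
    summarise(erpd = mean(.data$erpd), .groups = "drop")
  cells <- add_basis_columns(cells, time_col = "t_s", degree = degree)
  lv <- unique(as.character(cells[[factor_name]]))
  if (!is.null(reference) && reference %in% lv) {
    lv <- c(reference, setdiff(lv, reference))
  }
  cells[[factor_name]] <- factor(as.character(cells[[factor_name]]), levels = lv)
  cells$participant_id <- factor(cells$participant_id)
  cells
}

#' Fit a growth-curve mixed model
#'
#' Fits the Gaussian linear mixed model described by `formula_spec` to
#' dilation curves from a single SNR condition. Trials are first averaged to
#' one curve per participant x condition cell (random effects are
#' per-participant only, so trial-level curves would pseudo-replicate); the
#' orthogonal polynomial basis is evaluated on the realized analysis grid
#' and joined on. Fixed-effect inference treats the t statistic as a z
#' (normal approximation); use maximum likelihood (`reml = FALSE`) for
#' likelihood-ratio comparisons and REML for reported final estimates.
#'
#' Non-convergence is never silent: a rank-deficient fixed-effect design is
#' rejected before fitting (this is what a degenerate interaction cell
#' produces), optimizer failures are retried from perturbed starting values
#' (`restarts`), and the returned object carries `converged` and `singular`
#' flags.
#'
#' @param erpd_long Long dilation table (`participant_id`, `speech_type`,
#'   `t_s`, `erpd`, plus any covariates), one SNR at a time.
#' @param formula_spec Model formula string from [gca_formula()] (default:
#'   the full cubic-by-speech-type model).
#' @param reml Use REML (default `FALSE` = ML).
#' @param reference Reference level for the condition factor.
#' @param degree Polynomial degree of the basis.
#' @param restarts Deterministic optimizer restarts on non-convergence.
#' @return A `gca_fit`: tidy coefficient table (`estimate`, `std.error`,
#'   `statistic` = z, `p.value`), log-likelihood, convergence flags, the
#'   underlying `lmerMod`, and fitting metadata. Methods: [tidy()],
#'   [glance()], `print()`, [autoplot()].
#' @export
fit_gca <- function(erpd_long,
                    formula_spec = gca_formula(),
                    reml = FALSE,
                    reference = "plain",
                    degree = 3,
                    restarts = 3) {
  fml <- as.formula(formula_spec)
  vars <- all.vars(fml)
  factor_name <- if ("speech_type" %in% vars) "speech_type" else NULL
  covariates <- setdiff(
    vars,
    c("erpd", "participant_id", paste0("t", seq_len(degree)),
      factor_name)
  )
  data <- prepare_gca_data(
    erpd_long, factor_name = factor_name %||% "speech_type",
    covariates = covariates, degree = degree, reference = reference
  )
  fit_gca_prepared(data, formula_spec, reml = reml, restarts = restarts)
}

# Core fitter on prepared (cell-mean + basis) data.
fit_gca_prepared <- function(data, formula_spec, reml = FALSE, restarts = 3) {
  fml <- as.formula(formula_spec)
  fixed_fml <- lme4::nobars(fml)
  X <- model.matrix(stats::delete.response(stats::terms(fixed_fml)), data)
  rank_ok <- qr(X)$rank == ncol(X)
  base <- list(
    formula = formula_spec, reml = reml,
    n_obs = nrow(data), n_participants = nlevels(data$participant_id),
    data = data
  )
  if (!rank_ok) {
    out <- c(base, list(
      fit = NULL, coefficients = tibble(), loglik = NA_real_, df = NA_integer_,
      converged = FALSE, singular = NA,
      reason = "rank-deficient fixed-effect design"
    ))
    class(out) <- "gca_fit"
    return(out)
  }
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = data, REML = reml,
               control = lme4::lmerControl(calc.derivs = TRUE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  conv_failed <- function(m) {
    any(grepl("failed to converge|convergence code", m, ignore.case = TRUE)) ||
      !is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0
  }
  tries <- 0
  while (conv_failed(msgs) && tries < restarts) {
    tries <- tries + 1
    theta0 <- lme4::getME(fit, "theta")
    # deterministic perturbations; no RNG so caller seed state is untouched
    start <- switch(tries,
      pmax(theta0 * 0.5, 0.01),
      theta0 + 0.1,
      rep(1, length(theta0))
    )
    msgs <- character(0)
    fit <- withCallingHandlers(
      lme4::lmer(fml, data = data, REML = reml, start = start,
                 control = lme4::lmerControl(calc.derivs = TRUE)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      }
    )
  }
  converged <- !conv_failed(msgs)
  sm <- summary(fit)$coefficients
  coefs <- tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(2 * pnorm(-abs(sm[, "t value"])))
  )
  ll <- logLik(fit)
  out <- c(base, list(
    fit = fit, coefficients = coefs,
    loglik = as.numeric(ll), df = attr(ll, "df"),
    converged = converged, singular = lme4::isSingular(fit),
    reason = if (converged) "" else paste(unique(msgs), collapse = "; ")
  ))
  class(out) <- "gca_fit"
  out
}

#' @export
print.gca_fit <- function(x, ...) {
  cat("Growth-curve mixed model:", x$formula, "\n")
  cat(sprintf(
    "  %s fit, logLik %.2f, %d obs, %d participants%s%s\n",
    if (x$reml) "REML" else "ML", x$loglik, x$n_obs, x$n_participants,
    if (!isTRUE(x$converged)) " [NOT CONVERGED]" else "",
    if (isTRUE(x$singular)) " [singular]" else ""
  ))
  if (nrow(x$coefficients)) print(x$coefficients, n = Inf)
  invisible(x)
}

#' Likelihood-ratio test between nested growth-curve fits
#'
#' \eqn{\chi^2 = 2(\ell_{big} - \ell_{small})} on degrees of freedom equal
#' to the number of parameters added, with an upper-tail chi-square p-value.
#' Both fits must be maximum-likelihood (REML likelihoods are not comparable
#' across fixed-effect structures) on the same data, and the smaller model's
#' fixed terms must nest in the larger's.
#'
#' @param fit_small,fit_big `gca_fit` objects from ML fits.
#' @return A one-row tibble: `chisq`, `df`, `p`.
#' @export
lrt_compare <- function(fit_small, fit_big) {
  for (f in list(fit_small, fit_big)) {
    if (!inherits(f, "gca_fit")) stop_pupilgca("inputs must be gca_fit objects")
    if (isTRUE(f$reml)) stop_pupilgca("LRT requires ML fits, not REML")
    if (is.null(f$fit)) stop_pupilgca("cannot compare an unfitted model")
  }
  if (fit_small$n_obs != fit_big$n_obs) {
    stop_pupilgca("fits are not on the same data")
  }
  nest_ok <- all(
    attr(stats::terms(lme4::nobars(as.formula(fit_small$formula))), "term.labels") %in%
      attr(stats::terms(lme4::nobars(as.formula(fit_big$formula))), "term.labels")
  )
  df <- fit_big$df - fit_small$df
  if (!nest_ok || df < 0) stop_pupilgca("models are not nested")
  if (df == 0) return(tibble(chisq = 0, df = 0L, p = 1))
  chisq <- max(0, 2 * (fit_big$loglik - fit_small$loglik))
  tibble(chisq = chisq, df = as.integer(df), p = pchisq(chisq, df, lower.tail = FALSE))
}

#' Backward model selection with a non-convergence fallback ladder
#'
#' Starts from the complete model — all candidate covariates alongside the
#' speech-type factor, each crossed with the cubic orthogonal terms — and
#' removes every covariate whose deletion is not rejected by a
#' likelihood-ratio test at `alpha` (least significant first, refitting
#' after each removal). If a model does not converge (including a
#' rank-deficient interaction design), the fallback ladder drops the highest
#' remaining polynomial x speech-type interaction and refits: full model,
#' then without the cubic interaction, then without the quadratic. Every
#' comparison is recorded in the ladder. The selected model is refit with
#' REML for the reported estimates.
#'
#' @param erpd_long Long dilation table for one SNR.
#' @param covariates Candidate covariate column names (e.g. intelligibility).
#' @param alpha LRT retention threshold (default 0.05).
#' @param reference Reference speech type.
#' @param degree Polynomial degree.
#' @return A list of class `gca_selection`: `fit` (REML `gca_fit` of the
#'   selected model), `fit_ml` (its ML fit), `ladder` (tibble of every LRT
#'   and fallback step), `formula`.
#' @export
select_model <- function(erpd_long, covariates = character(0), alpha = 0.05,
                         reference = "plain", degree = 3) {
  data <- prepare_gca_data(
    erpd_long, factor_name = "speech_type",
    covariates = covariates, degree = degree, reference = reference
  )
  ladder <- list()
  note_step <- function(step, small, big, lrt, action) {
    ladder[[length(ladder) + 1]] <<- tibble(
      step = step, formula_small = small, formula_big = big,
      chisq = lrt$chisq %||% NA_real_, df = lrt$df %||% NA_integer_,
      p = lrt$p %||% NA_real_, action = action
    )
  }

  # descend the interaction ladder until the full candidate model converges
  max_order <- degree
  current_covs <- covariates
  fit_full <- NULL
  while (max_order >= 0) {
    fml <- gca_formula(
      covariates = current_covs, degree = degree,
      max_interaction_order = max_order
    )
    fit_full <- fit_gca_prepared(data, fml, reml = FALSE)
    if (isTRUE(fit_full$converged)) break
    note_step(
      "fallback", fml, fml, list(),
      sprintf("non-convergence (%s): dropping t%d:speech_type", fit_full$reason, max_order)
    )
    max_order <- max_order - 1
  }
  if (!isTRUE(fit_full$converged)) {
    stop_pupilgca(paste("no converging candidate model; last failure:", fit_full$reason))
  }

  # backward elimination over the candidate covariates
  repeat {
    if (!length(current_covs)) break
    tests <- purrr::map(current_covs, function(cv) {
      reduced <- gca_formula(
        covariates = setdiff(current_covs, cv), degree = degree,
        max_interaction_order = max_order
      )
      fit_red <- fit_gca_prepared(data, reduced, reml = FALSE)
      list(cov = cv, fml = reduced, fit = fit_red,
           lrt = lrt_compare(fit_red, fit_full))
    })
    ps <- purrr::map_dbl(tests, ~ .x$lrt$p)
    worst <- which.max(ps)
    t_ <- tests[[worst]]
    if (ps[worst] >= alpha) {
      note_step("drop-covariate", t_$fml, fit_full$formula, t_$lrt,
                sprintf("removed %s (p = %.3g >= %.3g)", t_$cov, ps[worst], alpha))
      current_covs <- setdiff(current_covs, t_$cov)
      fit_full <- t_$fit
    } else {
      for (i in seq_along(tests)) {
        note_step("keep-covariate", tests[[i]]$fml, fit_full$formula,
                  tests[[i]]$lrt,
                  sprintf("kept %s (p = %.3g < %.3g)", tests[[i]]$cov,
                          ps[i], alpha))
      }
      break
    }
  }

  best_fml <- gca_formula(
    covariates = current_covs, degree = degree,
    max_interaction_order = max_order
  )
  fit_reml <- fit_gca_prepared(data, best_fml, reml = TRUE)
  structure(
    list(
      fit = fit_reml, fit_ml = fit_full,
      ladder = if (length(ladder)) dplyr::bind_rows(ladder) else
        tibble(step = character(), formula_small = character(),
               formula_big = character(), chisq = double(),
               df = integer(), p = double(), action = character()),
      formula = best_fml
    ),
    class = "gca_selection"
  )
}

#' @export
print.gca_selection <- function(x, ...) {
  cat("Selected model:", x$formula, "\n")
  if (nrow(x$ladder)) {
    cat("Ladder:\n")
    print(x$ladder, n = Inf)
  }
  print(x$fit)
  invisible(x)
}
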
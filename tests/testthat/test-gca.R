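default_betas <- function() {
  m <- rbind(
    plain   = c(9, 12, -6, -3),
    Lombard = c(6, 9, -4, -2),
    SSDRC   = c(6.5, 9.5, -4.5, -2),
    TTS     = c(10.5, 13, -6.5, -3.5)
  )
  colnames(m) <- c("b0", "b1", "b2", "b3")
  m
}

test_that("the formula mini-grammar builds the documented model shapes", {
  expect_equal(
    gca_formula(),
    "erpd~(t1+t2+t3)*speech_type+(t1+t2+t3|participant_id)"
  )
  expect_equal(
    gca_formula(max_interaction_order = 2),
    "erpd~(t1+t2+t3)+speech_type+t1:speech_type+t2:speech_type+(t1+t2+t3|participant_id)"
  )
  expect_equal(
    gca_formula(factor_name = NULL),
    "erpd~t1+t2+t3+(t1+t2+t3|participant_id)"
  )
  expect_match(gca_formula(covariates = "intelligibility"),
               "\\(t1\\+t2\\+t3\\)\\*intelligibility", all = FALSE)
})

test_that("noise-free fits recover the generating coefficients", {
  withr::with_seed(71, {
    d <- simulate_gca_cells(
      n_participants = 8, betas = default_betas(),
      re_cov = diag(c(0, 0, 0, 0)) + 1e-12 * diag(4),
      noise_sd = 1e-4, ar_coef = 0, thin = 5
    )
  })
  fit <- fit_gca(d)
  est <- fit$coefficients
  B <- default_betas()
  truth <- c(
    B["plain", ],
    B["Lombard", ] - B["plain", ],
    B["SSDRC", ] - B["plain", ],
    B["TTS", ] - B["plain", ]
  )
  # treatment coding, reference plain: intercept block then type offsets
  expect_equal(est$estimate[est$term == "(Intercept)"], B["plain", "b0"],
               tolerance = 1e-4)
  expect_equal(est$estimate[est$term == "speech_typeTTS"],
               B["TTS", "b0"] - B["plain", "b0"], tolerance = 1e-4)
  expect_equal(est$estimate[est$term == "t1"], B["plain", "b1"],
               tolerance = 1e-4)
  expect_equal(est$estimate[est$term == "t3:speech_typeLombard"],
               B["Lombard", "b3"] - B["plain", "b3"], tolerance = 1e-4)
  # treatment coding has one row per (polynomial term) x (type contrast)
  expect_equal(nrow(est), length(truth))
})

test_that("fitted curves are invariant to the fixed-effect parameterization", {
  withr::with_seed(73, {
    d <- simulate_gca_cells(
      n_participants = 6, betas = default_betas()[c("plain", "TTS"), ],
      re_cov = diag(c(1, 1, 0.5, 0.25)), noise_sd = 1.5, thin = 10
    )
  })
  basis <- orthogonal_poly_basis(sort(unique(d$t_s)))
  dd <- dplyr::left_join(d, dplyr::rename(basis, t_s = time), by = "t_s")
  dd$participant_id <- factor(dd$participant_id)
  dd$speech_type <- factor(dd$speech_type, levels = c("plain", "TTS"))
  dd$r1 <- dd$t_s; dd$r2 <- dd$t_s^2; dd$r3 <- dd$t_s^3
  f_orth <- lme4::lmer(
    erpd ~ (t1 + t2 + t3) * speech_type + (t1 + t2 + t3 | participant_id),
    data = dd, REML = FALSE
  )
  f_raw <- lme4::lmer(
    erpd ~ (r1 + r2 + r3) * speech_type + (t1 + t2 + t3 | participant_id),
    data = dd, REML = FALSE
  )
  pred_orth <- model.matrix(~ (t1 + t2 + t3) * speech_type, dd) %*% lme4::fixef(f_orth)
  pred_raw <- model.matrix(~ (r1 + r2 + r3) * speech_type, dd) %*% lme4::fixef(f_raw)
  expect_lt(max(abs(pred_orth - pred_raw)), 1e-6)
})

test_that("likelihood-ratio comparisons count parameters and nest", {
  withr::with_seed(79, {
    d <- simulate_gca_cells(
      n_participants = 6, betas = default_betas(),
      re_cov = diag(c(2, 2, 1, 0.5)), noise_sd = 1.5, thin = 10
    )
  })
  full <- fit_gca(d, gca_formula(), reml = FALSE)
  eq3 <- fit_gca(d, gca_formula(max_interaction_order = 2), reml = FALSE)
  none <- fit_gca(d, gca_formula(factor_name = NULL), reml = FALSE)
  same <- lrt_compare(full, full)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  lrt <- lrt_compare(eq3, full)
  expect_equal(lrt$df, 3L) # t3 x each non-reference speech type
  lrt_all <- lrt_compare(none, full)
  expect_equal(lrt_all$df, 12L) # 16 - 4 fixed effects, random parts match
  expect_gte(lrt$chisq, 0)
  reml_fit <- fit_gca(d, gca_formula(), reml = TRUE)
  expect_error(lrt_compare(reml_fit, full), "ML")
  expect_error(lrt_compare(full, none), "not nested")
})

test_that("exchangeability: relabeling participants leaves estimates alone", {
  withr::with_seed(83, {
    d <- simulate_gca_cells(
      n_participants = 6, betas = default_betas()[c("plain", "TTS"), ],
      re_cov = diag(c(1, 1, 0.5, 0.25)), noise_sd = 1, thin = 10
    )
  })
  f1 <- fit_gca(d)
  relabeled <- dplyr::mutate(
    d, participant_id = chartr("123456", "642531", participant_id)
  )
  f2 <- fit_gca(relabeled)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("degenerate interaction designs trigger the fallback ladder", {
  # one speech type observed at only 3 distinct times: the cubic interaction
  # column is linearly dependent there, so the full model is rank-deficient
  grid <- seq(0, 4.5, by = 0.25)
  withr::with_seed(89, {
    plain <- tidyr::crossing(
      participant_id = sprintf("P%d", 1:6), t_s = grid
    ) |>
      dplyr::mutate(speech_type = "plain",
                    erpd = 8 + 2 * t_s - 0.5 * t_s^2 + rnorm(dplyr::n(), 0, 0.3))
    tts <- tidyr::crossing(
      participant_id = sprintf("P%d", 1:6), t_s = grid[c(1, 10, 19)]
    ) |>
      dplyr::mutate(speech_type = "TTS",
                    erpd = 10 + 1.5 * t_s + rnorm(dplyr::n(), 0, 0.3))
  })
  d <- dplyr::bind_rows(plain, tts)
  full_direct <- fit_gca(d, gca_formula())
  expect_false(full_direct$converged)
  expect_match(full_direct$reason, "rank-deficient")

  sel <- select_model(d)
  expect_equal(
    sel$formula,
    "erpd~(t1+t2+t3)+speech_type+t1:speech_type+t2:speech_type+(t1+t2+t3|participant_id)"
  )
  expect_true(any(grepl("dropping t3:speech_type", sel$ladder$action)))
  expect_true(sel$fit_ml$converged)
})

test_that("model selection keeps strong covariates and drops null ones", {
  withr::with_seed(97, {
    base <- simulate_gca_cells(
      n_participants = 10, betas = default_betas()[c("plain", "TTS"), ],
      re_cov = diag(c(1, 1, 0.5, 0.25)), noise_sd = 1, thin = 10
    )
    cells <- base |>
      dplyr::distinct(participant_id, speech_type) |>
      dplyr::mutate(
        null_cov = rnorm(dplyr::n()),
        strong_cov = rnorm(dplyr::n())
      )
    d <- dplyr::left_join(base, cells, by = c("participant_id", "speech_type")) |>
      dplyr::mutate(erpd = erpd + 5 * strong_cov)
  })
  sel <- select_model(d, covariates = c("null_cov", "strong_cov"))
  expect_false(grepl("null_cov", sel$formula))
  expect_true(grepl("strong_cov", sel$formula))
  expect_true(any(grepl("removed null_cov", sel$ladder$action)))
  expect_true(isTRUE(sel$fit$reml))
})

test_that("behavioral mixed model reports the interaction two ways", {
  withr::with_seed(101, {
    cells <- tidyr::crossing(
      participant_id = sprintf("P%02d", 1:20),
      speech_type = c("plain", "Lombard", "SSDRC", "TTS"),
      snr_db = c(-1, -3, -5)
    ) |>
      dplyr::mutate(
        rau = 50 + 5 * (snr_db + 3) + 10 * (speech_type == "Lombard") +
          3 * (speech_type == "TTS") * (snr_db == -5) +
          rnorm(dplyr::n(), 0, 4) +
          rep(rnorm(20, 0, 6), each = 12)
      )
  })
  fit <- fit_behavioral_lmm(cells, "rau")
  expect_equal(fit$interaction$df1, 6L) # (4-1)(3-1)
  expect_equal(fit$interaction$df2, 240 - 12 - 20 + 1)
  expect_true(fit$interaction$p_lrt > 0 && fit$interaction$p_lrt < 1)
  g <- glance(fit)
  expect_equal(g$n_participants, 20)

  flat <- dplyr::mutate(cells, rau = 42)
  fit_flat <- suppressMessages(fit_behavioral_lmm(flat, "rau"))
  expect_equal(fit_flat$interaction$F, 0, tolerance = 1e-8)

  one_cell_gone <- dplyr::filter(cells, !(speech_type == "TTS" & snr_db == -5))
  expect_error(fit_behavioral_lmm(one_cell_gone, "rau"), "empty design cell")
})

test_that("pairwise contrasts are Tukey-adjusted cell-mean differences", {
  withr::with_seed(103, {
    cells <- tidyr::crossing(
      participant_id = sprintf("P%02d", 1:12),
      speech_type = c("plain", "Lombard", "SSDRC", "TTS"),
      snr_db = c(-1, -5)
    ) |>
      dplyr::mutate(rau = 50 + 8 * (speech_type == "Lombard") +
                      rnorm(dplyr::n(), 0, 3))
  })
  fit <- fit_behavioral_lmm(cells, "rau")
  pw <- emmeans_pairwise(fit)
  expect_equal(nrow(pw$contrasts), 6 * 2) # C(4,2) pairs x 2 SNRs
  # balanced design: contrast estimates equal differences of cell means
  cm <- cells |>
    dplyr::group_by(speech_type, snr_db) |>
    dplyr::summarise(m = mean(rau), .groups = "drop")
  for (i in seq_len(nrow(pw$contrasts))) {
    parts <- strsplit(as.character(pw$contrasts$contrast[i]), " - ")[[1]]
    snr <- pw$contrasts$snr_db[i]
    expected <- cm$m[cm$speech_type == parts[1] & cm$snr_db == snr] -
      cm$m[cm$speech_type == parts[2] & cm$snr_db == snr]
    expect_equal(pw$contrasts$estimate[i], expected, tolerance = 1e-10)
  }
  # adjusted p >= unadjusted p for every contrast
  un <- emmeans_pairwise(fit, adjust = "none")
  expect_true(all(pw$contrasts$p.value >= un$contrasts$p.value - 1e-12))
  # identical cells give difference exactly 0 and adjusted p = 1
  wide <- cells |>
    dplyr::mutate(rau = dplyr::if_else(
      speech_type == "TTS",
      rau[match(paste(participant_id, "plain", snr_db),
                paste(participant_id, speech_type, snr_db))],
      rau
    ))
  fit_same <- fit_behavioral_lmm(wide, "rau")
  pw_same <- emmeans_pairwise(fit_same)$contrasts
  tts_rows <- grepl("plain - TTS", pw_same$contrast)
  expect_equal(pw_same$estimate[tts_rows], rep(0, 2), tolerance = 1e-10)
  expect_equal(pw_same$p.value[tts_rows], rep(1, 2), tolerance = 1e-9)
})
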
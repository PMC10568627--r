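test_that("keyword scoring is exact-match, case-folded, one credit each", {
  keys <- c("glow", "bright", "lamps", "dark", "room")
  expect_equal(score_keywords("The glow of bright lamps filled the dark room", keys), 5)
  expect_equal(score_keywords("", keys), 0)
  expect_equal(score_keywords(c("glow", "dark", "lamps", "and", "stuff"), keys), 3)
  # punctuation and case are stripped; a keyword is credited once
  expect_equal(score_keywords("GLOW, glow; glow!", keys), 1)
  # duplicate keywords need their own tokens
  expect_equal(score_keywords("sun sun", c("sun", "sun", "moon", "star", "sky")), 2)
  expect_error(score_keywords("x", c("a", "b")), "5 keywords")
})

test_that("RAU satisfies the complement identity and midpoint", {
  for (n in c(5, 20, 75)) {
    x <- 0:n
    expect_equal(rau_transform(x, n) + rau_transform(n - x, n),
                 rep(100, n + 1), tolerance = 1e-10)
  }
  expect_equal(rau_transform(10, 20), 50)
  expect_equal(rau_transform(50, 100), 50)
  # strictly increasing in x, range within [-23, 123]
  v <- rau_transform(0:300, 300)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > -23 & v < 123))
  expect_error(rau_transform(6, 5), "\\[0, n\\]")
})

test_that("RAU matches a direct evaluation of the transform", {
  direct <- function(x, n) {
    th <- asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))
    146 / pi * th - 23
  }
  expect_equal(rau_transform(100, 100), direct(100, 100), tolerance = 1e-10)
  expect_equal(rau_transform(0, 75), direct(0, 75), tolerance = 1e-10)
  expect_gt(rau_transform(100, 100), 100) # ceiling maps above 100
})

test_that("rmcorr recovers perfect common slopes", {
  d <- tidyr::crossing(pid = letters[1:6], x = 1:8) |>
    dplyr::mutate(y = 2 * x + as.integer(factor(pid)) * 10)
  res <- rmcorr_test(d, pid, x, y)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-10)
  res_neg <- rmcorr_test(dplyr::mutate(d, y = -x + as.integer(factor(pid))), pid, x, y)
  expect_equal(res_neg$r, -1)
  expect_equal(res$df, 6 * 8 - 6 - 1)
})

test_that("rmcorr equals the explicit ANCOVA least-squares oracle", {
  withr::with_seed(53, {
    for (rep in 1:10) {
      d <- tidyr::crossing(pid = sprintf("S%02d", 1:10), obs = 1:12) |>
        dplyr::mutate(
          x = rnorm(dplyr::n()),
          y = 0.6 * x + rnorm(dplyr::n()) +
            as.integer(factor(pid)) * runif(1, -2, 2)
        )
      got <- rmcorr_test(d, pid, x, y)
      ref <- rmcorr_oracle(d$pid, d$x, d$y)
      expect_equal(got$r, ref$r, tolerance = 1e-10)
      expect_equal(got$df, ref$df)
    }
  })
})

test_that("rmcorr is invariant to per-participant shifts", {
  withr::with_seed(59, {
    d <- tidyr::crossing(pid = letters[1:8], obs = 1:10) |>
      dplyr::mutate(x = rnorm(dplyr::n()), y = 0.5 * x + rnorm(dplyr::n()))
  })
  base <- rmcorr_test(d, pid, x, y)
  shifts <- setNames(runif(8, -100, 100), letters[1:8])
  d2 <- dplyr::mutate(d, x = x + shifts[pid], y = y - 2 * shifts[pid])
  expect_equal(rmcorr_test(d2, pid, x, y)$r, base$r, tolerance = 1e-10)
})

test_that("rmcorr rejects degenerate inputs", {
  d <- tibble::tibble(pid = c("a", "a", "b", "b"), x = c(1, 1, 2, 2), y = 1:4)
  expect_error(rmcorr_test(d, pid, x, y), "constant within")
  expect_error(
    rmcorr_test(tibble::tibble(pid = "a", x = 1, y = 1)[0, ], pid, x, y),
    ">= 2 participants"
  )
})

test_that("pearson correlation handles exact and sampled cases", {
  d <- tibble::tibble(x = c(1, 2, 4, 8), y = c(1, 2, 4, 8))
  expect_equal(pearson_cor(d, x, y)$r, 1)
  d2 <- dplyr::mutate(d, y = -3 * x + 7)
  expect_equal(pearson_cor(d2, x, y)$r, -1)
  withr::with_seed(61, {
    z <- MASS::mvrnorm(10000, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2))
  })
  big <- tibble::tibble(x = z[, 1], y = z[, 2])
  expect_lt(abs(pearson_cor(big, x, y)$r - 0.5), 0.03)
  expect_error(pearson_cor(tibble::tibble(x = c(1, 1, 1), y = 1:3), x, y),
               "zero variance")
})

test_that("condition summaries treat the participant as the unit", {
  trials <- tidyr::crossing(
    participant_id = c("P1", "P2"), speech_type = "plain", snr_db = -1,
    trial_index = 1:5
  ) |>
    dplyr::mutate(
      block_id = "B01",
      keywords_correct = ifelse(participant_id == "P1", 2L, 3L)
    )
  s <- condition_summary(trials)
  expect_equal(s$pct_correct_mean, 50) # (40% + 60%) / 2
  expect_equal(s$pct_correct_se, 10)
  same <- dplyr::mutate(trials, keywords_correct = 4L)
  expect_equal(condition_summary(same)$pct_correct_se, 0)
  # permutation invariance in trial order
  perm <- trials[sample(nrow(trials)), ]
  expect_equal(condition_summary(perm), s)
})

test_that("cell scores aggregate counts and transform to RAU", {
  trials <- tidyr::crossing(
    participant_id = "P1", speech_type = c("plain", "TTS"), snr_db = -1,
    trial_index = 1:4
  ) |>
    dplyr::mutate(block_id = "B", keywords_correct = 3L)
  cells <- rau_cell_scores(trials)
  expect_equal(cells$x, c(12, 12))
  expect_equal(cells$n, c(20, 20))
  expect_equal(cells$pct, c(60, 60))
  expect_equal(cells$rau, rau_transform(c(12, 12), 20))
})

test_that("generator intelligibility means match the psychometric truth", {
  cfg <- synth_config(
    n_participants = 12, trials_per_block = 10, familiarization_per_block = 0,
    snrs = c(-1, -5), blink_rate = 0, noise_sd = 0, seed = 67
  )
  sim <- simulate_experiment(cfg)
  s <- condition_summary(sim$trials)
  truth <- sim$truth$condition_p
  joined <- dplyr::left_join(s, truth, by = c("speech_type", "snr_db"))
  n_draws <- 12 * 10 * 5
  for (i in seq_len(nrow(joined))) {
    se <- 100 * sqrt(joined$p_keyword[i] * (1 - joined$p_keyword[i]) / n_draws)
    expect_lt(
      abs(joined$pct_correct_mean[i] - 100 * joined$p_keyword[i]),
      qnorm(0.9995) * se + 1e-9
    )
  }
})
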
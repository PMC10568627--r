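test_that("downsampling averages blocks and respects the half-valid rule", {
  t_s <- seq(0, 999) / 500
  const <- downsample(t_s, rep(3, 1000), 500, 50)
  expect_equal(const$pupil, rep(3, 100))
  expect_equal(diff(const$t_s)[1], 1 / 50)

  one_block <- downsample(seq(0, 9) / 500, 1:10, 500, 50)
  expect_equal(one_block$pupil, 5.5)

  x <- as.numeric(1:10)
  x[c(1, 2, 3, 5, 7, 9)] <- NA # 6 of 10 missing
  expect_true(is.na(downsample(seq(0, 9) / 500, x, 500, 50)$pupil))
  x2 <- as.numeric(1:10)
  x2[1:5] <- NA # exactly half valid -> mean of the valid half
  expect_equal(downsample(seq(0, 9) / 500, x2, 500, 50)$pupil, 8)

  expect_error(downsample(t_s, rep(1, 1000), 120, 50), "integer multiple")
})

test_that("area-to-diameter is the circular geometry map", {
  expect_equal(area_to_diameter(pi, "area"), 2)
  expect_equal(area_to_diameter(0, "area"), 0)
  expect_equal(area_to_diameter(c(3, NA, 5), "diameter"), c(3, NA, 5))
  expect_true(is.na(area_to_diameter(c(1, NA), "area")[2]))
  expect_error(area_to_diameter(-1, "area"), "negative")
  # scaling areas by c scales diameters by sqrt(c)
  withr::with_seed(5, a <- runif(100, 10, 100))
  expect_equal(area_to_diameter(a * 4, "area"),
               2 * area_to_diameter(a, "area"), tolerance = 1e-12)
})

test_that("artifact detection matches a hand-computed oracle", {
  expect_equal(sum(detect_artifacts(rep(5, 50))$mask), 0) # sigma = 0

  x <- c(rep(5, 100), rep(1, 3))
  mu <- mean(x); sg <- sd(x)
  expect_true(1 < mu - 2 * sg) # the hand oracle's premise
  det <- detect_artifacts(x)
  expect_equal(which(det$mask), 101:103)

  all_missing <- detect_artifacts(rep(NA_real_, 20))
  expect_false(all_missing$usable)
  expect_match(all_missing$reason, "no valid samples")
})

test_that("interpolation reconstructs lines and matches brute force", {
  # single missing sample on linear data
  x <- c(2, 3, 4, NA, 6, 7, 8)
  res <- interpolate_missing(x, is.na(x))
  expect_equal(res$values[4], 5)
  expect_false(any(res$edge))

  # affine traces are reconstructed exactly for any interior run
  aff <- 0.5 + 0.25 * (1:60)
  for (run in list(10:13, 30:44, 58:59)) {
    y <- aff; y[run] <- NA
    got <- interpolate_missing(y, is.na(y))
    expect_equal(got$values, aff, tolerance = 1e-12)
    expect_equal(which(got$interpolated), run)
  }

  # observed samples never altered; brute-force oracle agreement
  withr::with_seed(23, {
    for (rep in 1:20) {
      x <- cumsum(rnorm(80)) + 50
      miss <- rep(FALSE, 80)
      a <- sample(5:70, 1)
      miss[a:(a + 3)] <- TRUE
      got <- interpolate_missing(x, miss)
      ref <- brute_force_fill(x, miss)
      expect_equal(got$values, ref, tolerance = 1e-10)
      expect_equal(got$values[!miss], x[!miss])
    }
  })

  # edge runs fall back to nearest-value extension and are flagged
  y <- c(NA, NA, 4, 5, 6)
  got <- interpolate_missing(y, is.na(y))
  expect_equal(got$values, c(4, 4, 4, 5, 6))
  expect_equal(which(got$edge), 1:2)

  all_na <- interpolate_missing(rep(NA_real_, 5), rep(TRUE, 5))
  expect_false(all_na$usable)
})

test_that("baseline uses the half-open pre-onset second", {
  t_s <- seq(-100, 225) / 50
  x <- rep(4, length(t_s))
  bl <- compute_baseline(t_s, x, rep(FALSE, length(t_s)))
  expect_equal(bl$baseline, 4)
  # exactly 50 samples enter at 50 Hz: [-1, 0)
  expect_equal(sum(t_s >= -1 & t_s < 0), 50)
  step <- ifelse(t_s < -0.5, 3, 5)
  expect_equal(compute_baseline(t_s, step, rep(FALSE, length(t_s)))$baseline, 4)
  # fully-missing window is unusable
  m <- t_s >= -1 & t_s < 0
  expect_false(compute_baseline(t_s, x, m)$usable)
})

test_that("percent dilation is baseline-anchored and scale-free", {
  t_s <- seq(-50, 225) / 50
  x <- rep(4, length(t_s))
  e <- compute_erpd(t_s, x, 4)
  expect_equal(e$erpd, rep(0, length(e$t_s)))
  expect_equal(length(e$t_s), 226)
  expect_equal(compute_erpd(0, 4.2, 4.0)$erpd, 5)
  withr::with_seed(7, y <- runif(length(t_s), 3, 6))
  e1 <- compute_erpd(t_s, y, mean(y[t_s < 0]))
  e2 <- compute_erpd(t_s, y * 137, mean(y[t_s < 0]) * 137)
  expect_equal(e1$erpd, e2$erpd, tolerance = 1e-10)
  expect_error(compute_erpd(t_s, y, 0), "positive")
})

test_that("moving average smooths with truncated symmetric edges", {
  expect_equal(smooth_ma(rep(2, 20)), rep(2, 20))
  imp <- c(rep(0, 10), 5, rep(0, 10))
  sm <- smooth_ma(imp)
  expect_equal(sm[9:13], rep(1, 5))
  expect_equal(sum(sm > 0), 5)
  ramp <- 1:30 * 0.5
  expect_equal(smooth_ma(ramp)[3:28], ramp[3:28])
  expect_error(smooth_ma(1:10, 4), "odd")
  expect_equal(smooth_ma(c(1, 5, 2), 3)[1], 1) # edge truncates to width 1
})

test_that("the full chain matches the generator and is scale-invariant", {
  cfg <- synth_config(
    n_participants = 2, trials_per_block = 2, familiarization_per_block = 0,
    speech_types = c("plain", "TTS"), snrs = -1,
    noise_sd = 0, blink_rate = 0, duration_jitter = 0, seed = 21
  )
  sim <- simulate_experiment(cfg)
  pp <- preprocess_trials(sim$traces)
  expect_true(all(pp$usable))
  el <- erpd_long(pp)
  # oracle: the smoothed injected curve per participant x speech type
  basis <- orthogonal_poly_basis(sim$truth$analysis_grid)
  B <- cbind(1, as.matrix(basis[, c("t1", "t2", "t3")]))
  for (i in seq_len(nrow(pp))) {
    row <- pp[i, ]
    beta <- as.numeric(
      sim$truth$fixed_effects[
        sim$truth$fixed_effects$speech_type == row$speech_type,
        c("b0", "b1", "b2", "b3")
      ]
    ) + as.numeric(
      sim$truth$random_effects[
        sim$truth$random_effects$participant_id == row$participant_id,
        c("b0", "b1", "b2", "b3")
      ]
    )
    injected <- smooth_ma(as.numeric(B %*% beta))
    expect_equal(row$erpd[[1]]$erpd, injected, tolerance = 1e-9)
  }
  # positive rescaling of the raw recording leaves every ERPD unchanged
  for (c_scale in c(0.01, 137)) {
    scaled <- sim$traces
    scaled$pupil <- scaled$pupil * c_scale
    attr(scaled, "unit") <- attr(sim$traces, "unit")
    attr(scaled, "rate_hz") <- attr(sim$traces, "rate_hz")
    el2 <- erpd_long(preprocess_trials(scaled))
    expect_equal(el2$erpd, el$erpd, tolerance = 1e-10)
  }
})

test_that("sentinel-only trials and rerun fixpoints behave", {
  t_s <- seq(-100, 150) / 50
  res <- preprocess_trial(t_s, rep(NA_real_, length(t_s)), "area", 50)
  expect_false(res$qc$usable)
  expect_match(res$qc$reason, "detect_artifacts: no valid samples")

  # idempotence: already-clean 50 Hz diameter data, smoothing disabled
  params <- preprocess_params(smooth_points = 1L)
  clean <- 5 + 0.3 * sin(t_s)
  p1 <- preprocess_trial(t_s, clean, "diameter", 50, params)
  rebuilt <- clean
  rebuilt[t_s >= 0 & t_s <= 4.5] <- NA
  # feed the ERPD back through with a unit baseline trace: ERPD of an
  # ERPD-shaped trace around its own baseline of the pre-onset mean
  base1 <- mean(clean[t_s >= -1 & t_s < 0])
  trace2 <- base1 * (1 + p1$erpd$erpd / 100)
  full2 <- c(clean[t_s < 0], trace2)
  p2 <- preprocess_trial(t_s[seq_along(full2)], full2, "diameter", 50, params)
  expect_equal(p2$erpd$erpd, p1$erpd$erpd, tolerance = 1e-10)
})

test_that("trials flagged unusable by the reader propagate with reasons", {
  tb <- tibble::tibble(
    participant_id = "P01", block_id = "B01", trial_index = 1L,
    speech_type = "plain", snr_db = -1,
    t_s = seq(-25, 225) / 50, pupil = 900
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_pupil_traces(tb, f, unit = "area", rate_hz = 50)
  back <- read_pupil_traces(f)
  pp <- preprocess_trials(back)
  expect_false(pp$usable)
  expect_match(pp$reason, "insufficient baseline")
})
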
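# Independent reference implementations used as oracles. These are written
# as plain loops from the documented rules, deliberately sharing no code
# with the package.

# Straight-line reference for the full calibration chain.
reference_preprocess <- function(t_s, pupil, unit, rate_hz,
                                 target_rate = 50, sd_threshold = 2,
                                 pre = 5, post = 8,
                                 baseline_window = c(-1, 0),
                                 analysis_window = c(0, 4.5),
                                 smooth_points = 5) {
  # 1. block-mean downsampling
  f <- as.integer(round(rate_hz / target_rate))
  if (f > 1) {
    nb <- length(pupil) %/% f
    x <- numeric(nb); tt <- numeric(nb)
    for (b in seq_len(nb)) {
      blk <- pupil[((b - 1) * f + 1):(b * f)]
      ok <- !is.na(blk)
      x[b] <- if (sum(ok) < f / 2) NA_real_ else mean(blk[ok])
      tt[b] <- t_s[(b - 1) * f + 1]
    }
  } else {
    x <- pupil; tt <- t_s
  }
  # 2. area -> diameter
  if (unit == "area") x <- 2 * sqrt(x / pi)
  # 3. 2-SD downward artifact detection, single pass
  ok <- !is.na(x)
  if (sum(ok) < 4) return(NULL)
  mu <- mean(x[ok]); sg <- sd(x[ok])
  miss <- !ok | (ok & x < mu - sd_threshold * sg)
  # 4. run-wise least-squares interpolation
  y <- ifelse(miss, NA_real_, x)
  if (all(miss)) return(NULL)
  i <- 1
  n <- length(y)
  while (i <= n) {
    if (!miss[i]) { i <- i + 1; next }
    j <- i
    while (j < n && miss[j + 1]) j <- j + 1
    valid <- which(!miss)
    left <- valid[valid < i]
    right <- valid[valid > j]
    if (!length(left) || !length(right)) {
      nearest <- if (length(left)) max(left) else min(right)
      y[i:j] <- x[nearest]
    } else {
      sup <- valid[valid >= i - pre & valid <= j + post]
      if (length(sup) < 2) sup <- c(max(left), min(right))
      cf <- qr.solve(cbind(1, sup), x[sup])
      y[i:j] <- cf[1] + cf[2] * (i:j)
    }
    i <- j + 1
  }
  # 5. baseline over [-1, 0)
  inb <- tt >= baseline_window[1] & tt < baseline_window[2]
  if (all(miss[inb])) return(NULL)
  bl <- mean(y[inb])
  if (!is.finite(bl) || bl <= 0) return(NULL)
  # 6. percent dilation on the analysis window
  ina <- tt >= analysis_window[1] - 1e-12 & tt <= analysis_window[2] + 1e-12
  e <- (y[ina] - bl) / bl * 100
  # 7. truncated-window moving average
  h <- (smooth_points - 1) / 2
  m <- length(e)
  out <- numeric(m)
  for (k in seq_len(m)) {
    w <- min(h, k - 1, m - k)
    out[k] <- mean(e[(k - w):(k + w)])
  }
  list(t_s = tt[ina], erpd = out)
}

# Brute-force design-matrix least-squares fill for one missing run.
brute_force_fill <- function(x, miss) {
  y <- ifelse(miss, NA_real_, x)
  valid <- which(!miss)
  runs <- rle(miss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (r in which(runs$values)) {
    a <- starts[r]; b <- ends[r]
    left <- valid[valid < a]; right <- valid[valid > b]
    if (!length(left) || !length(right)) {
      nearest <- if (length(left)) max(left) else min(right)
      y[a:b] <- x[nearest]
      next
    }
    sup <- valid[valid >= a - 5 & valid <= b + 8]
    if (length(sup) < 2) sup <- c(max(left), min(right))
    X <- cbind(1, sup)
    beta <- solve(t(X) %*% X, t(X) %*% x[sup])
    y[a:b] <- beta[1] + beta[2] * (a:b)
  }
  y
}

# Classical Gram-Schmidt orthonormalization of raw powers 1, t, ..., t^deg.
gram_schmidt_basis <- function(times, degree = 3) {
  tu <- sort(unique(times))
  M <- outer(tu, 0:degree, `^`)
  Q <- matrix(0, nrow(M), degree + 1)
  for (k in seq_len(degree + 1)) {
    v <- M[, k]
    if (k > 1) {
      for (j in seq_len(k - 1)) v <- v - sum(Q[, j] * M[, k]) * Q[, j]
    }
    Q[, k] <- v / sqrt(sum(v^2))
  }
  Q
}

# ANCOVA oracle for the repeated-measures correlation: explicit design
# matrices, residual sums of squares by least squares.
rmcorr_oracle <- function(pid, x, y) {
  P <- model.matrix(~ factor(pid))
  X_full <- cbind(P, x)
  X_red <- P
  rss <- function(X, y) {
    b <- qr.solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% b)^2)
  }
  rss_full <- rss(X_full, y)
  rss_red <- rss(X_red, y)
  ss_x <- rss_red - rss_full
  slope <- qr.solve(t(X_full) %*% X_full, t(X_full) %*% y)[ncol(X_full)]
  r <- sign(slope) * sqrt(ss_x / (ss_x + rss_full))
  df <- length(y) - nlevels(factor(pid)) - 1
  list(r = as.numeric(r), df = df)
}

# Random raw trace for oracle comparisons: positive smooth signal + noise,
# with random missing runs, at `rate_hz`, spanning [-2, 5] s.
random_raw_trial <- function(rate_hz = 100, unit = "area") {
  t_s <- seq(-2 * rate_hz, 5 * rate_hz) / rate_hz
  n <- length(t_s)
  level <- runif(1, 500, 2000)
  signal <- level * (1 + 0.05 * sin(seq(0, 3 * pi, length.out = n)) +
                       cumsum(rnorm(n, 0, 0.002)))
  x <- abs(signal + rnorm(n, 0, level * 0.01))
  n_runs <- rpois(1, 2)
  for (r in seq_len(n_runs)) {
    a <- sample.int(n, 1)
    len <- sample.int(30, 1)
    x[a:min(n, a + len - 1)] <- NA_real_
  }
  list(t_s = t_s, pupil = x, unit = unit, rate_hz = rate_hz)
}

# Direct cell-curve simulator for growth-curve recovery studies: one mean
# curve per participant x speech type on a thinned analysis grid. Betas are
# defined on the orthonormal basis of the thinned grid the model is fitted
# on; AR(1) trial noise runs at the acquisition rate (50 Hz) and is
# subsampled, so neighboring fitted samples are nearly decorrelated.
simulate_gca_cells <- function(n_participants, betas, re_cov,
                               noise_sd = 1.5, ar_coef = 0.6, n_trials = 15,
                               thin = 5) {
  grid50 <- seq(0, 225) / 50
  keep <- seq(1, length(grid50), by = thin)
  grid_fit <- grid50[keep]
  basis <- orthogonal_poly_basis(grid_fit)
  B <- cbind(1, as.matrix(basis[, c("t1", "t2", "t3")]))
  types <- rownames(betas)
  out <- list()
  for (i in seq_len(n_participants)) {
    b_i <- MASS::mvrnorm(1, rep(0, 4), re_cov)
    for (ty in types) {
      mu <- as.numeric(B %*% (betas[ty, ] + b_i))
      e <- numeric(length(grid50))
      e[1] <- rnorm(1, 0, 1)
      for (k in 2:length(e)) {
        e[k] <- ar_coef * e[k - 1] + rnorm(1, 0, sqrt(1 - ar_coef^2))
      }
      noise <- e[keep] * noise_sd / sqrt(n_trials)
      out[[length(out) + 1]] <- tibble::tibble(
        participant_id = sprintf("P%02d", i),
        speech_type = ty,
        t_s = grid_fit,
        erpd = mu + noise
      )
    }
  }
  dplyr::bind_rows(out)
}
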
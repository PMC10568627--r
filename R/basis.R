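#' Orthogonal polynomial basis on a time grid
#'
#' Builds the cubic (by default) orthogonal polynomial basis used by growth
#' curve analysis, evaluated on the realized sampling grid. Column `t0` is the
#' intercept (constant 1); `t1`, `t2`, `t3` are orthonormal, zero-sum, and
#' mutually orthogonal, obtained by QR orthonormalization of the raw powers
#' \eqn{1, t, t^2, t^3}. Signs are fixed so each column correlates positively
#' with its raw power, making the coefficients interpretable: the intercept is
#' the mean curve height, the linear term the overall rate of change, the
#' quadratic the peak shape, and the cubic the falling slope.
#'
#' @param times Numeric vector of grid times (seconds). Must contain at least
#'   `degree + 2` distinct values.
#' @param degree Polynomial degree (default 3, the cubic basis).
#' @return A tibble with columns `time`, `t0`, `t1`, ... `t<degree>`.
#' @examples
#' b <- orthogonal_poly_basis(seq(0, 4.5, by = 0.02))
#' crossprod(as.matrix(b[, c("t1", "t2", "t3")])) # ~ identity
#' @export
orthogonal_poly_basis <- function(times, degree = 3) {
  if (!is.numeric(times) || anyNA(times)) {
    stop_pupilgca("`times` must be a numeric vector without missing values")
  }
  tu <- sort(unique(times))
  if (length(tu) < degree + 2) {
    stop_pupilgca(sprintf(
      "need at least %d distinct time points for a degree-%d basis",
      degree + 2, degree
    ))
  }
  raw <- outer(tu, 0:degree, `^`)
  qd <- qr(raw)
  if (qd$rank < degree + 1) {
    stop_pupilgca("time grid does not support the requested polynomial degree")
  }
  q <- qr.Q(qd)
  # sign convention: positive correlation with the raw power of same order
  for (k in seq_len(degree + 1)) {
    ctr <- raw[, k] - mean(raw[, k])
    s <- if (k == 1) sum(q[, k]) else sum(q[, k] * ctr)
    if (s < 0) q[, k] <- -q[, k]
  }
  out <- tibble(time = tu)
  out$t0 <- 1
  for (k in seq_len(degree)) {
    out[[paste0("t", k)]] <- q[, k + 1]
  }
  out
}

# Join basis columns onto a long table keyed by time column `time_col`.
add_basis_columns <- function(data, time_col = "t_s", degree = 3) {
  basis <- orthogonal_poly_basis(data[[time_col]], degree = degree)
  names(basis)[1] <- time_col
  dplyr::left_join(data, basis[, -2], by = time_col) # drop t0 (intercept)
}
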
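#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n row_number across all_of distinct pull rename
#' @importFrom stats as.formula anova ave coef lm logLik pchisq pf pnorm pt
#'   qnorm rbinom rnorm rpois runif rexp sd setNames model.matrix
#'   complete.cases
#' @importFrom utils head tail
NULL

# Stop with a classed error so callers can condition on pupilgca failures.
stop_pupilgca <- function(msg, class = "pupilgca_error") {
  rlang::abort(msg, class = class)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

# Symmetric PSD check with a small tolerance on the smallest eigenvalue.
check_psd <- function(m, name = "re_cov") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_pupilgca(sprintf("`%s` must be a square matrix", name))
  }
  if (max(abs(m - t(m))) > 1e-8) {
    stop_pupilgca(sprintf("`%s` must be symmetric", name))
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop_pupilgca(sprintf("`%s` must be positive semi-definite", name))
  }
  invisible(TRUE)
}

# Runs of TRUE in a logical vector -> tibble(start, end, length).
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
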
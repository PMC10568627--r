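#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a growth-curve fit
#'
#' @param x A `gca_fit`.
#' @param ... Unused.
#' @return The coefficient table: `term`, `estimate`, `std.error`,
#'   `statistic` (z), `p.value`.
#' @export
tidy.gca_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.gca_fit
#' @export
glance.gca_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik, df = x$df, reml = x$reml,
    converged = x$converged, singular = x$singular,
    n_obs = x$n_obs, n_participants = x$n_participants
  )
}

#' Tidy a behavioral mixed model
#'
#' @param x A `behavioral_lmm`.
#' @param ... Unused.
#' @return Coefficient table (`tidy`) or interaction-test summary (`glance`).
#' @export
tidy.behavioral_lmm <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.behavioral_lmm
#' @export
glance.behavioral_lmm <- function(x, ...) {
  dplyr::bind_cols(
    tibble(response = x$response, n_obs = x$n_obs,
           n_participants = x$n_participants),
    x$interaction
  )
}
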
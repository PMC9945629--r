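# Early-phase exponential decline model. After irradiation shuts marrow
# output off, circulating counts fall as C_t = C0 * exp(-k t), with t the
# day after the Day-1 peak; equivalent to pure clearance with no input.

#' Early-phase exponential decline parameters
#'
#' @param C0 Concentration at the reference day (Day 1 peak), cells/uL.
#' @param k Decline-rate parameter, per day (>= 0).
#' @return An `exponential_phase_params` object.
#' @export
exponential_phase_params <- function(C0, k) {
  check_positive(C0, "C0")
  check_number(k, "k", lower = 0)
  structure(list(C0 = C0, k = k), class = "exponential_phase_params")
}

#' Evaluate the early-phase exponential decline
#'
#' Closed-form evaluation of \eqn{C(t) = C_0 e^{-kt}} on a grid of days
#' after the reference day; no solver involved.
#'
#' @param params An `exponential_phase_params` object.
#' @param t_grid Days after the reference day (>= 0).
#' @return A tibble with `time_days` and `value`.
#' @export
#' @examples
#' simulate_exponential_phase(exponential_phase_params(100, log(2)), 0:3)
simulate_exponential_phase <- function(params, t_grid) {
  stopifnot(inherits(params, "exponential_phase_params"))
  if (any(!is.finite(t_grid)) || any(t_grid < 0)) {
    abort("`t_grid` must be non-negative (days after the reference day).")
  }
  tibble(time_days = t_grid, value = params$C0 * exp(-params$k * t_grid))
}
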
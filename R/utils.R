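# internal input checks and small shared helpers

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (is.finite(x) && (x < lower || x > upper)) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be positive and finite.", name))
  }
  invisible(x)
}

check_increasing <- function(t, name = "t_grid") {
  if (!is.numeric(t) || length(t) < 2L || any(!is.finite(t)) || any(diff(t) <= 0)) {
    abort(sprintf("`%s` must be a strictly increasing numeric grid.", name))
  }
  invisible(t)
}

#' Convert between the time units used by the models
#'
#' The recirculation model works in minutes (lymphocyte trafficking happens
#' on that scale); the myelokinetic models work in days. These helpers
#' convert at the boundary.
#'
#' @param x Numeric vector of times.
#' @return Numeric vector in the target unit.
#' @export
#' @examples
#' minutes_to_days(1440)
minutes_to_days <- function(x) x / 1440

#' @rdname minutes_to_days
#' @export
days_to_minutes <- function(x) x * 1440

# deterministic multi-start design on [0,1]^p: rows are starts, columns
# parameters; a shifted low-discrepancy lattice so starts spread without RNG
start_lattice <- function(n_starts, n_par) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  i <- seq_len(n_starts)
  sapply(seq_len(n_par), function(j) {
    ((i - 0.5) * sqrt(primes[(j - 1L) %% length(primes) + 1L])) %% 1
  })
}
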
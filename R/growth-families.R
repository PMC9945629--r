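# Registry of closed-form growth/recovery function families used for
# phenomenological fitting of post-irradiation blood-count time series.

growth_registry <- new.env(parent = emptyenv())

#' Register a growth-function family
#'
#' The built-in registry holds five canonical families (`linear`,
#' `exponential_decay`, `exponential_rise_to_plateau`, `logistic`,
#' `gompertz`); additional families can be registered, e.g. polynomials for
#' overfitting experiments.
#'
#' @param name Family name.
#' @param params Character vector of parameter names (length >= 2).
#' @param fn Function `(t, p)` evaluating the curve at times `t` for a
#'   named parameter vector/list `p`; vectorized over `t`.
#' @param start Function `(t, y)` returning a named list of data-driven
#'   starting values.
#' @param lower,upper Named numeric bounds (recycled -Inf/Inf if omitted).
#' @param design Optional function `(t)` returning a design matrix when the
#'   family is linear in its parameters; such families are fitted exactly by
#'   least squares.
#' @return The registered spec, invisibly.
#' @export
register_growth_family <- function(name, params, fn, start,
                                   lower = NULL, upper = NULL, design = NULL) {
  if (length(params) < 2L) abort("Growth families must have >= 2 parameters.")
  spec <- structure(
    list(family = name, params = params, fn = fn, start = start,
         lower = lower %||% setNames(rep(-Inf, length(params)), params),
         upper = upper %||% setNames(rep(Inf, length(params)), params),
         design = design, n_params = length(params)),
    class = "growth_family")
  order <- get0(".order", envir = growth_registry, ifnotfound = character(0))
  if (!name %in% order) {
    assign(".order", c(order, name), envir = growth_registry)
  }
  assign(name, spec, envir = growth_registry)
  invisible(spec)
}

#' List or fetch registered growth families
#'
#' @param family Family name; if missing, the names of all registered
#'   families are returned (in registration order, used for deterministic
#'   tie-breaking).
#' @return A `growth_family` spec, or a character vector of names.
#' @export
growth_family <- function(family) {
  if (missing(family)) {
    return(get0(".order", envir = growth_registry, ifnotfound = character(0)))
  }
  if (inherits(family, "growth_family")) return(family)
  if (!exists(family, envir = growth_registry, inherits = FALSE)) {
    abort(sprintf("Unknown growth family '%s'; registered: %s.",
                  family, paste(growth_family(), collapse = ", ")))
  }
  get(family, envir = growth_registry, inherits = FALSE)
}

#' Evaluate a growth family at given times
#'
#' @param spec A `growth_family` spec or family name.
#' @param params Named vector/list of parameter values.
#' @param t Times (vectorized).
#' @return Numeric vector of curve values.
#' @export
#' @examples
#' evaluate_growth("logistic", c(A = 100, r = 0.5, tm = 10), t = 10)  # 50
evaluate_growth <- function(spec, params, t) {
  spec <- growth_family(spec)
  p <- as.list(params)
  missing <- setdiff(spec$params, names(p))
  if (length(missing)) {
    abort(sprintf("Missing parameter(s) for family '%s': %s.",
                  spec$family, paste(missing, collapse = ", ")))
  }
  spec$fn(t, p)
}

# built-in families -------------------------------------------------------
local({
  register_growth_family(
    "linear", c("a", "b"),
    fn = function(t, p) p$a + p$b * t,
    start = function(t, y) {
      f <- coef(lm(y ~ t)); list(a = unname(f[1]), b = unname(f[2]))
    },
    design = function(t) cbind(a = 1, b = t))

  register_growth_family(
    "exponential_decay", c("A", "k"),
    fn = function(t, p) p$A * exp(-p$k * t),
    start = function(t, y) {
      yp <- pmax(y, max(y, 1e-9) * 1e-6)
      f <- coef(lm(log(yp) ~ t))
      list(A = exp(unname(f[1])), k = max(-unname(f[2]), 1e-6))
    },
    lower = c(A = 1e-12, k = 0), upper = c(A = Inf, k = Inf))

  register_growth_family(
    "exponential_rise_to_plateau", c("A", "y0", "k"),
    fn = function(t, p) p$A - (p$A - p$y0) * exp(-p$k * t),
    start = function(t, y) {
      list(A = max(y) * 1.05, y0 = y[which.min(t)],
           k = 2 / max(diff(range(t)), 1e-9))
    },
    lower = c(A = 1e-12, y0 = -Inf, k = 1e-9))

  register_growth_family(
    "logistic", c("A", "r", "tm"),
    fn = function(t, p) p$A / (1 + exp(-p$r * (t - p$tm))),
    start = function(t, y) {
      A <- max(y) * 1.05
      half <- A / 2
      tm <- t[which.min(abs(y - half))]  # half-max crossing heuristic
      list(A = A, r = 4 / max(diff(range(t)) / 4, 1e-9) / 4, tm = tm)
    },
    lower = c(A = 1e-12, r = 1e-9, tm = -Inf))

  register_growth_family(
    "gompertz", c("A", "b", "c"),
    fn = function(t, p) p$A * exp(-p$b * exp(-p$c * t)),
    start = function(t, y) {
      A <- max(y) * 1.05
      y1 <- max(min(y[which.min(t)], A * 0.99), A * 1e-6)
      list(A = A, b = -log(y1 / A), c = 2 / max(diff(range(t)), 1e-9))
    },
    lower = c(A = 1e-12, b = 1e-9, c = 1e-9))
})
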
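# Two-stage individual-based estimation: fit every subject separately,
# then summarise the parameter distribution across subjects; a pooled fit
# (all observations together, one parameter set) is kept for contrast with
# the conventional population-mean approach.

#' Two-stage individual-based parameter estimation
#'
#' Fits the chosen model to each subject separately (stage 1), then
#' summarises the per-subject estimates (mean, SD, CV per parameter) over
#' converged subjects (stage 2). A pooled fit of all observations with a
#' single parameter set is included for comparison: with heterogeneous
#' subjects the pooled estimate can sit away from the individual-based
#' population mean. Subjects whose fit fails or does not converge are
#' excluded from the summary and counted.
#'
#' @param data Data frame with `subject_id`, time and count columns;
#'   needs >= 2 subjects.
#' @param model Model kind passed to [estimate_parameters()], or
#'   `"growth"` to fit a growth family via [fit_growth()].
#' @param free Named list of bounds (mechanistic models).
#' @param fixed Named list of fixed parameters (mechanistic models).
#' @param family Growth family (when `model = "growth"`).
#' @param time,response Column names.
#' @param ... Further arguments to the underlying fitter.
#' @return An `individual_estimates` object: `individual` (per-subject
#'   tibble of estimates with convergence flags), `summary` (per-parameter
#'   mean, sd, cv), `pooled` (`leuco_fit` on all data), `n_failed`.
#' @export
fit_individuals <- function(data, model, free = NULL, fixed = list(),
                            family = NULL, time = "time", response = "count",
                            ...) {
  data <- as_tibble(data)
  if (!"subject_id" %in% names(data)) abort("`data` must contain `subject_id`.")
  subjects <- unique(data$subject_id)
  if (length(subjects) < 2L) abort("Need >= 2 subjects; got 1.")

  fit_one <- function(d) {
    if (identical(model, "growth")) {
      fit_growth(d, family, time = time, response = response, ...)
    } else {
      estimate_parameters(d, model, free = free, fixed = fixed,
                          time = time, response = response, ...)
    }
  }

  ind_rows <- list(); n_failed <- 0L
  for (s in subjects) {
    d <- data[data$subject_id == s, ]
    fit <- tryCatch(fit_one(d), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      if (!is.null(fit)) {
        ind_rows[[length(ind_rows) + 1L]] <-
          tibble(subject_id = s, !!!fit$estimates, converged = FALSE)
      }
      next
    }
    ind_rows[[length(ind_rows) + 1L]] <-
      tibble(subject_id = s, !!!fit$estimates, converged = TRUE)
  }
  if (length(ind_rows) == 0L) abort("Every subject failed to fit.")
  individual <- bind_rows(ind_rows)
  ok <- individual[individual$converged, ]
  par_cols <- setdiff(names(individual), c("subject_id", "converged"))
  summary_tab <- purrr::map_dfr(par_cols, function(pc) {
    v <- ok[[pc]]
    tibble(parameter = pc, mean = mean(v), sd = sd(v),
           cv = sd(v) / abs(mean(v)), n = length(v))
  })
  pooled <- tryCatch(fit_one(select(data, -"subject_id")),
                     error = function(e) NULL)

  structure(list(individual = individual, summary = summary_tab,
                 pooled = pooled, n_failed = n_failed,
                 n_subjects = length(subjects)),
            class = "individual_estimates")
}

#' @export
print.individual_estimates <- function(x, ...) {
  cat(sprintf("<individual_estimates> %d subjects (%d failed/non-converged)\n",
              x$n_subjects, x$n_failed))
  print(x$summary)
  invisible(x)
}

#' @describeIn fit_individuals Per-subject estimates as a tibble.
#' @param x An `individual_estimates` object.
#' @export
tidy.individual_estimates <- function(x, ...) x$individual

#' @describeIn fit_individuals Population summary (mean, sd, cv per
#'   parameter).
#' @export
glance.individual_estimates <- function(x, ...) x$summary
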
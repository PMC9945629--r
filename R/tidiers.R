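# broom-style accessors and plots for fitted objects

#' Tidy a fitted model
#'
#' @param x A `leuco_fit`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.leuco_fit <- function(x, ...) {
  tibble(term = names(x$estimates),
         estimate = unname(unlist(x$estimates)))
}

#' One-row fit summary
#'
#' @param x A `leuco_fit`.
#' @param ... Unused.
#' @return Tibble with n_obs, n_params, ssr, mse, aic, bic, converged.
#' @export
glance.leuco_fit <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_params = x$n_params, ssr = x$ssr, mse = x$mse,
         aic = x$aic, bic = x$bic, loss = x$loss, converged = x$converged,
         at_bounds = x$at_bounds)
}

#' @export
autoplot.leuco_fit <- function(object, n_fine = 200, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time", y = "Count (cells/µL)",
                  title = sprintf("%s fit%s", object$model,
                                  if (!is.na(object$family))
                                    paste0(" (", object$family, ")") else "")) +
    ggplot2::theme_minimal()
  if (!is.null(object$predict_fn)) {
    tf <- seq(min(d$t), max(d$t), length.out = n_fine)
    curve <- tibble(t = tf, y = object$predict_fn(tf))
    p <- p + ggplot2::geom_line(data = curve, colour = "steelblue")
  }
  p
}

#' @export
tidy.screen_result <- function(x, ...) x$ranking

#' @export
glance.screen_result <- function(x, ...) {
  tibble(best = x$best, criterion = x$criterion,
         n_levels = nrow(x$per_level))
}

#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @export
glance.cv_result <- function(x, ...) {
  tibble(scheme = x$scheme, k = x$k, cv_rmse = x$cv_rmse, seed = x$seed)
}
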
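# Least-squares fitting of growth families, information-criterion model
# selection, and recovery/homeostasis classification.

# Gaussian-residual information criteria from SSR, n, p
ic_from_ssr <- function(ssr, n, p) {
  ssr <- max(ssr, 1e-300)
  list(aic = n * log(ssr / n) + 2 * p,
       bic = n * log(ssr / n) + p * log(n),
       aicc = if (n - p - 1 > 0) n * log(ssr / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
              else NA_real_)
}

new_leuco_fit <- function(model, family = NA_character_, estimates, fixed = list(),
                          data, fitted, residuals, loss, converged,
                          at_bounds = FALSE, predict_fn = NULL) {
  n <- length(residuals)
  p <- length(estimates)
  ssr <- sum(residuals^2)
  ic <- ic_from_ssr(ssr, n, p)
  structure(
    list(model = model, family = family, estimates = estimates, fixed = fixed,
         data = data, fitted = fitted, residuals = residuals, loss = loss,
         ssr = ssr, n_obs = n, n_params = p, mse = ssr / n,
         aic = ic$aic, bic = ic$bic, aicc = ic$aicc,
         converged = converged, at_bounds = at_bounds, predict_fn = predict_fn),
    class = "leuco_fit")
}

#' @export
print.leuco_fit <- function(x, ...) {
  cat(sprintf("<leuco_fit> model: %s%s | n = %d, p = %d%s\n",
              x$model, if (!is.na(x$family)) paste0(" (", x$family, ")") else "",
              x$n_obs, x$n_params,
              if (!x$converged) " | NOT CONVERGED" else ""))
  cat(sprintf("  SSR = %.6g, MSE = %.6g, AIC = %.4f, BIC = %.4f\n",
              x$ssr, x$mse, x$aic, x$bic))
  cat("  estimates:\n")
  print(unlist(x$estimates))
  invisible(x)
}

#' Fit a growth family to a recovery time series
#'
#' Least-squares fit of a closed-form growth function to `(t, y)` pairs,
#' minimising the sum of squared residuals (optionally on the log scale for
#' positive, heteroscedastic counts). Families linear in their parameters
#' are solved exactly; nonlinear families use Levenberg-Marquardt
#' (`minpack.lm::nlsLM`) from multiple deterministic, data-driven starts.
#' Non-convergence of every start is reported via the `converged` flag,
#' never silently.
#'
#' @param data Data frame with the time and response columns.
#' @param family Growth family name or spec (see [growth_family()]).
#' @param time,response Column names (default `"time"`, `"count"`).
#' @param weighting `"none"` (fit on the natural scale) or `"log_scale"`
#'   (fit on log counts; requires positive responses).
#' @param n_starts Number of deterministic multi-starts (default 10).
#' @return A `leuco_fit` object (estimates, SSR, MSE, AIC/BIC, residuals,
#'   convergence flag); supports [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' d <- tibble::tibble(time = 0:20,
#'                     count = 100 * exp(-0.3 * (0:20)))
#' fit_growth(d, "exponential_decay")
fit_growth <- function(data, family, time = "time", response = "count",
                       weighting = c("none", "log_scale"), n_starts = 10) {
  weighting <- match.arg(weighting)
  spec <- growth_family(family)
  data <- as_tibble(data)
  if (!all(c(time, response) %in% names(data))) {
    abort(sprintf("`data` must contain columns '%s' and '%s'.", time, response))
  }
  t <- data[[time]]; y <- data[[response]]
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(y) <= spec$n_params) {
    abort(sprintf("Need more observations (%d) than parameters (%d).",
                  length(y), spec$n_params))
  }
  if (weighting == "log_scale" && any(y <= 0)) {
    abort("log_scale weighting requires strictly positive responses.")
  }
  trans <- if (weighting == "log_scale") log else identity
  obj_resid <- function(p) {
    pred <- spec$fn(t, as.list(p))
    if (weighting == "log_scale") {
      pred <- pmax(pred, 1e-12)
    }
    trans(y) - trans(pred)
  }

  if (!is.null(spec$design) && weighting == "none") {
    X <- spec$design(t)
    fit <- lm.fit(X, y)
    est <- as.list(setNames(fit$coefficients, spec$params))
    res <- y - drop(X %*% fit$coefficients)
    return(new_leuco_fit("growth", spec$family, est, data = tibble(t = t, y = y),
                         fitted = y - res, residuals = res, loss = weighting,
                         converged = TRUE,
                         predict_fn = function(tt) spec$fn(tt, est)))
  }

  base_start <- tryCatch(spec$start(t, y), error = function(e) NULL)
  if (is.null(base_start)) {
    base_start <- as.list(setNames(rep(1, spec$n_params), spec$params))
  }
  lat <- start_lattice(n_starts, spec$n_params)
  starts <- lapply(seq_len(n_starts), function(i) {
    s <- unlist(base_start)[spec$params]
    # multiplicative jitter in [1/3, 3] on magnitude, sign kept; first start exact
    if (i > 1L) {
      fac <- 3^(2 * lat[i, ] - 1)
      s <- s * fac
      s[!is.finite(s) | s == 0] <- fac[!is.finite(s) | s == 0]
    }
    pmin(pmax(s, spec$lower[spec$params] + 1e-12), spec$upper[spec$params])
  })

  best <- NULL
  for (s in starts) {
    cand <- tryCatch({
      yy <- trans(y)
      env <- list2env(list(t = t, yy = yy, spec = spec, trans = trans))
      # build a formula exposing each parameter by name to nlsLM
      rhs <- sprintf("trans(pmax(spec$fn(t, list(%s)), 1e-12))",
                     paste(sprintf("%s = %s", spec$params, spec$params),
                           collapse = ", "))
      form <- stats::as.formula(paste("yy ~", rhs), env = env)
      fit <- minpack.lm::nlsLM(
        form, start = as.list(s),
        lower = unname(spec$lower[spec$params]),
        upper = unname(spec$upper[spec$params]),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      est <- as.list(coef(fit))
      list(est = est, ssr = sum(obj_resid(est)^2), ok = fit$convInfo$isConv)
    }, error = function(e) NULL)
    if (!is.null(cand) && (is.null(best) || cand$ssr < best$ssr)) best <- cand
  }

  if (is.null(best)) {
    est <- base_start
    res <- obj_resid(est)
    return(new_leuco_fit("growth", spec$family, est, data = tibble(t = t, y = y),
                         fitted = trans(y) - res, residuals = res,
                         loss = weighting, converged = FALSE,
                         predict_fn = function(tt) spec$fn(tt, est)))
  }
  est <- best$est
  res <- obj_resid(est)
  at_bounds <- any(abs(unlist(est) - spec$lower[spec$params]) < 1e-10 &
                     is.finite(spec$lower[spec$params])) ||
    any(abs(unlist(est) - spec$upper[spec$params]) < 1e-10 &
          is.finite(spec$upper[spec$params]))
  new_leuco_fit("growth", spec$family, est, data = tibble(t = t, y = y),
                fitted = trans(y) - res, residuals = res, loss = weighting,
                converged = isTRUE(best$ok), at_bounds = at_bounds,
                predict_fn = function(tt) spec$fn(tt, est))
}

#' Rank fitted models by a selection criterion
#'
#' Ranks fits of different function families (or model structures) to the
#' same series by mean squared error, AIC, or BIC. Ties (criterion values
#' within 1e-9) are broken by fewer parameters, then by registration/family
#' order of the supplied list — both deterministic.
#'
#' @param fits List of `leuco_fit` objects on the identical series.
#' @param criterion `"aic"` (default), `"bic"` or `"mse"`.
#' @return A `model_ranking` tibble (family, n_params, ssr, mse, aic, bic,
#'   delta, rank) with the best model first; the winning fit is in
#'   `attr(, "best")`.
#' @export
select_model <- function(fits, criterion = c("aic", "bic", "mse")) {
  criterion <- match.arg(criterion)
  if (inherits(fits, "leuco_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "leuco_fit")))
  n_obs <- vapply(fits, `[[`, 0, "n_obs")
  if (length(unique(n_obs)) != 1L) {
    abort("All fits must be on the identical series (n_obs mismatch).")
  }
  tab <- tibble(
    family = vapply(fits, function(f) if (is.na(f$family)) f$model else f$family, ""),
    n_params = vapply(fits, `[[`, 0, "n_params"),
    ssr = vapply(fits, `[[`, 0, "ssr"),
    mse = vapply(fits, `[[`, 0, "mse"),
    aic = vapply(fits, `[[`, 0, "aic"),
    bic = vapply(fits, `[[`, 0, "bic"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    input_order = seq_along(fits))
  crit <- tab[[criterion]]
  # tie-stable ordering: criterion, then parameter count, then input order
  ord <- order(round(crit / 1e-9) * 1e-9, tab$n_params, tab$input_order)
  tab <- tab[ord, ]
  tab$delta <- tab[[criterion]] - tab[[criterion]][1]
  tab$rank <- seq_len(nrow(tab))
  structure(tab, class = c("model_ranking", class(tab)),
            criterion = criterion, best = fits[[tab$input_order[1]]])
}

#' Classify the recovery/homeostasis outcome of a fitted series
#'
#' Decides (1) whether the fitted curve reached a stable point (plateau)
#' within the observation window — the relative change of the fitted curve
#' over the final 10% of the window is below `plateau_slope_tol` — and
#' (2) whether that plateau equals the pre-treatment baseline within
#' `baseline_tol` (homeostasis restored) or settles elsewhere (altered).
#' If no plateau is reached the baseline comparison is `indeterminate`:
#' either regulation is disrupted or the observation period was too short.
#'
#' @param best A `leuco_fit` (typically the winner of [select_model()]).
#' @param baseline Pre-treatment level (> 0).
#' @param plateau_slope_tol Relative change across the final 10% of the
#'   window below which the curve counts as flat (default 0.01).
#' @param baseline_tol Relative tolerance for "restored" (default 0.1).
#' @return A one-row tibble: `pattern`, `plateau_reached`, `plateau_level`,
#'   `baseline_restored` (`restored` / `altered` / `indeterminate`).
#' @export
classify_recovery <- function(best, baseline, plateau_slope_tol = 0.01,
                              baseline_tol = 0.1) {
  stopifnot(inherits(best, "leuco_fit"))
  check_positive(baseline, "baseline")
  if (is.null(best$predict_fn)) abort("Fit does not carry a prediction function.")
  t <- best$data$t
  t_fine <- seq(min(t), max(t), length.out = 200)
  yhat <- best$predict_fn(t_fine)
  tail_idx <- t_fine >= max(t) - 0.1 * diff(range(t))
  tail_y <- yhat[tail_idx]
  rel_change <- abs(diff(range(tail_y))) / max(abs(mean(tail_y)), 1e-12)
  plateau_reached <- rel_change < plateau_slope_tol
  plateau_level <- if (plateau_reached) mean(tail_y) else NA_real_
  restored <- if (!plateau_reached) "indeterminate"
  else if (abs(plateau_level - baseline) / baseline < baseline_tol) "restored"
  else "altered"
  pattern <- if (!is.na(best$family)) best$family else best$model
  tibble(pattern = pattern, plateau_reached = plateau_reached,
         plateau_level = plateau_level, baseline_restored = restored)
}
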
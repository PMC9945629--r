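# Model validation: residual-randomness diagnostics (goodness of fit) and
# cross-validation.

#' Wald-Wolfowitz runs test on a sign sequence
#'
#' Normal-approximation runs test of randomness for the signs of a numeric
#' sequence (zeros dropped). Used to operationalise "are the residuals
#' randomly scattered around the fit": too few runs means systematic
#' misfit, too many means alternation.
#'
#' @param x Numeric vector (e.g. residuals).
#' @return List: `n_pos`, `n_neg`, `n_runs`, `expected_runs`, `z`,
#'   `p_value` (two-sided), `degenerate` (all one sign).
#' @export
runs_test <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0L || n2 == 0L) {
    return(list(n_pos = n1, n_neg = n2, n_runs = if (n > 0) 1L else 0L,
                expected_runs = NA_real_, z = NA_real_, p_value = NA_real_,
                degenerate = TRUE))
  }
  runs <- 1L + sum(s[-1] != s[-length(s)])
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(v)
  list(n_pos = n1, n_neg = n2, n_runs = runs, expected_runs = mu, z = z,
       p_value = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Goodness-of-fit diagnostics from residual randomness
#'
#' Estimates the randomness of the residual distribution: a runs test on
#' the residual signs (in time order) and the lag-1 residual
#' autocorrelation with an approximate normal p-value. A well-specified
#' model leaves residuals that behave like noise; structure (long runs,
#' positive autocorrelation) flags misfit. Residuals of identical sign are
#' reported as a degenerate case, not an error.
#'
#' @param fit A `leuco_fit`, or a numeric vector of residuals in time
#'   order; at least 8 residuals required.
#' @return One-row tibble: `n`, `n_runs`, `runs_z`, `runs_p`, `acf1`,
#'   `acf1_p`, `degenerate`.
#' @export
goodness_of_fit <- function(fit) {
  res <- if (inherits(fit, "leuco_fit")) fit$residuals else fit
  if (!is.numeric(res)) abort("`fit` must be a leuco_fit or numeric residuals.")
  res <- res[is.finite(res)]
  if (length(res) < 8L) {
    abort(sprintf("Need >= 8 residuals for the diagnostics; got %d.", length(res)))
  }
  rt <- runs_test(res)
  n <- length(res)
  r1 <- sum(res[-1] * res[-n]) / sum(res^2)
  acf1_p <- 2 * pnorm(-abs(r1 * sqrt(n)))
  tibble(n = n, n_runs = rt$n_runs, runs_z = rt$z, runs_p = rt$p_value,
         acf1 = r1, acf1_p = acf1_p, degenerate = rt$degenerate)
}

#' Cross-validate a model on a blood-count time series
#'
#' Partitions the data into complementary subsets, fits on the training
#' part and evaluates prediction error on the held-out part, iterating so
#' every observation is tested exactly once. Two schemes: blocked
#' contiguous time folds for a single trajectory (random folds would leak
#' the temporal structure) and leave-one-subject-out for multi-subject
#' data. Large held-out errors relative to training errors flag
#' overfitting.
#'
#' @param data Data frame with time and count columns (plus `subject_id`
#'   for `leave_one_subject_out`).
#' @param model `"growth"` (fit a growth family) or a mechanistic model
#'   kind for [estimate_parameters()].
#' @param scheme `"k_fold_blocked_time"` or `"leave_one_subject_out"`.
#' @param k Number of folds (blocked-time scheme).
#' @param seed Integer seed; folds and fits are deterministic given the
#'   seed.
#' @param family Growth family when `model = "growth"`.
#' @param free,fixed Passed to [estimate_parameters()].
#' @param time,response Column names.
#' @param ... Further fitter arguments.
#' @return A `cv_result`: `folds` tibble (fold, n_train, n_test,
#'   train_rmse, test_rmse), `cv_rmse` (RMSE over all held-out points),
#'   `scheme`, `k`, `seed`.
#' @export
cross_validate <- function(data, model,
                           scheme = c("k_fold_blocked_time", "leave_one_subject_out"),
                           k = 5, seed = 1, family = NULL,
                           free = NULL, fixed = list(),
                           time = "time", response = "count", ...) {
  scheme <- match.arg(scheme)
  data <- as_tibble(data)
  if (!all(c(time, response) %in% names(data))) {
    abort(sprintf("`data` must contain columns '%s' and '%s'.", time, response))
  }

  if (scheme == "k_fold_blocked_time") {
    ord <- order(data[[time]])
    data <- data[ord, ]
    n <- nrow(data)
    if (k > n) abort(sprintf("k = %d exceeds the %d usable blocks.", k, n))
    fold_id <- rep(seq_len(k), times = diff(floor(seq(0, n, length.out = k + 1))))
  } else {
    if (!"subject_id" %in% names(data)) {
      abort("leave_one_subject_out requires a `subject_id` column.")
    }
    subs <- unique(data$subject_id)
    k <- length(subs)
    fold_id <- match(data$subject_id, subs)
  }

  fit_one <- function(d) {
    if (identical(model, "growth")) {
      fit_growth(d, family, time = time, response = response, ...)
    } else {
      estimate_parameters(d, model, free = free, fixed = fixed,
                          time = time, response = response, ...)
    }
  }

  rows <- list(); held_err <- c()
  for (f in seq_len(k)) {
    train <- data[fold_id != f, ]
    test <- data[fold_id == f, ]
    fit <- withr::with_seed(seed + f, fit_one(train))
    if (is.null(fit$predict_fn)) abort("Fitted model carries no prediction function.")
    pred_test <- fit$predict_fn(test[[time]])
    pred_train <- fit$predict_fn(train[[time]])
    test_rmse <- sqrt(mean((test[[response]] - pred_test)^2))
    train_rmse <- sqrt(mean((train[[response]] - pred_train)^2))
    held_err <- c(held_err, test[[response]] - pred_test)
    rows[[f]] <- tibble(fold = f, n_train = nrow(train), n_test = nrow(test),
                        train_rmse = train_rmse, test_rmse = test_rmse)
  }
  structure(list(folds = bind_rows(rows),
                 cv_rmse = sqrt(mean(held_err^2)),
                 scheme = scheme, k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, k = %d, CV RMSE = %.4g\n",
              x$scheme, x$k, x$cv_rmse))
  print(x$folds)
  invisible(x)
}
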
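# Clinical blood-count summary metrics: lymphopenia grading, the
# neutrophil-to-lymphocyte ratio (NLR), the lymphocyte-to-monocyte ratio
# (LMR) with its prognostic threshold, and the linear-quadratic chromosome
# aberration dose response.

#' Grade lymphopenia from an absolute lymphocyte count
#'
#' Grades against the two published cut points: counts below 500 cells/uL
#' are severe (grade 3-4) lymphopenia; 500 to < 1000 is below the normal
#' range (grade 1-2); 1000-4800 is normal. Counts above 4800 fall outside
#' the grading and are flagged `above_normal`. The lower bound is strict
#' (`< 500`); full CTCAE sub-grades are not invented — pass custom `bins`
#' to use different cut points.
#'
#' @param lymphocytes Lymphocyte count(s), cells/uL, >= 0.
#' @param bins Numeric cut points `c(severe, lower_normal, upper_normal)`
#'   (default `c(500, 1000, 4800)`).
#' @return Factor with levels `grade3_4`, `below_normal_grade1_2`,
#'   `normal`, `above_normal`.
#' @export
#' @examples
#' grade_lymphopenia(c(400, 700, 1500, 5000))
grade_lymphopenia <- function(lymphocytes, bins = c(500, 1000, 4800)) {
  if (any(!is.finite(lymphocytes)) || any(lymphocytes < 0)) {
    abort("Lymphocyte counts must be finite and >= 0.")
  }
  stopifnot(length(bins) == 3, !is.unsorted(bins))
  lv <- c("grade3_4", "below_normal_grade1_2", "normal", "above_normal")
  out <- ifelse(lymphocytes < bins[1], lv[1],
         ifelse(lymphocytes < bins[2], lv[2],
         ifelse(lymphocytes <= bins[3], lv[3], lv[4])))
  factor(out, levels = lv)
}

#' Neutrophil-to-lymphocyte ratio
#'
#' NLR = neutrophils / lymphocytes in peripheral blood, an inflammation
#' marker. A zero lymphocyte count makes the ratio undefined and is an
#' error (no infinity is returned).
#'
#' @param neutrophils,lymphocytes Counts, cells/uL.
#' @return Numeric ratio, vectorized.
#' @export
#' @examples
#' compute_nlr(4000, 1000)  # 4
compute_nlr <- function(neutrophils, lymphocytes) {
  if (any(!is.finite(neutrophils)) || any(neutrophils < 0)) {
    abort("Neutrophil counts must be finite and >= 0.")
  }
  if (any(!is.finite(lymphocytes)) || any(lymphocytes <= 0)) {
    abort("NLR undefined: lymphocyte count must be > 0.")
  }
  neutrophils / lymphocytes
}

#' Lymphocyte-to-monocyte ratio with prognostic classification
#'
#' LMR = lymphocytes / monocytes, classified `high` when the ratio is at
#' or above the threshold (default 4.25, the published cut point at which
#' a high LMR associated with favourable disease-free survival). The
#' boundary convention is `>=` = high. The literature occasionally writes
#' the ratio the other way around; `invert = TRUE` computes
#' monocytes/lymphocytes instead (the classification then flags `high`
#' when the inverted ratio is at or below `1/threshold`).
#'
#' @param lymphocytes,monocytes Counts, cells/uL.
#' @param threshold Classification threshold on the lymphocyte/monocyte
#'   scale (default 4.25).
#' @param invert Compute monocytes/lymphocytes instead.
#' @return Tibble with `lmr` and `lmr_class` (`high`/`low`), vectorized.
#' @export
#' @examples
#' compute_lmr(1700, 400)  # 4.25, high
compute_lmr <- function(lymphocytes, monocytes, threshold = 4.25,
                        invert = FALSE) {
  if (any(!is.finite(lymphocytes)) || any(lymphocytes < 0)) {
    abort("Lymphocyte counts must be finite and >= 0.")
  }
  if (any(!is.finite(monocytes)) || any(monocytes <= 0)) {
    abort("LMR undefined: monocyte count must be > 0.")
  }
  check_positive(threshold, "threshold")
  ratio_lm <- lymphocytes / monocytes
  high <- ratio_lm >= threshold
  if (invert) {
    if (any(lymphocytes <= 0)) abort("Inverted LMR undefined: lymphocyte count must be > 0.")
    tibble(lmr = monocytes / lymphocytes,
           lmr_class = factor(ifelse(high, "high", "low"), c("high", "low")))
  } else {
    tibble(lmr = ratio_lm,
           lmr_class = factor(ifelse(high, "high", "low"), c("high", "low")))
  }
}

#' Add leucocyte summary metrics to a blood-count table
#'
#' Data-frame-first wrapper computing lymphopenia grade, NLR and LMR per
#' row from `neutrophils`, `lymphocytes`, `monocytes` columns. Missing
#' counts stay missing (never zero-imputed); metrics needing a missing or
#' zero denominator come back `NA`.
#'
#' @param data Data frame with `neutrophils`, `lymphocytes`, `monocytes`
#'   columns (cells/uL).
#' @param lmr_threshold,invert_lmr Passed to [compute_lmr()].
#' @return The input tibble with `lymphopenia_grade`, `nlr`, `lmr`,
#'   `lmr_class` columns appended.
#' @export
add_leucocyte_metrics <- function(data, lmr_threshold = 4.25,
                                  invert_lmr = FALSE) {
  data <- as_tibble(data)
  need <- c("neutrophils", "lymphocytes", "monocytes")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` must contain columns: %s.", paste(need, collapse = ", ")))
  }
  safe1 <- function(f, ...) tryCatch(f(...), error = function(e) NA)
  data |>
    mutate(
      lymphopenia_grade = factor(
        purrr::map_chr(.data$lymphocytes, function(l) {
          g <- safe1(grade_lymphopenia, l)
          if (all(is.na(g))) NA_character_ else as.character(g)
        }),
        levels = levels(grade_lymphopenia(0))),
      nlr = purrr::map2_dbl(.data$neutrophils, .data$lymphocytes,
                            function(n, l) as.numeric(safe1(compute_nlr, n, l))),
      lmr = purrr::map2_dbl(.data$lymphocytes, .data$monocytes, function(l, m) {
        r <- safe1(compute_lmr, l, m, threshold = lmr_threshold, invert = invert_lmr)
        if (all(is.na(r))) NA_real_ else r$lmr
      }),
      lmr_class = factor(
        purrr::map2_chr(.data$lymphocytes, .data$monocytes, function(l, m) {
          r <- safe1(compute_lmr, l, m, threshold = lmr_threshold, invert = invert_lmr)
          if (all(is.na(r))) NA_character_ else as.character(r$lmr_class)
        }), levels = c("high", "low")))
}

#' Linear-quadratic chromosome-aberration dose-response parameters
#'
#' Aberration yield per cell as a function of dose D (Gy):
#' \eqn{Y(D) = c + \alpha D + \beta D^2}. Coefficients are user inputs
#' (e.g. separate lymphocyte and neutrophil sets; lymphocytes show the
#' steeper response).
#'
#' @param c Baseline aberration frequency (>= 0).
#' @param alpha Linear coefficient, per Gy (>= 0).
#' @param beta Quadratic coefficient, per Gy^2 (>= 0).
#' @param lineage Optional lineage label.
#' @return An `aberration_params` object.
#' @export
aberration_params <- function(c, alpha, beta, lineage = NA_character_) {
  check_number(c, "c", lower = 0)
  check_number(alpha, "alpha", lower = 0)
  check_number(beta, "beta", lower = 0)
  structure(list(c = c, alpha = alpha, beta = beta, lineage = lineage),
            class = "aberration_params")
}

#' Expected chromosome aberrations per cell at a dose
#'
#' Evaluates the linear-quadratic yield \eqn{c + \alpha D + \beta D^2};
#' non-decreasing in dose for non-negative coefficients.
#'
#' @param dose Dose(s) in Gy, >= 0.
#' @param params An `aberration_params` object.
#' @return Expected aberrations per cell, vectorized over `dose`.
#' @export
#' @examples
#' aberration_yield(2, aberration_params(0.001, 0.05, 0.06))  # 0.341
aberration_yield <- function(dose, params) {
  stopifnot(inherits(params, "aberration_params"))
  if (any(!is.finite(dose)) || any(dose < 0)) {
    abort("`dose` must be finite and >= 0.")
  }
  params$c + params$alpha * dose + params$beta * dose^2
}
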
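# Seeded synthetic cohorts with the statistical structure the fitting
# stages assume: per-subject log-normal parameter variability around a
# truth, deterministic kinetic trajectories, multiplicative log-normal (or
# negative-binomial) observation noise, and ground truth attached so any
# estimator run on the dataset can be scored.

#' Describe a synthetic simulation design
#'
#' @param model Model kind (`"exponential"`, `"friberg_recovery"`,
#'   `"whole_course"`, `"linear"`).
#' @param truth Named list of true parameter values for the model.
#' @param n_subjects Number of subjects.
#' @param iiv_cv Named numeric vector of inter-individual coefficients of
#'   variation (log-normal, per parameter); parameters not named get CV 0.
#' @param sampling_days Observation days (within the simulation horizon).
#' @param noise List: `kind = "lognormal"` with `sigma` (log-scale SD,
#'   default 0.1) or `kind = "negbin"` with `size` (dispersion).
#' @param cell_type Cell-type label for the output rows.
#' @param seed Integer seed (mandatory: every draw is reproducible).
#' @return A `simulation_design` object.
#' @export
simulation_design <- function(model, truth, n_subjects = 1,
                              iiv_cv = numeric(0), sampling_days,
                              noise = list(kind = "lognormal", sigma = 0.1),
                              cell_type = "neutrophil", seed) {
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is mandatory.")
  if (any(iiv_cv < 0)) abort("Inter-individual CVs must be >= 0.")
  if (length(iiv_cv) && is.null(names(iiv_cv))) abort("`iiv_cv` must be named.")
  if (any(!names(iiv_cv) %in% names(truth))) {
    abort("`iiv_cv` names must be parameters of `truth`.")
  }
  check_increasing(sampling_days, "sampling_days")
  noise$kind <- noise$kind %||% "lognormal"
  if (!noise$kind %in% c("lognormal", "negbin")) {
    abort("`noise$kind` must be 'lognormal' or 'negbin'.")
  }
  if (noise$kind == "lognormal") noise$sigma <- noise$sigma %||% 0.1
  if (noise$kind == "negbin") noise$size <- noise$size %||% 20
  structure(list(model = model, truth = truth, n_subjects = n_subjects,
                 iiv_cv = iiv_cv, sampling_days = sampling_days,
                 noise = noise, cell_type = cell_type, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Draw per-subject parameters for a simulation design
#'
#' Log-normal draws around the design truth with the stated CVs (the
#' truth is the median; `sdlog = sqrt(log(1 + CV^2))` so the distribution
#' has exactly the requested coefficient of variation). Reproducible under
#' the design seed.
#'
#' @param design A `simulation_design`.
#' @return Tibble: `subject_id` plus one column per model parameter.
#' @export
generate_population_params <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  withr::with_seed(design$seed, {
    n <- design$n_subjects
    cols <- purrr::imap(design$truth, function(val, nm) {
      cv <- design$iiv_cv[nm]
      if (is.na(cv) || length(cv) == 0 || cv == 0) return(rep(val, n))
      sdlog <- sqrt(log(1 + cv^2))
      val * exp(rnorm(n, 0, sdlog))
    })
    tibble(subject_id = sprintf("S%02d", seq_len(n)), !!!cols)
  })
}

synthetic_curve <- function(model, params, times) {
  if (model == "linear") {
    params$C0 + params$k * times
  } else {
    mechanistic_predict(model, params, times)
  }
}

#' Generate a synthetic blood-count dataset with ground truth
#'
#' Simulates each subject's noiseless trajectory from its drawn parameters,
#' samples it at the design's observation days, applies observation noise
#' (multiplicative log-normal by default; negative-binomial counts
#' optionally), and returns a long-format dataset plus the ground truth
#' needed to score any estimator run on it.
#'
#' @param design A `simulation_design`.
#' @return A `synthetic_dataset`: `data` (tibble `subject_id`, `time`,
#'   `cell_type`, `count`), `subject_params` (true per-subject parameters),
#'   `truth_curves` (noiseless values at the sampling days), `design`.
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  params <- generate_population_params(design)
  days <- design$sampling_days
  curves <- purrr::pmap(params, function(subject_id, ...) {
    p <- list(...)
    tibble(subject_id = subject_id, time = days,
           true_value = synthetic_curve(design$model, p, days))
  }) |> bind_rows()
  data <- withr::with_seed(design$seed + 1L, {
    noise <- design$noise
    count <- if (noise$kind == "lognormal") {
      curves$true_value * exp(rnorm(nrow(curves), 0, noise$sigma))
    } else {
      rnbinom(nrow(curves), mu = pmax(curves$true_value, 1e-9), size = noise$size)
    }
    tibble(subject_id = curves$subject_id, time = curves$time,
           cell_type = design$cell_type, count = count)
  })
  structure(list(data = data, subject_params = params,
                 truth_curves = curves, design = design),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> model %s, %d subject(s), %d rows (seed %d)\n",
              x$design$model, x$design$n_subjects, nrow(x$data), x$design$seed))
  print(head(x$data))
  invisible(x)
}

# Fixture truth constants. These are artifact constants chosen so the
# noiseless curves show the qualitative total-body-irradiation kinetics
# (neutrophils: Day-1 rise, exponential fall to a ~10%-of-baseline nadir
# near Day 14, recovery with a slight rebound to baseline; lymphocytes:
# ~3% nadir, recovery over 100-300 days with a transient rebound). They
# are NOT fitted estimates from any published study.
macaque_truth <- function(kind) {
  switch(kind,
    neutrophil = list(C0 = 5000, mtt = 3.0, kcirc = 0.25, gamma = 0.08,
                      n_transit = 3, spike = 0.2, bm_surviving = 0.03,
                      ramp_start = 1, ramp_end = 14, ramp_shape = "linear"),
    lymphocyte = list(C0 = 2500, mtt = 30, kcirc = 0.06, gamma = 0.10,
                      n_transit = 3, deplete_frac = 0.03),
    abort("`kind` must be 'neutrophil' or 'lymphocyte'."))
}

#' Synthetic macaque-like total-body-irradiation fixture
#'
#' Builds a seeded synthetic dataset emulating post-irradiation blood-count
#' kinetics in macaques. The neutrophil fixture uses the two-phase
#' whole-course model (Day-1 demargination rise, exponential decline while
#' marrow output is off, nadir near Day 14 around 10% of baseline,
#' feedback-driven recovery with a modest rebound, plateau at baseline by
#' Day 60). The lymphocyte fixture uses the feedback recovery model after
#' instantaneous depletion to ~3% of baseline, recovering with a transient
#' rebound to stable levels between Day 100 and 300. All fixture constants
#' are synthetic package choices, not published estimates.
#'
#' @param kind `"neutrophil"` or `"lymphocyte"`.
#' @param seed Integer seed.
#' @param sigma_log Observation log-normal sigma (default 0.1; 0 gives the
#'   noiseless curve).
#' @param n_subjects Number of subjects (default 1).
#' @param iiv_cv Named inter-individual CVs (default none).
#' @return A `synthetic_dataset`; `truth_summary` in the result holds the
#'   noiseless nadir/recovery summary from [nadir_and_recovery()].
#' @export
#' @examples
#' fx <- make_macaque_like_fixture("neutrophil", seed = 1)
#' fx$truth_summary
make_macaque_like_fixture <- function(kind = c("neutrophil", "lymphocyte"),
                                      seed = 1, sigma_log = 0.1,
                                      n_subjects = 1, iiv_cv = numeric(0)) {
  kind <- match.arg(kind)
  truth <- macaque_truth(kind)
  if (kind == "neutrophil") {
    days <- c(0, 1, 2, 3, 4, 5, 6, 7, 8, 10, 12, 14, 16, 18, 20, 22, 25,
              28, 32, 36, 40, 45, 50, 55, 60)
    model <- "whole_course"
  } else {
    days <- c(0, 1, 3, 7, 14, 21, 30, 40, 50, 65, 80, 95, 110, 125, 140,
              160, 180, 200, 225, 250, 275, 300, 330, 365)
    model <- "friberg_recovery"
  }
  design <- simulation_design(model = model, truth = truth,
                              n_subjects = n_subjects, iiv_cv = iiv_cv,
                              sampling_days = days,
                              noise = list(kind = "lognormal", sigma = sigma_log),
                              cell_type = kind, seed = seed)
  out <- generate_dataset(design)
  # dense noiseless curve + its summary as ground truth
  dense <- seq(min(days), max(days), length.out = 481)
  curve <- synthetic_curve(model, truth, dense)
  out$truth_dense <- tibble(time_days = dense, value = curve)
  out$truth_summary <- nadir_and_recovery(out$truth_dense, baseline = truth$C0)
  out$kind <- kind
  out
}
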
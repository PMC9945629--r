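# shared estimation engine, covariate screening, individual-based fits

test_that("noiseless exponential data are recovered to high precision", {
  t <- 0:20
  d <- tibble::tibble(time = t, count = 5000 * exp(-0.25 * t))
  fit <- estimate_parameters(d, "exponential",
                             free = list(C0 = c(100, 1e5), k = c(0.01, 2)))
  expect_true(fit$converged)
  expect_equal(fit$estimates$C0, 5000, tolerance = 1e-4)
  expect_equal(fit$estimates$k, 0.25, tolerance = 1e-4)
})

test_that("noiseless whole-course output returns its own (kcirc, gamma)", {
  tt <- c(0:14, seq(16, 60, by = 2))
  y <- leucokin:::mechanistic_predict("whole_course", neutrophil_truth, tt)
  fit <- estimate_parameters(
    tibble::tibble(time = tt, count = y), "whole_course",
    free = list(kcirc = c(0.05, 1), gamma = c(0.02, 0.5)),
    fixed = neutrophil_truth[c("C0", "mtt", "n_transit", "spike",
                               "bm_surviving", "ramp_start", "ramp_end",
                               "ramp_shape")],
    n_starts = 3)
  expect_true(fit$converged)
  expect_equal(fit$estimates$kcirc, 0.25, tolerance = 1e-3)
  expect_equal(fit$estimates$gamma, 0.08, tolerance = 1e-3)
})

test_that("estimation guards identifiability and input shape", {
  d <- tibble::tibble(time = 0:2, count = c(10, 5, 2))
  expect_error(
    estimate_parameters(d, "exponential",
                        free = list(C0 = c(1, 100), k = c(0.01, 2),
                                    x1 = c(1, 2))),
    "Identifiability")
  d2 <- tibble::tibble(subject_id = c("a", "a", "b", "b"),
                       time = c(0, 1, 0, 1), count = c(10, 5, 9, 4))
  expect_error(estimate_parameters(d2, "exponential",
                                   free = list(C0 = c(1, 100), k = c(0.01, 2))),
               "fit_individuals")
  expect_error(estimate_parameters(d, "exponential",
                                   free = list(C0 = c(-1, 100), k = c(0.01, 2))),
               "bounds")
})

test_that("covariate screening favours the null without an effect and the true link with one", {
  make_arm <- function(d, k, r) {
    des <- simulation_design("linear", truth = list(C0 = 1000, k = k),
                             sampling_days = seq(0.25, 10, length.out = 40),
                             noise = list(kind = "lognormal", sigma = 0.1),
                             seed = 1000 * r + d)
    out <- generate_dataset(des)$data
    out$dose_Gy <- d
    out
  }
  null_wins <- 0; lin_wins <- 0
  for (r in 1:20) {
    d_null <- dplyr::bind_rows(lapply(c(2, 4, 8), function(d) make_arm(d, -40, r)))
    if (screen_variable(d_null)$best == "constant") null_wins <- null_wins + 1
    d_eff <- dplyr::bind_rows(lapply(c(2, 4, 8), function(d) make_arm(d, -10 * d, r)))
    sc <- screen_variable(d_eff, families = c("constant", "linear"))
    if (sc$best == "linear") lin_wins <- lin_wins + 1
  }
  expect_gte(null_wins, 18)
  expect_gte(lin_wins, 18)
})

test_that("screening recovers per-level slopes and guards its inputs", {
  dat <- dplyr::bind_rows(lapply(c(2, 6), function(d) {
    tibble::tibble(time = 0:9, count = 1000 - 15 * d * (0:9), dose_Gy = d)
  }))
  sc <- screen_variable(dat, families = c("constant", "linear"))
  expect_equal(sc$per_level$k_hat, c(-30, -90), tolerance = 1e-8)
  expect_equal(sc$best, "linear")
  # single level errors
  expect_error(screen_variable(dat[dat$dose_Gy == 2, ]), ">= 2 covariate levels")
  # under-populated levels are dropped with a warning
  dat2 <- dplyr::bind_rows(dat,
    tibble::tibble(time = c(0, 1), count = c(1000, 990), dose_Gy = 9))
  expect_warning(sc2 <- screen_variable(dat2, families = c("constant", "linear")),
                 "excluded")
  expect_equal(nrow(sc2$per_level), 2L)
})

test_that("identical subjects give near-zero population CV and matching pooled fit", {
  t <- 0:14
  dat <- dplyr::bind_rows(lapply(sprintf("S%02d", 1:4), function(s) {
    tibble::tibble(subject_id = s, time = t, count = 4000 * exp(-0.3 * t))
  }))
  ie <- fit_individuals(dat, "exponential",
                        free = list(C0 = c(100, 1e5), k = c(0.01, 2)))
  expect_equal(ie$n_failed, 0L)
  cv_k <- ie$summary$cv[ie$summary$parameter == "k"]
  expect_lt(cv_k, 1e-4)
  expect_equal(ie$pooled$estimates$k,
               mean(tidy(ie)$k), tolerance = 1e-4)
})

test_that("heterogeneous subgroups mislead the pooled fit but not the individual mean", {
  # two subgroups with very different decline rates; the pooled single-k
  # fit compromises between them
  t <- 0:14
  dat <- dplyr::bind_rows(
    lapply(1:3, function(i) tibble::tibble(
      subject_id = sprintf("A%d", i), time = t, count = 4000 * exp(-0.05 * t))),
    lapply(1:3, function(i) tibble::tibble(
      subject_id = sprintf("B%d", i), time = t, count = 4000 * exp(-0.6 * t))))
  # natural-scale loss: the pooled fit is dominated by the slowly declining
  # (larger-count) subgroup, while the individual-based mean is not
  ie <- fit_individuals(dat, "exponential",
                        free = list(C0 = c(100, 1e5), k = c(0.005, 2)),
                        loss = "ssr")
  k_ind <- mean(tidy(ie)$k)           # ~ (0.05 + 0.6)/2
  k_pool <- ie$pooled$estimates$k
  expect_equal(k_ind, 0.325, tolerance = 0.02)
  expect_gt(abs(k_pool - k_ind), 0.05)
  expect_equal(sort(unique(round(tidy(ie)$k, 3))), c(0.05, 0.6),
               tolerance = 1e-2)
})

test_that("population CV of 30% is recovered within 10 percentage points", {
  des <- simulation_design("exponential", truth = list(C0 = 5000, k = 0.25),
                           n_subjects = 20, iiv_cv = c(k = 0.3),
                           sampling_days = seq(1, 14, 1),
                           noise = list(kind = "lognormal", sigma = 0.1),
                           seed = 2)
  ds <- generate_dataset(des)
  ie <- fit_individuals(ds$data, "exponential",
                        free = list(C0 = c(500, 5e4), k = c(0.01, 2)),
                        n_starts = 3)
  cv <- ie$summary$cv[ie$summary$parameter == "k"]
  expect_lt(abs(cv - 0.3), 0.10)
})
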
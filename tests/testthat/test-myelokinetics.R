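# semi-mechanistic myeloid models and the two-phase radiation model

test_that("feedback factor follows the power law with a floor", {
  fb <- feedback_params(C0 = 5000, gamma = 1)
  expect_equal(feedback_factor(5000, fb), 1)
  expect_equal(feedback_factor(2500, fb), 2)
  fb0 <- feedback_params(C0 = 5000, gamma = 0)
  expect_equal(feedback_factor(123, fb0, quiet = TRUE), 1)
  # strictly decreasing in C for gamma > 0
  cs <- seq(500, 10000, by = 500)
  f <- feedback_factor(cs, fb)
  expect_true(all(diff(f) < 0))
  # floor engages (with a message) instead of blowing up at C <= 0
  expect_message(v <- feedback_factor(0, fb), "clamped")
  expect_equal(v, 1 / 1e-3)
  expect_error(feedback_factor(NA_real_, fb), "NA")
})

test_that("early-phase exponential decline is evaluated in closed form", {
  expect_equal(simulate_exponential_phase(exponential_phase_params(100, 0), 0:5)$value,
               rep(100, 6))
  expect_equal(simulate_exponential_phase(exponential_phase_params(100, log(2)), 1)$value,
               50)
  expect_equal(simulate_exponential_phase(exponential_phase_params(100, 0.2), 13)$value,
               100 * exp(-2.6))
  expect_error(simulate_exponential_phase(exponential_phase_params(100, 0.2), -1),
               "non-negative")
})

test_that("steady-state calibration balances every compartment", {
  p <- friberg_params(C0 = 5000, mtt = 4, kcirc = 0.3, gamma = 0.2)
  # transit pools C0*kcirc*mtt/(n+1) each
  expect_equal(unname(p$setpoints["transit1"]), 5000 * 0.3 * 4 / 4)
  expect_equal(unname(p$setpoints["prolif"]), 5000 * 0.3 / p$ktr)
  # completed set passes a consistency check; wrong set points are named
  expect_silent(calibrate_steady_state("friberg", C0 = 5000, mtt = 4, kcirc = 0.3,
                                       setpoints = c(transit1 = 1500)))
  expect_error(calibrate_steady_state("friberg", C0 = 5000, mtt = 4, kcirc = 0.3,
                                      setpoints = c(transit1 = 99)),
               "flux balance")
  # unbounded proliferating pool rejected
  expect_error(bm_blood_params(C0 = 5000, k = 1, k1 = 0.5, k2 = 2, p = 1.5),
               "Unbounded")
})

test_that("every calibrated model is flat from steady state", {
  grid <- seq(0, 100, by = 1)
  models <- list(
    circ_of(simulate_friberg(quick_friberg(0.3), grid)),
    circ_of(simulate_bm_blood(
      bm_blood_params(C0 = 5000, k = 1.2, k1 = 0.8, k2 = 2.2,
                      gamma_p = 0.2, gamma_m = 0.1), grid)),
    circ_of(simulate_monocytes(monocyte_params(), grid)))
  for (ser in models) {
    expect_lt(max(abs(ser$value / ser$value[1] - 1)), 1e-6)
  }
})

test_that("feedback drives homeostatic return with a transient rebound", {
  p <- quick_friberg(gamma = 0.2)
  tr <- simulate_friberg(p, seq(0, 250, by = 0.5),
    perturbation = list(kind = "deplete_pool", pool = "circulating",
                        fraction = 0.1))
  ser <- circ_of(tr)
  expect_equal(min(ser$value) / 5000, 0.1, tolerance = 0.05)
  # returns to within 1% of the set point
  expect_lt(abs(ser$value[nrow(ser)] / 5000 - 1), 0.01)
  # overshoot above baseline on the way back
  expect_gt(max(ser$value), 5000 * 1.01)
})

test_that("open-loop chain settles at the level set by the proliferating pool", {
  p <- quick_friberg(gamma = 0)
  init <- p$setpoints
  init["prolif"] <- init["prolif"] / 2  # halved proliferation influx
  tr <- simulate_friberg(p, seq(0, 400, by = 2), init = init)
  ser <- circ_of(tr)
  expect_equal(ser$value[nrow(ser)], 2500, tolerance = 1e-3)
})

test_that("with marrow pools empty and feedback off, the circulating pool is pure clearance", {
  p <- quick_friberg(gamma = 0)
  init <- p$setpoints
  init[setdiff(names(init), "circulating")] <- 0
  grid <- seq(0, 30, by = 0.5)
  tr <- simulate_friberg(p, grid, init = init)
  ser <- circ_of(tr)
  expect_equal(ser$value, 5000 * exp(-0.25 * grid), tolerance = 1e-6)
})

test_that("bone-marrow/blood model boosts proliferation when depleted", {
  p <- bm_blood_params(C0 = 5000, k = 1.2, k1 = 0.8, k2 = 2.2,
                       gamma_p = 0.3, gamma_m = 0.1)
  tr <- simulate_bm_blood(p, seq(0, 60, by = 0.25),
    perturbation = list(kind = "deplete_pool", pool = "circulating",
                        fraction = 0.1))
  ser <- circ_of(tr)
  # at the nadir the effective proliferation rate exceeds its baseline
  c_nadir <- min(ser$value)
  expect_gt((p$C0 / c_nadir)^p$gamma_p, 1)
  # homeostatic return
  expect_lt(abs(ser$value[nrow(ser)] / 5000 - 1), 0.01)
})

test_that("monocyte chain reproduces the classical-dominant blood composition", {
  p <- monocyte_params()
  sp <- p$setpoints
  share <- sp[["classical"]] /
    (sp[["classical"]] + sp[["intermediate"]] + sp[["non_classical"]])
  expect_equal(unname(share), 0.99, tolerance = 0.001)
  # last-compartment balance: doubling d3 halves the non-classical pool
  p2 <- monocyte_params(d3 = 2 / 7.4)
  expect_equal(p2$setpoints[["non_classical"]], sp[["non_classical"]] / 2)
  # transient depletion of the marrow mature pool refills from upstream
  tr <- simulate_monocytes(p, seq(0, 80, by = 0.5),
    perturbation = list(kind = "deplete_pool", pool = "bm_mature", fraction = 0.5))
  ser <- circ_of(tr)
  expect_lt(abs(ser$value[nrow(ser)] / sp[["classical"]] - 1), 0.01)
})

test_that("whole-course model: null ramp is steady state; full shutdown is pure clearance", {
  p <- quick_friberg(gamma = 0.08)
  wc_none <- whole_course_params(p, ramp_shape = "none")
  ser <- circ_of(simulate_whole_course(wc_none, seq(0, 60, by = 1)))
  expect_lt(max(abs(ser$value / 5000 - 1)), 1e-6)

  wc_off <- whole_course_params(p, ramp_shape = "off", spike = 0,
                                bm_surviving = 1)
  tr <- simulate_whole_course(wc_off, seq(0, 80, by = 0.25))
  # once the transit pools are essentially empty the log-slope is -kcirc
  wide <- tidyr::pivot_wider(tr, names_from = "compartment",
                             values_from = "value", id_cols = "time_days")
  emptied <- wide$transit3 < 1e-6 * p$setpoints[["transit3"]]
  t_sel <- wide$time_days[emptied]
  c_sel <- wide$circulating[emptied]
  expect_gt(length(t_sel), 3)
  slopes <- diff(log(c_sel)) / diff(t_sel)
  expect_equal(mean(slopes), -0.25, tolerance = 0.01)
})

test_that("whole-course trajectory shows spike, decline, nadir, sigmoid recovery", {
  p <- friberg_params(C0 = neutrophil_truth$C0, mtt = neutrophil_truth$mtt,
                      kcirc = neutrophil_truth$kcirc, gamma = neutrophil_truth$gamma)
  wc <- whole_course_params(p, spike = 0.2, bm_surviving = 0.03)
  ser <- circ_of(simulate_whole_course(wc, seq(0, 90, by = 0.25)))
  expect_equal(ser$value[ser$time_days == 1], 6000)  # demargination spike
  s <- nadir_and_recovery(ser, baseline = 5000)
  expect_lt(s$nadir_fraction, 0.15)
  expect_gt(s$nadir_day, 10)
  expect_true(s$plateau_reached)
  expect_equal(s$plateau / 5000, 1, tolerance = 0.05)
  # monotone decline between spike and nadir
  mid <- ser$value[ser$time_days >= 1 & ser$time_days <= s$nadir_day]
  expect_true(all(diff(mid) <= 1e-8))
})

test_that("nadir_and_recovery summarises constant and dipping series correctly", {
  flat <- tibble::tibble(time_days = 0:20, value = rep(100, 21))
  s <- nadir_and_recovery(flat, baseline = 100)
  expect_equal(s$nadir_fraction, 1)
  expect_equal(s$recovery_day, 0)
  expect_true(s$plateau_reached)

  dip <- tibble::tibble(time_days = 0:20,
                        value = c(100, 60, 30, 10, 20, 40, 60, 80, 95,
                                  rep(100, 12)))
  s2 <- nadir_and_recovery(dip, baseline = 100)
  expect_equal(s2$nadir_fraction, 0.10)
  expect_equal(s2$nadir_day, 3)
  expect_equal(s2$recovery_day, 8)  # first day at >= 90 after the nadir
  expect_error(nadir_and_recovery(flat[0, ], baseline = 100), "non-empty")
})
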
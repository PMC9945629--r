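# blood <-> lymphoid-organ recirculation model

test_that("calibration solves the star-topology flux balance", {
  # symmetric two-compartment exchange
  p <- calibrate_recirculation(pi = c(blood = 0.5, organ = 0.5),
                               tau = c(blood = 10, organ = 10))
  expect_equal(unname(p$q["organ"]), 1)
  expect_equal(unname(p$rate_matrix["organ", "blood"]), 0.1)
  expect_equal(unname(p$rate_matrix["blood", "organ"]), 0.1)

  # unknown residence time solved from balance: pi_o/tau_o = pi_b/tau_b
  p2 <- calibrate_recirculation(pi = c(blood = 0.2, organ = 0.8),
                                tau = c(blood = 10))
  expect_equal(unname(p2$tau["organ"]), 40)

  # rodent calibration reproduces the published steady-state fractions
  expect_equal(unname(rodent$pi),
               c(0.0415, 0.3321, 0.5808, 0.0456) / 1.0000)
  organs <- setdiff(rodent$compartments, "blood")
  expect_equal(unname(rodent$pi[organs] / rodent$tau[organs]),
               unname(rodent$q[organs] * rodent$pi[["blood"]] / rodent$tau[["blood"]]),
               tolerance = 1e-9)
  expect_equal(sum(rodent$q), 1, tolerance = 1e-9)
})

test_that("infeasible or underdetermined calibrations error informatively", {
  # blood residence too long: organs demand more influx than blood supplies
  expect_error(
    calibrate_recirculation(
      pi = c(blood = 0.0415, spleen = 0.3321, other_SLO = 0.5808, others = 0.0456),
      tau = c(blood = 25, spleen = 150, other_SLO = 600)),
    "infeasible")
  # fully specified but unbalanced
  expect_error(
    calibrate_recirculation(pi = c(blood = 0.5, organ = 0.5),
                            tau = c(blood = 10, organ = 20)),
    "infeasible")
  # two unknown residence times
  expect_error(
    calibrate_recirculation(pi = c(blood = 0.2, a = 0.4, b = 0.4),
                            tau = c(blood = 5)),
    "at most one")
  expect_error(
    calibrate_recirculation(pi = c(blood = 0.6, organ = 0.5),
                            tau = c(blood = 10, organ = 10)),
    "sum to 1")
})

test_that("steady-state initial conditions give a flat, conserved trajectory", {
  tr <- simulate_recirculation(rodent, t_grid = seq(0, 10000, by = 100))
  wide <- tidyr::pivot_wider(tr, names_from = "compartment", values_from = "count",
                             id_cols = "time_min")
  for (cmp in rodent$compartments) {
    expect_lt(max(abs(wide[[cmp]] / wide[[cmp]][1] - 1)), 1e-6)
  }
  totals <- tapply(tr$count, tr$time_min, sum)
  expect_lt(max(abs(totals / totals[1] - 1)), 1e-6)
})

test_that("ODE solution matches the matrix-exponential closed form", {
  skip_if_not_installed("Matrix")
  p <- calibrate_recirculation(
    pi = c(blood = 0.1, spleen = 0.5, rest = 0.4),
    tau = c(blood = 5, spleen = 120))
  x0 <- c(blood = 1, spleen = 0, rest = 0)
  grid <- seq(0, 600, by = 50)
  tr <- simulate_recirculation(p, grid, init = x0)
  wide <- tidyr::pivot_wider(tr, names_from = "compartment", values_from = "count",
                             id_cols = "time_min")
  A <- p$rate_matrix
  for (i in seq_along(grid)) {
    ref <- as.numeric(Matrix::expm(A * grid[i]) %*% x0)
    names(ref) <- rownames(A)
    got <- unlist(wide[i, p$compartments])
    expect_equal(unname(got), unname(ref[p$compartments]), tolerance = 1e-6)
  }
})

test_that("any initial distribution relaxes to the calibrated fractions", {
  tr <- simulate_recirculation(
    rodent, t_grid = c(0, 10^(2:5)),
    init = c(blood = 1, spleen = 0, other_SLO = 0, others = 0))
  final <- dplyr::filter(tr, .data$time_min == 1e5)
  expect_equal(final$fraction_of_total[match(rodent$compartments, final$compartment)],
               unname(rodent$pi), tolerance = 1e-4)
})

test_that("depletion events deplete only the targeted compartment", {
  st <- c(blood = 100, spleen = 800)
  expect_equal(apply_depletion(st, "blood", 0), c(blood = 0, spleen = 800))
  expect_equal(apply_depletion(st, "blood", 1), st)
  expect_equal(apply_depletion(st, "blood", 0.5), c(blood = 50, spleen = 800))
  expect_error(apply_depletion(st, "thymus", 0.5), "spleen")
  expect_error(apply_depletion(st, "blood", 1.5), "surviving_fraction")
})

test_that("blood recovers above 80% of initial within 200 min of a sudden drop", {
  tr <- simulate_recirculation(
    rodent, t_grid = seq(0, 300, by = 1),
    events = tibble::tibble(time = 25, compartment = "blood",
                            surviving_fraction = 0))
  rt <- recovery_time(tr, "blood", threshold = 0.8, search_from = 25.5)
  expect_lt(rt, 200)
  blood <- dplyr::filter(tr, .data$compartment == "blood")
  expect_equal(blood$count[blood$time_min == 25], 0)  # post-event state
})

test_that("recovery_time handles degenerate thresholds and flat trajectories", {
  tr <- simulate_recirculation(rodent, t_grid = seq(0, 100, by = 10))
  expect_equal(recovery_time(tr, "blood", 0), 0)
  # trajectory stuck at 50% of the reference level never reaches 80%
  flat <- tr
  flat$count <- ifelse(flat$time_min == 0, flat$count, flat$count * 0.5)
  expect_true(is.na(recovery_time(flat, "blood", 0.8, search_from = 10)))
  expect_error(recovery_time(tr, "blood", 1.2), "threshold")
  expect_error(recovery_time(tr, "blood", -0.1), "threshold")
})

test_that("refill after blood-only depletion is monotone up to equilibrium", {
  tr <- simulate_recirculation(
    rodent, t_grid = seq(0, 2000, by = 5),
    events = tibble::tibble(time = 25, compartment = "blood",
                            surviving_fraction = 0))
  blood <- dplyr::filter(tr, .data$compartment == "blood", .data$time_min >= 25)
  eq <- 0.0415 * (1 - 0.0415)  # new equilibrium after removing blood mass
  upto <- blood$count < 0.99 * eq
  diffs <- diff(blood$count[upto])
  expect_true(all(diffs >= -1e-12))
})
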
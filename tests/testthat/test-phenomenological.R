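# growth-family registry, fitting, model selection, recovery classification

test_that("growth families evaluate their closed forms", {
  expect_equal(evaluate_growth("logistic", c(A = 100, r = 0.7, tm = 12), 12), 50)
  expect_equal(evaluate_growth("exponential_rise_to_plateau",
                               c(A = 80, y0 = 5, k = 0.4), 1e6), 80)
  expect_equal(evaluate_growth("gompertz", c(A = 70, b = 1.3, c = 0.2), 0),
               70 * exp(-1.3))
  expect_equal(evaluate_growth("linear", c(a = 2, b = 3), c(0, 1, 2)),
               c(2, 5, 8))
  expect_error(evaluate_growth("splinezoid", c(a = 1, b = 2), 0), "Unknown growth family")
  expect_error(evaluate_growth("logistic", c(A = 1, r = 1), 0), "Missing parameter")
})

test_that("noiseless self-consistency: each family recovers its own parameters", {
  t <- seq(0, 30, length.out = 40)
  cases <- list(
    list(fam = "exponential_decay", p = c(A = 100, k = 0.3)),
    list(fam = "logistic", p = c(A = 5000, r = 0.4, tm = 12)),
    list(fam = "gompertz", p = c(A = 900, b = 2.5, c = 0.25)),
    list(fam = "exponential_rise_to_plateau", p = c(A = 4000, y0 = 300, k = 0.15)),
    list(fam = "linear", p = c(a = 40, b = 2.5)))
  for (cs in cases) {
    y <- evaluate_growth(cs$fam, cs$p, t)
    fit <- fit_growth(tibble::tibble(time = t, count = y), cs$fam)
    expect_true(fit$converged)
    expect_lt(fit$ssr, 1e-10)
    expect_equal(unlist(fit$estimates)[names(cs$p)], cs$p, tolerance = 1e-6)
  }
})

test_that("information criteria follow the Gaussian-residual convention", {
  t <- seq(0, 20, length.out = 25)
  y <- evaluate_growth("linear", c(a = 10, b = 2), t) + sin(seq_len(25))
  fit <- fit_growth(tibble::tibble(time = t, count = y), "linear")
  n <- fit$n_obs; p <- fit$n_params; ssr <- sum(fit$residuals^2)
  expect_equal(fit$aic, n * log(ssr / n) + 2 * p)
  expect_equal(fit$bic, n * log(ssr / n) + p * log(n))
  expect_equal(fit$n_obs, length(fit$residuals))
})

test_that("a rigid family cannot beat the generating flexible family on its own data", {
  t <- seq(0, 30, length.out = 30)
  y <- evaluate_growth("logistic", c(A = 5000, r = 0.4, tm = 14), t)
  d <- tibble::tibble(time = t, count = y)
  f_lin <- fit_growth(d, "linear")
  f_log <- fit_growth(d, "logistic")
  expect_gt(f_lin$ssr, f_log$ssr)
  rk <- select_model(list(f_lin, f_log), criterion = "aic")
  expect_equal(rk$family[1], "logistic")
})

test_that("noisy logistic data recover parameters within 15%", {
  t <- seq(0, 30, length.out = 30)
  truth <- c(A = 5000, r = 0.4, tm = 12)
  y <- withr::with_seed(7,
    evaluate_growth("logistic", truth, t) * exp(rnorm(30, 0, 0.1)))
  fit <- fit_growth(tibble::tibble(time = t, count = y), "logistic",
                    weighting = "log_scale")
  est <- unlist(fit$estimates)[names(truth)]
  expect_true(all(abs(est / truth - 1) < 0.15))
})

test_that("model ranking is deterministic with documented tie-breaking", {
  t <- seq(0, 10, length.out = 20)
  y <- evaluate_growth("linear", c(a = 5, b = 1), t)
  d <- tibble::tibble(time = t, count = y)
  f2 <- fit_growth(d, "linear")                       # 2 parameters, exact
  f3 <- fit_growth(d, "exponential_rise_to_plateau")  # >= as flexible
  rk <- select_model(list(f3, f2), criterion = "aic")
  # equal-SSR ties resolve to the smaller model
  if (abs(f3$ssr - f2$ssr) < 1e-9) expect_equal(rk$family[1], "linear")
  expect_equal(rk$rank, seq_len(nrow(rk)))
  # single candidate ranks itself
  rk1 <- select_model(list(f2))
  expect_equal(nrow(rk1), 1L)
  # mismatched series are rejected
  d2 <- d[-1, ]
  f_other <- fit_growth(d2, "linear")
  expect_error(select_model(list(f2, f_other)), "n_obs")
})

test_that("recovery classification distinguishes restored, altered, indeterminate", {
  t <- seq(0, 60, length.out = 40)
  base <- 1000
  # plateaus back at baseline
  y1 <- evaluate_growth("exponential_rise_to_plateau",
                        c(A = 1000, y0 = 100, k = 0.3), t)
  c1 <- classify_recovery(fit_growth(tibble::tibble(time = t, count = y1),
                                     "exponential_rise_to_plateau"), base)
  expect_true(c1$plateau_reached)
  expect_equal(c1$baseline_restored, "restored")
  # plateaus at 60% of baseline: homeostasis altered
  y2 <- evaluate_growth("exponential_rise_to_plateau",
                        c(A = 600, y0 = 100, k = 0.3), t)
  c2 <- classify_recovery(fit_growth(tibble::tibble(time = t, count = y2),
                                     "exponential_rise_to_plateau"), base)
  expect_true(c2$plateau_reached)
  expect_equal(c2$baseline_restored, "altered")
  # still rising at the end of the window
  y3 <- evaluate_growth("linear", c(a = 100, b = 12), t)
  c3 <- classify_recovery(fit_growth(tibble::tibble(time = t, count = y3),
                                     "linear"), base)
  expect_false(c3$plateau_reached)
  expect_equal(c3$baseline_restored, "indeterminate")
})

test_that("classification is invariant to uniform rescaling of counts", {
  t <- seq(0, 60, length.out = 40)
  y <- evaluate_growth("exponential_rise_to_plateau",
                       c(A = 800, y0 = 50, k = 0.25), t)
  f1 <- fit_growth(tibble::tibble(time = t, count = y),
                   "exponential_rise_to_plateau")
  f2 <- fit_growth(tibble::tibble(time = t, count = 1000 * y),
                   "exponential_rise_to_plateau")
  c1 <- classify_recovery(f1, 1000)
  c2 <- classify_recovery(f2, 1e6)
  expect_equal(c1$plateau_reached, c2$plateau_reached)
  expect_equal(c1$baseline_restored, c2$baseline_restored)
})

test_that("custom families can be registered and are fitted exactly when linear", {
  register_growth_family(
    "poly4_test", c("b0", "b1", "b2", "b3", "b4"),
    fn = function(t, p) p$b0 + p$b1 * t + p$b2 * t^2 + p$b3 * t^3 + p$b4 * t^4,
    start = function(t, y) as.list(setNames(rep(0, 5), paste0("b", 0:4))),
    design = function(t) cbind(1, t, t^2, t^3, t^4))
  expect_true("poly4_test" %in% growth_family())
  t <- seq(0, 10, length.out = 15)
  y <- 3 + 2 * t - 0.1 * t^2
  fit <- fit_growth(tibble::tibble(time = t, count = y), "poly4_test")
  expect_lt(fit$ssr, 1e-12)
})

test_that("fit accessors expose tidy, glance and a plot", {
  t <- seq(0, 20, length.out = 20)
  y <- evaluate_growth("exponential_decay", c(A = 100, k = 0.2), t)
  fit <- fit_growth(tibble::tibble(time = t, count = y), "exponential_decay")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  gl <- glance(fit)
  expect_true(all(c("aic", "bic", "converged") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
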
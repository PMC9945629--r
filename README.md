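# leucokin

Quantitative modelling of leucocyte kinetics after irradiation.

Radiotherapy depletes circulating white blood cells; the depth and the
recovery of that depletion differ sharply between the lymphoid lineage
(nadirs of a few percent of baseline, recovery over months) and the myeloid
lineage (nadir near 10% of baseline, recovery within weeks). `leucokin` is
an R package for scientists modelling these kinetics from longitudinal
blood-count data. It provides:

- **Lymphocyte recirculation** — a star-topology compartmental ODE model of
  blood ↔ secondary-lymphoid-organ exchange, calibrated from steady-state
  organ fractions and residence times by solving the flux balance
  π_i/τ_i = q_i · π_b/τ_b. It reproduces the rapid refill of the blood pool
  from organ reservoirs after a sudden drop.
- **Semi-mechanistic myelosuppression models** — transit-compartment
  (Friberg-type) models with power-law homeostatic feedback
  f(C) = (C₀/C)^γ on proliferation (so the turnover rate is
  k = k₀ (C₀/C)^γ), a three-pool bone-marrow/blood neutrophil model, and a
  five-pool monocyte chain (classical → intermediate → non-classical).
- **A two-phase whole-course model of radiation-induced neutropenia** —
  marrow output shut off at Day 1 and restored gradually to Day 14, with a
  demargination spike at Day 1; while the transit chain is empty the
  circulating pool decays exponentially (C_t = C₀ e^(−kt)), and the late
  phase recovers under the feedback model with a slight rebound.
- **Phenomenological curve fitting** — five growth families (linear,
  exponential decay, rise-to-plateau, logistic, Gompertz; extensible
  registry), least squares with deterministic multi-starts, MSE/AIC/BIC
  model selection, and recovery classification (plateau reached? baseline
  restored or altered?).
- **Estimation and validation** — bounded multi-start least squares for
  the mechanistic models, dose-covariate screening of f(d) = k link
  families against a no-covariate null, two-stage individual-based
  estimation with population CVs, runs-test residual diagnostics, and
  blocked-time / leave-one-subject-out cross-validation.
- **Clinical metrics** — lymphopenia grading (grade 3–4 below 500
  cells/µL; normal 1000–4800), NLR, LMR with the 4.25 prognostic
  threshold, and the linear-quadratic aberration yield c + αD + βD².
- **A seeded synthetic-data generator** — log-normal inter-individual
  variability and observation noise (or negative-binomial counts) around
  the mechanistic trajectories, including macaque-like total-body-
  irradiation fixtures with ground truth attached.

## Worked example

Simulate the two-phase neutrophil course, summarise it, and recover its
parameters from noisy observations:

```r
library(leucokin)

late <- friberg_params(C0 = 5000, mtt = 3, kcirc = 0.25, gamma = 0.08)
wc   <- whole_course_params(late, spike = 0.2, bm_surviving = 0.03)
traj <- simulate_whole_course(wc, seq(0, 90, by = 0.25))
nadir_and_recovery(traj, baseline = 5000)
#> # A tibble: 1 × 6
#>   nadir nadir_fraction nadir_day recovery_day plateau plateau_reached
#>   <dbl>          <dbl>     <dbl>        <dbl>   <dbl> <lgl>
#> 1  369.         0.0738      14.5         29.2   5012. TRUE
```

The nadir is 7.4% of baseline at Day 14.5, the count is back to 90% of
baseline at Day 29.2, and the curve has settled at 5012 cells/µL (within
1% of baseline) by Day 90.

```r
fx  <- make_macaque_like_fixture("neutrophil", seed = 1, sigma_log = 0.1)
fit <- estimate_parameters(
  fx$data, "whole_course",
  free  = list(kcirc = c(0.05, 1), gamma = c(0.02, 0.5), mtt = c(1, 10)),
  fixed = list(C0 = 5000, n_transit = 3, spike = 0.2, bm_surviving = 0.03,
               ramp_start = 1, ramp_end = 14, ramp_shape = "linear"))
tidy(fit)
#> # A tibble: 3 × 2
#>   term  estimate
#>   <chr>    <dbl>
#> 1 kcirc   0.242
#> 2 gamma   0.0917
#> 3 mtt     3.39
```

With 10% multiplicative noise on 25 sampling days, the clearance rate,
feedback exponent and mean transit time come back within 15% of the
generating values (0.25, 0.08, 3).

The recirculation model answers "how fast does the blood pool refill from
the lymphoid organs?":

```r
p  <- rodent_recirc_params()
tr <- simulate_recirculation(
  p, seq(0, 200, by = 1),
  events = tibble::tibble(time = 25, compartment = "blood",
                          surviving_fraction = 0))
recovery_time(tr, "blood", threshold = 0.8, search_from = 26)
#> [1] 45
```

After the blood compartment is emptied at 25 min, recruitment from the
spleen and other lymphoid organs brings it back above 80% of its initial
level by 45 min.

See `vignettes/leucocyte-kinetics.Rmd` for the models, their assumptions
and the package's numerical choices.

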
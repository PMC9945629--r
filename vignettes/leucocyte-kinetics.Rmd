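---
title: "Modelling leucocyte kinetics after irradiation with leucokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling leucocyte kinetics after irradiation with leucokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leucokin)
```

`leucokin` models how white-blood-cell counts fall and recover after
radiation exposure. This vignette describes the models, the parameters that
matter and their defaults, the synthetic data the package generates, and
the numerical and design choices behind them.

## The lymphocyte recirculation model

Naïve lymphocytes continually exchange between the blood and the secondary
lymphoid organs (SLOs: spleen, lymph nodes). Because only a few percent of
the body's lymphocytes are in the blood at any moment, the blood pool can
refill rapidly from the organ reservoirs after an acute loss. We model this
with a closed linear compartmental system in *star topology*: every organ
exchanges cells only through the blood,

$$\frac{dx_b}{dt} = \sum_i \frac{x_i}{\tau_i} - \frac{x_b}{\tau_b},
\qquad
\frac{dx_i}{dt} = q_i \frac{x_b}{\tau_b} - \frac{x_i}{\tau_i},$$

where $\tau$ are mean residence times (minutes) and $q_i$ is the fraction
of blood outflow routed to organ $i$. Star topology is standard
recirculation physiology and makes calibration a closed-form balance
solve: given steady-state organ fractions $\pi$ and residence times, the
balance $\pi_i/\tau_i = q_i\,\pi_b/\tau_b$ yields every $q_i$, and one
organ may leave its residence time free to be solved from
$\sum_i q_i = 1$.

```{r}
tidy(rodent_recirc_params())
```

**Defaults and a feasibility constraint.** The rodent calibration uses the
published steady-state distribution (blood 4.15%, spleen 33.21%, other SLO
58.08%, others 4.56%) with spleen residence 150 min and other-SLO residence
600 min, consistent with reported transit times (more than 2 h in spleen,
about 10 h in lymph nodes). The blood residence time is not published; it
is bounded above by the flux balance, since the blood must turn over fast
enough to supply every organ:
$\tau_b \le \pi_b / \sum_i \pi_i/\tau_i \approx 13$ min for these
fractions. We use $\tau_b = 10$ min — a short per-pass blood transit is
physiologically expected — and expose it in `rodent_recirc_params()`. The
sub-minute lung/liver transit is folded into the blood compartment: it is
far below the minute resolution of this module. The "others" residence
time absorbs the remaining routing fraction (about 47 min at the
defaults).

Depletion experiments multiply a compartment by a surviving fraction
between integration segments (`apply_depletion()`, or `events =` in
`simulate_recirculation()`); the state reported at an event time is the
post-event state. With the defaults, zeroing the blood pool at 25 min
returns it above 80% of its initial level within about 45 min — recruitment
from the SLO reservoirs, whose own levels decline gradually.

## Myeloid models with homeostatic feedback

Marrow output maintains circulating counts against continuous loss.
Homeostasis is modelled as a power-law negative feedback of the
circulating count $C$ on the proliferating pool's turnover rate:

$$f(C) = \left(\frac{C_0}{C}\right)^{\gamma}, \qquad k = k_0\, f(C),$$

with set point $C_0$ and control coefficient $\gamma \ge 0$ ($\gamma = 0$
is open loop). Three structures share this loop:

* **Friberg-type transit model** (`friberg_params()`,
  `simulate_friberg()`): a proliferating compartment, `n_transit`
  (default 3) maturation compartments, and a circulating compartment with
  elimination rate `kcirc`. We tie the transit rate to the mean transit
  time as $k_{tr} = (n+1)/MTT$ and set the steady-state proliferation rate
  equal to $k_{tr}$, so every marrow pool holds $C_0 k_{circ}/k_{tr}$
  cells. This is the conventional transit parameterisation; the feedback
  parameters $(C_0, k_0, \gamma)$ are the quantities of scientific
  interest.
* **Bone-marrow/blood model** (`bm_blood_params()`): mitotic pool
  (proliferation rate $p$, maturation rate $k$), marrow transit pool
  (release rate $k_1$), circulating pool (loss rate $k_2$), with optional
  feedback exponents on proliferation (`gamma_p`) and release
  (`gamma_m`); both zero recovers the open-loop model. Steady state
  requires $p = k$ — anything else means unbounded exponential growth of
  the mitotic pool, and such configurations are rejected.
* **Monocyte chain** (`monocyte_params()`): precursors → marrow mature
  pool (release $k_1 = 1/1.6$ per day, i.e. 1.6 days in marrow) →
  classical → intermediate → non-classical monocytes. Disappearance rates
  default to blood residences of about 1, 4.3 and 7.4 days. The
  maturation rates $k_2, k_3$ are not separately published; we choose
  $k_2 = 0.002$, $k_3 = 1/43$ per day so that classical monocytes make up
  99% of blood monocytes at steady state, the published composition.

`calibrate_steady_state()` closes the flux-balance equations for any of
these structures and rejects inconsistent over-specification, naming the
violated balance. Every simulator starts from the calibrated steady state
unless perturbed, and equilibrium is preserved to high accuracy (drift
below $10^{-6}$ over 100 days in the test suite).

**Feedback floor.** As $C \to 0$ the factor $(C_0/C)^\gamma$ diverges; we
clamp $C$ at $10^{-3} C_0$ (configurable) inside the feedback and report
when the clamp engages. The floor only matters for depletions below 0.1%
of baseline.

## The two-phase whole-course neutropenia model

After total-body irradiation, neutrophil counts show a rise at Day 1, an
exponential decline to a nadir around 10% of baseline near Day 14, and a
sigmoid-like recovery with a slight rebound to a steady level. The
package's whole-course model (`whole_course_params()`,
`simulate_whole_course()`) produces this as one continuous trajectory from
the Friberg-type structure plus three radiation terms:

1. **Turnover shutdown and restoration ramp.** Radiation reduces the
   proliferating pool's turnover to zero at `ramp_start` (Day 1) and the
   rate is restored gradually, reaching its stable value at `ramp_end`
   (Day 14). The multiplier applies to the pool's whole turnover
   (proliferation and maturation out), so during shutdown the pool is
   frozen, the transit chain drains, and the circulating pool decays
   exponentially at `kcirc` — which is exactly the phenomenological
   early-phase model $C_t = C_0 e^{-kt}$ read mechanistically: no marrow
   input, clearance-driven kinetics. The default ramp is linear
   ("gradual" is all that is known about its shape); `smoothstep` is
   available, as are the degenerate shapes `none` (no radiation; the
   trajectory stays at steady state) and `off` (permanent shutdown; the
   late log-slope tends to $-k_{circ}$).
2. **Marrow kill.** The insult also depletes the marrow pools to
   `bm_surviving` (default 0.1) at `ramp_start`. Without this term the
   model cannot reproduce the observed curve: if the proliferating pool
   instead drained through a proliferation-only shutdown it would collapse
   by $\sim e^{-13}$ over the 13-day ramp and the feedback-driven regrowth
   would overshoot baseline several-fold, while a frozen full-sized pool
   with no kill restores production mid-ramp and cannot reach a 10% nadir.
   A surviving fraction of a few percent, consistent with the
   radiosensitivity of cycling precursors, yields the observed shape.
3. **Demargination spike.** The Day-1 rise is treated as an
   initial-condition offset, $C(\text{Day 1}) = C_0(1 + \text{spike})$
   (default 0.2), not modelled mechanistically.

The early-phase decline parameter and the late-phase clearance are left as
independent quantities (`exponential_phase_params()` vs `kcirc`); in the
mechanistic reading they coincide, and the fixture tests verify that an
early-phase exponential fit recovers `kcirc` to within 15%.

`nadir_and_recovery()` summarises any trajectory: nadir value/fraction/day,
first day back at a recovery threshold (default 90% of baseline), and the
plateau (mean over the final 10% of the grid, reported only when the
relative change across that window is below `plateau_tol`, default 1%).

## Phenomenological fitting and model selection

When no mechanism is assumed, recovery series are fitted with closed-form
growth families: `linear`, `exponential_decay`,
`exponential_rise_to_plateau`, `logistic`, `gompertz`. The exact inventory
of useful families is a modelling choice, so the registry is extensible
(`register_growth_family()`); families linear in their parameters (e.g.
polynomials) declare a design matrix and are solved exactly.

`fit_growth()` minimises the sum of squared residuals, optionally on the
log scale (`log_scale`), using Levenberg–Marquardt from 10 deterministic
starts built from data-driven heuristics (range, first observation,
half-maximum crossing) with fixed multiplicative perturbations — no RNG, so
fits are reproducible by construction. Non-convergence of all starts is
reported in the `converged` flag, never silently.

Model selection (`select_model()`) uses the Gaussian-residual conventions
$AIC = n \ln(SSR/n) + 2p$ and $BIC = n \ln(SSR/n) + p\ln n$ (small-sample
AICc is computed alongside). Ties within $10^{-9}$ break to the model with
fewer parameters, then to input order — deterministic by construction.
`classify_recovery()` then answers the two scientific questions about the
winning curve: was a stable point reached within the observation window
(relative change of the fitted curve over the final 10% of the window
below 1% by default), and if so, does the plateau equal the pre-treatment
baseline within 10% (homeostasis restored) or not (altered)? With no
plateau the comparison is *indeterminate* — regulation may be disrupted,
or the window too short.

## Covariate screening

To ask whether a radiation parameter $d$ (e.g. dose in Gy) modulates
kinetics, `screen_variable()` uses the linear base model $C = C_0 + kt$:
stage 1 estimates $k_i$ per covariate level; stage 2 fits link families
$f(d) = k$ — constant (the no-covariate null), linear, power, exponential
— jointly across levels with per-level intercepts profiled out, and ranks
them by information criterion.

The default criterion here is **BIC**, not AIC, and this is deliberate:
for nested families differing by one parameter, AIC prefers the larger
family with probability $P(\chi^2_1 > 2) \approx 0.16$ even when the
covariate has no effect, regardless of sample size — a 1-in-6
false-selection rate is a poor default for a screening tool. BIC's $\ln n$
penalty makes null selection consistent while costing little power against
real dose effects at realistic effect sizes. AIC and MSE remain available
(`criterion =`).

## Estimation, individual-based fits and validation

`estimate_parameters()` fits the mechanistic models by bounded least
squares — on log counts by default (`ssr_log`), since blood counts are
positive with roughly multiplicative error — optimising in log-parameter
space with `L-BFGS-B` from a deterministic low-discrepancy lattice of
starts. Identifiability is guarded (more free parameters than observations
is an error) and bound-hitting estimates are flagged.

`fit_individuals()` implements two-stage individual-based estimation: each
subject fitted separately, then the parameter distribution summarised
(mean, SD, CV over converged subjects, failures counted). A pooled fit is
included for contrast; with heterogeneous subgroups the pooled estimate
can sit far from the individual-based mean, which is the reason to prefer
the two-stage view when individual series exist. Full nonlinear
mixed-effects machinery is intentionally out of scope — the two-stage
approach matches the framing above at desk scale.

`goodness_of_fit()` operationalises "are the residuals random" with a
Wald–Wolfowitz runs test on residual signs plus the lag-1 residual
autocorrelation, both with approximate normal p-values (at least 8
residuals required; same-signed residuals yield a flagged degenerate
report, not an error). No specific test being canonical here, the runs
test was chosen as the simplest assumption-free check of sign patterns.
`cross_validate()` partitions data into complementary subsets and
evaluates held-out RMSE: contiguous blocked-time folds for single
trajectories (random folds would leak temporal structure) and
leave-one-subject-out for cohorts. Comparing held-out RMSE between a
parsimonious and an over-parameterised family exposes overfitting.

## Synthetic data and the macaque-like fixtures

`simulation_design()` + `generate_dataset()` produce seeded cohorts:
per-subject parameters drawn log-normally around the design truth with
stated CVs (the truth is the median and the CV is exact by construction,
$sd_{\log} = \sqrt{\ln(1+CV^2)}$), trajectories simulated by the kinetic
modules, and observation noise applied — multiplicative log-normal with
$\sigma = 0.1$ by default (blood counts are positive and heteroscedastic;
no noise model is published for the motivating data, so 0.1 is a stated
stand-in), or negative-binomial for integer-count realism. The seed is
mandatory and output is byte-reproducible. Ground truth (per-subject
parameters, noiseless curves, true nadir/recovery summaries) travels with
the dataset so any estimator can be scored against it.

`make_macaque_like_fixture()` encodes two reference scenarios emulating
total-body irradiation in macaques:

* **neutrophil** — whole-course model with $C_0 = 5000$ cells/µL,
  $MTT = 3$ d, $k_{circ} = 0.25$/d, $\gamma = 0.08$, spike 0.2, marrow
  survival 0.03, ramp Day 1 → 14; the noiseless curve has its nadir at
  7.4% of baseline on Day 14.5, is back at 90% of baseline by Day 29, and
  rebounds less than 25% above baseline before settling within 5% of
  baseline by Day 60. Sampling uses 25 days over 0–60.
* **lymphocyte** — feedback recovery after instantaneous depletion of all
  pools to 3% of baseline, with $C_0 = 2500$ cells/µL, $MTT = 30$ d,
  $k_{circ} = 0.06$/d, $\gamma = 0.10$: nadir 3% of baseline, a transient
  rebound of about 15% above baseline, and stable levels (within 5%)
  reached around Day 260, inside the expected 100–300 day window.

These constants are package choices tuned to the qualitative published
pattern; they are **not** fitted estimates from any study (the underlying
fit parameters were never published in usable form). What passing tests on
these fixtures shows is that the estimation machinery recovers known
ground truth under the stated noise — not that real macaque data would
yield these parameter values. Real data add features the generator omits:
irregular sampling, assay detection limits, inter-occasion variability,
and correlated physiology between lineages (the generator treats
populations as independently regulated, matching the framing assumption).

## Clinical metrics

`grade_lymphopenia()` grades counts against the two published cut points —
below 500 cells/µL is grade 3–4, 1000–4800 is the normal range — without
inventing intermediate sub-grades (the boundary is strict `< 500`; custom
bins can be supplied). `compute_nlr()` is neutrophils/lymphocytes.
`compute_lmr()` is **lymphocytes/monocytes** with the published threshold
4.25 classified as high at `>=`. The source literature is inconsistent
about the LMR direction — the ratio is sometimes written
monocyte/lymphocyte while the name and the "high LMR of 4.25 is
favourable" usage imply lymphocyte/monocyte. We implement the latter and
provide `invert = TRUE` for the other convention; this choice is
deliberate and documented rather than silent. `aberration_yield()`
evaluates the linear-quadratic chromosome-aberration dose response
$c + \alpha D + \beta D^2$; coefficients are user inputs (lymphocyte and
neutrophil sets differ, lymphocytes responding more steeply), with no
defaults pretending to be published values.

## Numerical choices

* ODE integration: `deSolve::lsoda` (stiff-capable), rtol $10^{-8}$, atol
  $10^{-10}$ scaled to the system size. Instantaneous events (depletions,
  the Day-1 insult) are applied between integration segments, never
  through the solver.
* Closed systems conserve total mass to better than $10^{-6}$ relative;
  the recirculation ODE matches the matrix-exponential closed form to
  $10^{-6}$.
* Optimisation: `L-BFGS-B` in log-parameter space (positivity for free),
  deterministic multi-starts; Levenberg–Marquardt for growth families.
* All stochastic procedures take explicit integer seeds; defaults are
  recorded in run logs (`run_command()` writes seed, package version,
  config hash and wall time).
* Problem sizes used by the test suite and the acceptance script — e.g.
  100-replicate selection studies at 40 observations per dose level, one
  whole-course fit at 25 sampling days, 20-subject cohorts — were chosen
  as the smallest designs at which the calibration properties are stable.

## Known limitations

* Cytokine dynamics (G-CSF and relatives) are implicit in the power-law
  feedback, not modelled explicitly.
* Chemotherapy-style drug-effect terms are absent; perturbations are
  radiation-shaped (shutdown/ramp, kill fractions, depletions).
* The recirculation module covers rodent-like calibrations; human organ
  fractions cannot be calibrated the same way without organ-size
  assumptions we do not make.
* Two-stage individual estimation understates shrinkage relative to full
  mixed-effects models when per-subject data are sparse.
* The whole-course structure is one defensible reading of a two-phase
  description; alternatives (e.g. a drained-pool shutdown) produce
  qualitatively different rebounds, which is itself a reason to fit and
  compare structures on real data.
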
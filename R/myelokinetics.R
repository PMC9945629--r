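# Semi-mechanistic myeloid cell kinetics: transit-compartment models of
# myelosuppression with power-law homeostatic feedback, and the two-phase
# whole-course model of radiation-induced neutropenia.
#
# Time unit: days. Counts: cells/uL.

#' Homeostatic feedback parameters
#'
#' The negative feedback of the circulating pool on proliferation:
#' \eqn{f(C) = (C_0/C)^\gamma}, so the proliferating-pool turnover rate is
#' \eqn{k = k_0 (C_0/C)^\gamma}. When the circulating pool falls below its
#' set point the turnover rate rises, driving recovery; at the set point
#' the factor is 1.
#'
#' @param C0 Circulating set point (cells/uL, > 0).
#' @param k0 Turnover rate of the proliferating pool at steady state
#'   (per day, > 0).
#' @param gamma Coefficient of homeostasis control (dimensionless, >= 0);
#'   0 switches the loop off.
#' @param floor_frac Relative floor applied to C before the power law to
#'   avoid the singularity as C -> 0; clamping is reported via a message.
#' @return A `feedback_params` object.
#' @export
feedback_params <- function(C0, k0 = 1, gamma = 0, floor_frac = 1e-3) {
  check_positive(C0, "C0"); check_positive(k0, "k0")
  check_number(gamma, "gamma", lower = 0)
  check_number(floor_frac, "floor_frac", lower = 0, upper = 1)
  structure(list(C0 = C0, k0 = k0, gamma = gamma, floor_frac = floor_frac),
            class = "feedback_params")
}

#' Evaluate the homeostatic feedback factor
#'
#' Returns \eqn{(C_0/C)^\gamma}; the instantaneous turnover rate is
#' `k0 * feedback_factor(C, fb)`. Non-positive C is clamped to
#' `floor_frac * C0` (and the clamp is reported) so the factor stays finite.
#'
#' @param C Circulating count(s), cells/uL.
#' @param fb A `feedback_params` object.
#' @param quiet Suppress the clamp message.
#' @return Dimensionless factor, vectorized over `C`.
#' @export
#' @examples
#' fb <- feedback_params(C0 = 5000, gamma = 1)
#' feedback_factor(2500, fb)  # 2
feedback_factor <- function(C, fb, quiet = FALSE) {
  stopifnot(inherits(fb, "feedback_params"))
  if (any(is.na(C))) abort("`C` contains NA/NaN.")
  floor_c <- fb$floor_frac * fb$C0
  if (any(C < floor_c) && !quiet) {
    inform(sprintf("feedback_factor: %d value(s) clamped to the floor %.4g (= %.0e * C0).",
                   sum(C < floor_c), floor_c, fb$floor_frac))
  }
  (fb$C0 / pmax(C, floor_c))^fb$gamma
}

# ---- steady-state calibration --------------------------------------------

#' Complete a mechanistic parameter set so that steady state is well defined
#'
#' Solves input = output for every compartment of the requested model
#' structure, returning pool set points consistent with the rates (and
#' checking user-supplied set points against the balance). Proliferating
#' pools are always balanced (proliferation rate equals maturation rate at
#' steady state with feedback factor 1); configurations implying unbounded
#' exponential growth are rejected.
#'
#' @param kind One of `"friberg"`, `"bm_blood"`, `"monocyte"`.
#' @param ... Rates and set points for the chosen structure; see
#'   [friberg_params()], [bm_blood_params()], [monocyte_params()].
#' @param setpoints Optional named vector of pool set points to verify
#'   against the computed balance (inconsistent over-specification errors,
#'   naming the violated balance equation).
#' @return The completed parameter object of the matching class.
#' @export
calibrate_steady_state <- function(kind = c("friberg", "bm_blood", "monocyte"),
                                   ..., setpoints = NULL) {
  kind <- match.arg(kind)
  obj <- switch(kind,
    friberg = friberg_params(...),
    bm_blood = bm_blood_params(...),
    monocyte = monocyte_params(...))
  if (!is.null(setpoints)) {
    ref <- obj$setpoints
    for (nm in names(setpoints)) {
      if (!nm %in% names(ref)) abort(sprintf("Unknown set point '%s'.", nm))
      if (abs(setpoints[[nm]] - ref[[nm]]) > 1e-6 * max(ref[[nm]], 1)) {
        abort(sprintf(
          "Inconsistent over-specification: supplied %s = %.6g violates the flux balance (input = output requires %s = %.6g).",
          nm, setpoints[[nm]], nm, ref[[nm]]))
      }
    }
  }
  obj
}

# ---- Friberg-type transit model ------------------------------------------

#' Friberg-type myelosuppression model parameters
#'
#' Proliferating compartment, `n_transit` maturation transit compartments,
#' and a circulating compartment. The transit rate is tied to the mean
#' transit time as \eqn{k_{tr} = (n+1)/MTT}; at steady state the
#' proliferation rate equals \eqn{k_{tr}} and every bone-marrow pool holds
#' \eqn{C_0 k_{circ}/k_{tr}} cells. The circulating pool feeds back on
#' proliferation via \eqn{(C_0/C)^\gamma}.
#'
#' @param C0 Circulating set point (cells/uL).
#' @param mtt Mean transit time through the maturation chain (days).
#' @param kcirc Circulating elimination rate (per day).
#' @param gamma Feedback exponent (>= 0).
#' @param n_transit Number of transit compartments (default 3).
#' @param floor_frac Feedback floor, see [feedback_params()].
#' @return A `friberg_params` object with derived `ktr` and steady-state
#'   `setpoints`.
#' @export
#' @examples
#' friberg_params(C0 = 5000, mtt = 3.5, kcirc = 0.2, gamma = 0.6)
friberg_params <- function(C0, mtt, kcirc, gamma = 0, n_transit = 3,
                           floor_frac = 1e-3) {
  check_positive(C0, "C0"); check_positive(mtt, "mtt"); check_positive(kcirc, "kcirc")
  check_number(gamma, "gamma", lower = 0)
  if (n_transit < 1 || n_transit != round(n_transit)) abort("`n_transit` must be an integer >= 1.")
  ktr <- (n_transit + 1) / mtt
  pool0 <- C0 * kcirc / ktr
  setpoints <- c(prolif = pool0,
                 setNames(rep(pool0, n_transit), paste0("transit", seq_len(n_transit))),
                 circulating = C0)
  structure(list(feedback = feedback_params(C0, k0 = ktr, gamma = gamma,
                                            floor_frac = floor_frac),
                 C0 = C0, mtt = mtt, kcirc = kcirc, gamma = gamma,
                 n_transit = as.integer(n_transit), ktr = ktr,
                 setpoints = setpoints),
            class = c("friberg_params", "leuco_params"))
}

# shared trajectory assembly
as_cell_trajectory <- function(sol, pools, params, circulating = "circulating") {
  if (any(!is.finite(sol))) {
    bad <- which(!is.finite(rowSums(sol[, -1, drop = FALSE])))[1]
    abort(sprintf("Solver produced a non-finite state at t = %.4g days (state: %s).",
                  sol[bad, 1],
                  paste(sprintf("%s=%.3g", pools, sol[bad, pools]), collapse = ", ")))
  }
  long <- as_tibble(as.data.frame(sol)) |>
    rename(time_days = "time") |>
    tidyr::pivot_longer(cols = all_of(pools), names_to = "compartment",
                        values_to = "value") |>
    mutate(compartment = factor(.data$compartment, levels = pools))
  structure(long, class = c("cell_trajectory", class(long)),
            params = params, circulating = circulating)
}

#' Extract the circulating series from a cell trajectory
#' @param traj A `cell_trajectory`.
#' @return Tibble with `time_days` and `value`.
#' @export
circulating_series <- function(traj) {
  stopifnot(inherits(traj, "cell_trajectory"))
  circ <- attr(traj, "circulating")
  out <- traj |>
    filter(.data$compartment == circ) |>
    select("time_days", "value")
  class(out) <- class(tibble())
  out
}

# integrate an ODE piecewise, applying instantaneous pool depletions
integrate_pools <- function(deriv, y0, t_grid, parms, depletions = NULL, atol_scale = 1) {
  ev_times <- if (is.null(depletions)) numeric(0) else unique(depletions$time)
  ev_times <- ev_times[ev_times > min(t_grid) & ev_times < max(t_grid)]
  times <- sort(unique(c(t_grid, ev_times)))
  # depletions at the initial time are applied to y0 directly
  if (!is.null(depletions)) {
    d0 <- depletions[depletions$time <= min(t_grid), , drop = FALSE]
    for (r in seq_len(nrow(d0))) {
      y0[d0$pools[[r]]] <- y0[d0$pools[[r]]] * d0$fraction[r]
    }
  }
  seg_bounds <- c(min(times), ev_times, max(times))
  state <- y0
  rows <- list()
  for (s in seq_len(length(seg_bounds) - 1L)) {
    seg <- times[times >= seg_bounds[s] & times <= seg_bounds[s + 1L]]
    sol <- deSolve::lsoda(y = state, times = seg, func = deriv, parms = parms,
                          rtol = 1e-8, atol = 1e-10 * atol_scale)
    keep <- if (s < length(seg_bounds) - 1L) sol[-nrow(sol), , drop = FALSE] else sol
    rows[[s]] <- keep
    state <- sol[nrow(sol), names(y0)]
    if (s < length(seg_bounds) - 1L) {
      dd <- depletions[depletions$time == seg_bounds[s + 1L], , drop = FALSE]
      for (r in seq_len(nrow(dd))) {
        state[dd$pools[[r]]] <- state[dd$pools[[r]]] * dd$fraction[r]
      }
    }
  }
  sol <- do.call(rbind, rows)
  sol[sol[, 1] %in% t_grid, , drop = FALSE]
}

# normalize the perturbation argument shared by the simulators
norm_perturbation <- function(perturbation, pool_names, circulating) {
  if (is.null(perturbation)) return(list(depletions = NULL, prolif_off = NULL))
  if (!is.list(perturbation)) abort("`perturbation` must be a list.")
  if (!is.null(perturbation$kind) || !is.null(perturbation$pool)) {
    perturbation <- list(perturbation)
  }
  deps <- list(); prolif_off <- NULL
  for (p in perturbation) {
    kind <- p$kind %||% "deplete_pool"
    if (kind == "deplete_pool") {
      pool <- p$pool %||% circulating
      pools <- if (identical(pool, "all")) pool_names else pool
      bad <- setdiff(pools, pool_names)
      if (length(bad)) abort(sprintf("Unknown pool(s) %s; valid: %s.",
                                     paste(bad, collapse = ", "),
                                     paste(pool_names, collapse = ", ")))
      frac <- p$fraction %||% abort("deplete_pool perturbation needs `fraction`.")
      check_number(frac, "fraction", 0, 1)
      deps[[length(deps) + 1L]] <- tibble(time = p$time %||% 0,
                                          pools = list(pools), fraction = frac)
    } else if (kind == "proliferation_off") {
      prolif_off <- c(p$from %||% 0, p$to %||% Inf)
    } else {
      abort(sprintf("Unknown perturbation kind '%s'.", kind))
    }
  }
  list(depletions = if (length(deps)) bind_rows(deps) else NULL,
       prolif_off = prolif_off)
}

#' Simulate the Friberg-type transit-compartment model
#'
#' Integrates proliferating -> transit chain -> circulating with
#' proliferation rate \eqn{k_{tr}(C_0/C)^\gamma}. Unperturbed from steady
#' state the trajectory is flat; after a depletion with `gamma > 0` the
#' circulating pool returns to its set point, typically with a transient
#' rebound above baseline.
#'
#' @param params A `friberg_params` object.
#' @param t_grid Strictly increasing grid in days.
#' @param perturbation Optional perturbation: either
#'   `list(kind = "deplete_pool", time, pool, fraction)` (pool may be a pool
#'   name, `"circulating"`, or `"all"`) or
#'   `list(kind = "proliferation_off", from, to)`; or a list of several.
#' @param init Optional named initial state; defaults to the steady state.
#' @return A `cell_trajectory` tibble (`time_days`, `compartment`, `value`).
#' @export
#' @examples
#' p <- friberg_params(C0 = 5000, mtt = 3.5, kcirc = 0.2, gamma = 0.4)
#' simulate_friberg(p, 0:60,
#'   perturbation = list(kind = "deplete_pool", pool = "all", fraction = 0.1))
simulate_friberg <- function(params, t_grid, perturbation = NULL, init = NULL) {
  stopifnot(inherits(params, "friberg_params"))
  check_increasing(t_grid)
  pools <- names(params$setpoints)
  y0 <- init %||% params$setpoints
  if (!setequal(names(y0), pools)) abort("`init` must name all pools.")
  y0 <- y0[pools]
  pert <- norm_perturbation(perturbation, pools, "circulating")
  fb <- params$feedback; ktr <- params$ktr; kcirc <- params$kcirc
  n <- params$n_transit
  off <- pert$prolif_off
  deriv <- function(t, y, parms) {
    m <- if (!is.null(off) && t >= off[1] && t <= off[2]) 0 else 1
    f <- feedback_factor(y[["circulating"]], fb, quiet = TRUE)
    dp <- ktr * y[[1]] * (m * f - 1)
    dtr <- ktr * (y[seq_len(n)] - y[1L + seq_len(n)])
    dc <- ktr * y[[n + 1L]] - kcirc * y[[n + 2L]]
    list(c(dp, dtr, dc))
  }
  sol <- integrate_pools(deriv, y0, t_grid, NULL, pert$depletions,
                         atol_scale = max(params$C0, 1))
  as_cell_trajectory(sol, pools, params)
}

# ---- bone-marrow / blood neutrophil model --------------------------------

#' Bone-marrow/blood neutrophil model parameters
#'
#' Three pools: mitotic precursors proliferating at rate `p`, a bone-marrow
#' transit (post-mitotic) pool entered at rate `k` and released into the
#' circulation at rate `k1`, and a circulating pool cleared at rate `k2`.
#' An optional negative feedback of the circulating count scales both the
#' proliferation rate (exponent `gamma_p`) and the bone-marrow release rate
#' (exponent `gamma_m`); both exponents 0 recovers the open-loop model.
#' Steady state requires `p = k` (otherwise the precursor pool would grow
#' or decay without bound), and pool set points follow from flux balance:
#' `k * P0 = k1 * T0 = k2 * C0`.
#'
#' @param C0 Circulating set point (cells/uL).
#' @param k Maturation (entry-into-transit) rate, per day; the steady-state
#'   proliferation rate equals `k`.
#' @param k1 Bone-marrow release rate, per day.
#' @param k2 Circulating loss rate (apoptosis/margination), per day.
#' @param gamma_p,gamma_m Feedback exponents on proliferation and release.
#' @param p Optional proliferation rate; if supplied it must equal `k`.
#' @param floor_frac Feedback floor.
#' @return A `bm_blood_params` object.
#' @export
bm_blood_params <- function(C0, k, k1, k2, gamma_p = 0, gamma_m = 0,
                            p = NULL, floor_frac = 1e-3) {
  check_positive(C0, "C0"); check_positive(k, "k")
  check_positive(k1, "k1"); check_positive(k2, "k2")
  check_number(gamma_p, "gamma_p", lower = 0)
  check_number(gamma_m, "gamma_m", lower = 0)
  if (!is.null(p) && abs(p - k) > 1e-12) {
    abort(sprintf(
      "Unbounded configuration rejected: steady state requires the proliferation rate p (%.4g) to equal the maturation rate k (%.4g); dP/dt = (p - k) P would otherwise grow or decay forever.",
      p, k))
  }
  setpoints <- c(mitotic = k2 * C0 / k, transit = k2 * C0 / k1, circulating = C0)
  structure(list(C0 = C0, p = k, k = k, k1 = k1, k2 = k2,
                 gamma_p = gamma_p, gamma_m = gamma_m,
                 feedback = feedback_params(C0, k0 = k, gamma = 1,
                                            floor_frac = floor_frac),
                 setpoints = setpoints),
            class = c("bm_blood_params", "leuco_params"))
}

#' Simulate the bone-marrow/blood neutrophil model
#'
#' @inheritParams simulate_friberg
#' @param params A `bm_blood_params` object.
#' @return A `cell_trajectory`.
#' @export
simulate_bm_blood <- function(params, t_grid, perturbation = NULL, init = NULL) {
  stopifnot(inherits(params, "bm_blood_params"))
  check_increasing(t_grid)
  pools <- names(params$setpoints)
  y0 <- init %||% params$setpoints
  y0 <- y0[pools]
  # guard: uncalibrated initial state must still satisfy flux balance checks
  pert <- norm_perturbation(perturbation, pools, "circulating")
  fb <- params$feedback
  off <- pert$prolif_off
  deriv <- function(t, y, parms) {
    m <- if (!is.null(off) && t >= off[1] && t <= off[2]) 0 else 1
    base <- (fb$C0 / pmax(y[["circulating"]], fb$floor_frac * fb$C0))
    fp <- base^params$gamma_p
    fm <- base^params$gamma_m
    dM <- params$p * fp * m * y[["mitotic"]] - params$k * y[["mitotic"]]
    dT <- params$k * y[["mitotic"]] - params$k1 * fm * y[["transit"]]
    dC <- params$k1 * fm * y[["transit"]] - params$k2 * y[["circulating"]]
    list(c(dM, dT, dC))
  }
  sol <- integrate_pools(deriv, y0, t_grid, NULL, pert$depletions,
                         atol_scale = max(params$C0, 1))
  as_cell_trajectory(sol, pools, params)
}

# ---- monocyte chain -------------------------------------------------------

#' Monocyte kinetics model parameters
#'
#' Five pools: bone-marrow precursors proliferating at rate `p` and maturing
#' at rate `k`; bone-marrow mature monocytes released into blood at rate
#' `k1`; circulating classical monocytes maturing into intermediate
#' monocytes at rate `k2` or disappearing at rate `d1`; intermediate
#' monocytes differentiating into long-lived non-classical monocytes at
#' rate `k3` or disappearing at `d2`; non-classical monocytes disappearing
#' at `d3`. Defaults use a bone-marrow residence of 1.6 days (`k1 = 1/1.6`),
#' blood residence of about 1, 4.3 and 7.4 days for the classical,
#' intermediate and non-classical pools, and `k2`, `k3` chosen so that the
#' classical subset makes up about 99% of blood monocytes at steady state.
#'
#' @param Cl0 Classical (circulating) monocyte set point, cells/uL.
#' @param k Precursor maturation rate (per day); steady-state proliferation
#'   rate equals `k`.
#' @param k1 Bone-marrow release rate (per day), default 1/1.6.
#' @param k2 Classical -> intermediate maturation rate (per day).
#' @param k3 Intermediate -> non-classical differentiation rate (per day).
#' @param d1,d2,d3 Disappearance rates of classical, intermediate and
#'   non-classical monocytes (per day).
#' @return A `monocyte_params` object with steady-state `setpoints`.
#' @export
#' @examples
#' p <- monocyte_params()
#' sp <- p$setpoints
#' sp[["classical"]] / (sp[["classical"]] + sp[["intermediate"]] + sp[["non_classical"]])
monocyte_params <- function(Cl0 = 400, k = 1, k1 = 1 / 1.6,
                            k2 = 0.002, k3 = 1 / 43,
                            d1 = 1, d2 = 1 / 4.3 - 1 / 43, d3 = 1 / 7.4) {
  for (nm in c("Cl0", "k", "k1", "k2", "k3", "d1", "d2", "d3")) {
    check_positive(get(nm), nm)
  }
  # flux balance: k*P0 = k1*M0 = (k2 + d1)*Cl0 ; k2*Cl0 = (k3 + d2)*I0 ;
  # k3*I0 = d3*N0
  influx <- (k2 + d1) * Cl0
  I0 <- k2 * Cl0 / (k3 + d2)
  N0 <- k3 * I0 / d3
  setpoints <- c(precursor = influx / k, bm_mature = influx / k1,
                 classical = Cl0, intermediate = I0, non_classical = N0)
  structure(list(Cl0 = Cl0, p = k, k = k, k1 = k1, k2 = k2, k3 = k3,
                 d1 = d1, d2 = d2, d3 = d3, setpoints = setpoints),
            class = c("monocyte_params", "leuco_params"))
}

#' Simulate the monocyte chain model
#'
#' @inheritParams simulate_friberg
#' @param params A `monocyte_params` object.
#' @return A `cell_trajectory`; the reported circulating series is the
#'   classical pool.
#' @export
simulate_monocytes <- function(params, t_grid, perturbation = NULL, init = NULL) {
  stopifnot(inherits(params, "monocyte_params"))
  check_increasing(t_grid)
  pools <- names(params$setpoints)
  y0 <- (init %||% params$setpoints)[pools]
  pert <- norm_perturbation(perturbation, pools, "classical")
  off <- pert$prolif_off
  deriv <- function(t, y, parms) {
    m <- if (!is.null(off) && t >= off[1] && t <= off[2]) 0 else 1
    dP <- params$p * m * y[["precursor"]] - params$k * y[["precursor"]]
    dM <- params$k * y[["precursor"]] - params$k1 * y[["bm_mature"]]
    dCl <- params$k1 * y[["bm_mature"]] - (params$k2 + params$d1) * y[["classical"]]
    dI <- params$k2 * y[["classical"]] - (params$k3 + params$d2) * y[["intermediate"]]
    dN <- params$k3 * y[["intermediate"]] - params$d3 * y[["non_classical"]]
    list(c(dP, dM, dCl, dI, dN))
  }
  sol <- integrate_pools(deriv, y0, t_grid, NULL, pert$depletions,
                         atol_scale = max(params$Cl0, 1))
  as_cell_trajectory(sol, pools, params, circulating = "classical")
}

# ---- two-phase whole-course radiation model ------------------------------

#' Two-phase whole-course radiation-induced neutropenia model parameters
#'
#' A single continuous model covering both phases of post-irradiation
#' neutrophil kinetics: radiation shuts proliferation off at `ramp_start`
#' (the multiplier on the proliferation input drops to 0), proliferation is
#' then restored gradually, reaching its stable rate at `ramp_end`; the
#' late phase is the Friberg-type feedback model, whose homeostatic loop
#' produces the sigmoid-like recovery with a slight rebound. The early
#' demargination rise is represented as an initial-condition offset: at
#' `ramp_start` the circulating pool is set to `C0 * (1 + spike)`. While
#' the transit chain is empty the circulating pool decays exponentially at
#' `kcirc`, which is the mechanistic reading of the early-phase
#' exponential-decline model.
#'
#' @param late A `friberg_params` object (the late-phase model; its `C0`
#'   is the pre-irradiation baseline).
#' @param ramp_start Day proliferation shuts off (default 1).
#' @param ramp_end Day proliferation reaches its stable rate (default 14).
#' @param ramp_shape `"linear"`, `"smoothstep"`, `"none"` (multiplier
#'   identically 1: no radiation), or `"off"` (identically 0: permanent
#'   shutdown).
#' @param spike Relative Day-`ramp_start` rise of the circulating pool
#'   above baseline (demargination), default 0.2.
#' @param bm_surviving Fraction of the proliferating and transit
#'   (bone-marrow) pools surviving the radiation insult at `ramp_start`
#'   (default 0.1); circulating cells are not directly killed — the
#'   circulating decline is driven by the loss of marrow input.
#' @param early Optional [exponential_phase_params()] describing the early
#'   phenomenological phase; defaults to `C0 * (1 + spike)` at the shut-off
#'   day declining at `kcirc` (the clearance-driven limit).
#' @return A `whole_course_params` object.
#' @export
whole_course_params <- function(late, ramp_start = 1, ramp_end = 14,
                                ramp_shape = c("linear", "smoothstep", "none", "off"),
                                spike = 0.2, bm_surviving = 0.1, early = NULL) {
  stopifnot(inherits(late, "friberg_params"))
  ramp_shape <- match.arg(ramp_shape)
  if (!(ramp_start < ramp_end)) abort("`ramp_start` must be < `ramp_end`.")
  check_number(spike, "spike", lower = 0)
  check_number(bm_surviving, "bm_surviving", lower = 0, upper = 1)
  early <- early %||% exponential_phase_params(C0 = late$C0 * (1 + spike),
                                               k = late$kcirc)
  structure(list(early = early, late = late, ramp_start = ramp_start,
                 ramp_end = ramp_end, ramp_shape = ramp_shape, spike = spike,
                 bm_surviving = bm_surviving),
            class = c("whole_course_params", "leuco_params"))
}

ramp_multiplier <- function(t, params) {
  rs <- params$ramp_start; re <- params$ramp_end
  switch(params$ramp_shape,
    none = rep(1, length(t)),
    off = ifelse(t < rs, 1, 0),
    linear = ifelse(t < rs, 1, pmin((t - rs) / (re - rs), 1)),
    smoothstep = {
      s <- pmin(pmax((t - rs) / (re - rs), 0), 1)
      ifelse(t < rs, 1, 3 * s^2 - 2 * s^3)
    })
}

#' Simulate the whole-course radiation-induced neutropenia model
#'
#' Proliferation input of the Friberg-type late model is multiplied by the
#' restoration ramp; at `ramp_start` the circulating pool receives the
#' demargination spike. The trajectory declines to a nadir near the end of
#' the ramp and then recovers, sigmoid-like with a slight rebound, to a
#' steady level near the baseline.
#'
#' @param params A `whole_course_params` object.
#' @param t_grid Strictly increasing grid in days (should cover the ramp).
#' @return A `cell_trajectory`.
#' @export
#' @examples
#' wc <- whole_course_params(friberg_params(5000, mtt = 3.5, kcirc = 0.25,
#'                                          gamma = 0.6))
#' traj <- simulate_whole_course(wc, seq(0, 60, by = 0.5))
simulate_whole_course <- function(params, t_grid) {
  stopifnot(inherits(params, "whole_course_params"))
  check_increasing(t_grid)
  late <- params$late
  pools <- names(late$setpoints)
  fb <- late$feedback; ktr <- late$ktr; kcirc <- late$kcirc; n <- late$n_transit
  # the ramp multiplies the turnover of the proliferating pool (its
  # proliferation AND maturation out): while output is shut off the pool is
  # frozen, the transit chain drains, and the circulating pool decays at
  # kcirc — the clearance-driven early phase
  deriv <- function(t, y, parms) {
    m <- ramp_multiplier(t, params)
    f <- feedback_factor(y[["circulating"]], fb, quiet = TRUE)
    dp <- m * ktr * y[[1]] * (f - 1)
    influx <- c(m * ktr * y[[1]], ktr * y[1L + seq_len(n - 1L)])
    dtr <- influx - ktr * y[1L + seq_len(n)]
    dc <- ktr * y[[n + 1L]] - kcirc * y[[n + 2L]]
    list(c(dp, dtr, dc))
  }
  rs <- params$ramp_start
  y0 <- late$setpoints
  if (params$ramp_shape == "none") {
    sol <- integrate_pools(deriv, y0, t_grid, NULL, NULL, atol_scale = late$C0)
    return(as_cell_trajectory(sol, pools, params))
  }
  times <- sort(unique(c(t_grid, rs, params$ramp_end)))
  times <- times[times >= min(t_grid) & times <= max(t_grid)]
  rows <- list()
  if (min(times) < rs) {
    pre <- times[times <= rs]
    if (length(pre) >= 2) {
      sol_pre <- deSolve::lsoda(y0, pre, deriv, NULL, rtol = 1e-8,
                                atol = 1e-10 * late$C0)
      rows[[1]] <- sol_pre[-nrow(sol_pre), , drop = FALSE]
    }
    y0 <- late$setpoints
  }
  # the insult at ramp_start: marrow pools reduced to the surviving
  # fraction, circulating demargination spike
  bm <- setdiff(pools, "circulating")
  y0[bm] <- y0[bm] * (params$bm_surviving %||% 1)
  y0[["circulating"]] <- late$C0 * (1 + params$spike)
  post <- times[times >= rs]
  if (length(post) < 2) abort("`t_grid` must extend beyond `ramp_start`.")
  sol_post <- deSolve::lsoda(y0, post, deriv, NULL, rtol = 1e-8,
                             atol = 1e-10 * late$C0)
  rows[[length(rows) + 1L]] <- sol_post
  sol <- do.call(rbind, rows)
  sol <- sol[sol[, 1] %in% t_grid, , drop = FALSE]
  as_cell_trajectory(sol, pools, params)
}

#' Nadir and recovery summary of a cell-count trajectory
#'
#' Computes the nadir (grid minimum), its time and fraction of baseline,
#' the first time after the nadir at which the count reaches
#' `recovery_threshold * baseline`, and the plateau level (mean over the
#' final 10% of the grid, reported only if the relative change across that
#' window is below `plateau_tol`).
#'
#' @param traj A `cell_trajectory`, or a data frame with `time_days` and
#'   `value` columns (the circulating series is used for trajectories).
#' @param baseline Baseline count (cells/uL, > 0).
#' @param recovery_threshold Fraction of baseline defining recovery
#'   (default 0.9).
#' @param plateau_tol Maximum relative change across the final 10% of the
#'   grid for the plateau to count as reached (default 0.01).
#' @return One-row tibble: `nadir`, `nadir_fraction`, `nadir_day`,
#'   `recovery_day` (NA if not reached), `plateau` (NA if none),
#'   `plateau_reached`.
#' @export
nadir_and_recovery <- function(traj, baseline, recovery_threshold = 0.9,
                               plateau_tol = 0.01) {
  check_positive(baseline, "baseline")
  check_number(recovery_threshold, "recovery_threshold", 0, 1)
  ser <- if (inherits(traj, "cell_trajectory")) circulating_series(traj)
         else as_tibble(traj)
  if (!all(c("time_days", "value") %in% names(ser)) || nrow(ser) == 0L) {
    abort("`traj` must be a cell_trajectory or have columns time_days, value (non-empty).")
  }
  ser <- arrange(ser, .data$time_days)
  i_nadir <- which.min(ser$value)
  nadir <- ser$value[i_nadir]
  nadir_day <- ser$time_days[i_nadir]
  after <- ser[ser$time_days >= nadir_day, ]
  hit <- after$time_days[after$value >= recovery_threshold * baseline]
  recovery_day <- if (length(hit)) min(hit) else NA_real_
  t_span <- diff(range(ser$time_days))
  tail_ser <- ser[ser$time_days >= max(ser$time_days) - 0.1 * t_span, ]
  rel_change <- abs(diff(range(tail_ser$value))) / max(mean(tail_ser$value), 1e-12)
  plateau_reached <- rel_change < plateau_tol
  tibble(nadir = nadir, nadir_fraction = nadir / baseline,
         nadir_day = nadir_day, recovery_day = recovery_day,
         plateau = if (plateau_reached) mean(tail_ser$value) else NA_real_,
         plateau_reached = plateau_reached)
}

#' @export
autoplot.cell_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_days, y = .data$value,
                                       colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (days)", y = "Cells/µL", colour = "Pool") +
    ggplot2::theme_minimal()
}
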
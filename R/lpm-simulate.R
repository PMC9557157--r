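#' Periodic activation waveform of an elastance chamber
#'
#' Squared-sine activation pulse: zero outside the activation window,
#' rising from 0 to 1 and back within it. The waveform is periodic with
#' period `60 / heart_rate` and may wrap across the cycle boundary (as
#' atrial activation does when it starts late in the cycle).
#'
#' @param t Time, s (vectorized). Non-negative.
#' @param heart_rate Heart rate, bpm.
#' @param chamber A [chamber_params()] object.
#' @return Activation value(s) in `[0, 1]`.
#' @export
activation_waveform <- function(t, heart_rate, chamber) {
  if (!is.numeric(heart_rate) || heart_rate <= 0) {
    stop("heart_rate must be positive")
  }
  period <- 60 / heart_rate
  phase <- (t / period) %% 1
  tau <- (phase - chamber$activation_onset) %% 1
  act <- ifelse(tau < chamber$activation_duration,
                sin(pi * tau / chamber$activation_duration)^2, 0)
  act
}

#' Instantaneous chamber pressure from the elastance model
#'
#' Blends the active isovolumic pressure, scaled by the activation
#' waveform, with the passive exponential EDPVR (see [chamber_params()]
#' for the functional forms).
#'
#' @inheritParams activation_waveform
#' @param volume Chamber volume, mL. Must be positive.
#' @return Pressure, mmHg.
#' @export
chamber_pressure <- function(volume, t, chamber, heart_rate) {
  if (any(volume <= 0)) stop("chamber volume must be positive")
  act <- activation_waveform(t, heart_rate, chamber)
  p_active <- act * chamber$peak_isovolumic_pressure *
    (volume - chamber$unstressed_volume) /
    (chamber$reference_volume - chamber$unstressed_volume)
  p_passive <- chamber$edpvr_alpha *
    (exp(chamber$edpvr_exponent * (volume - chamber$unstressed_volume)) - 1)
  p_active + p_passive
}

#' Flow through the continuous-flow pump at a given pressure head
#'
#' Solves the static quadratic head-flow characteristic
#' \eqn{H(Q) = h_0 + h_1 Q + h_2 Q^2} for the flow at which the pump
#' head equals `outlet_pressure - inlet_pressure`. Retrograde flow is
#' permitted (no clipping at zero), matching continuous-flow pump
#' physics when the differential pressure exceeds the shut-off head.
#'
#' @param inlet_pressure Pressure at the pump inlet (ventricle), mmHg.
#' @param outlet_pressure Pressure at the pump outlet (aorta), mmHg.
#' @param pump A [pump_params()] object.
#' @return Flow, L/min.
#' @export
pump_flow <- function(inlet_pressure, outlet_pressure, pump) {
  h <- pump$head_coeffs
  dp <- outlet_pressure - inlet_pressure
  if (abs(h[3]) < 1e-12) {
    return((dp - h[1]) / h[2])
  }
  disc <- h[2]^2 - 4 * h[3] * (h[1] - dp)
  if (any(disc < 0)) {
    stop(sprintf(
      "pump head-flow law has no real solution (max discriminant %.3g); head %.3g mmHg outside the characteristic",
      max(-disc), max(dp)))
  }
  # root on the monotonically decreasing branch (Q above the vertex)
  (-h[2] - sqrt(disc)) / (2 * h[3])
}

# Closure-compiled right-hand side of the closed-loop circulation ODE:
# all parameters are unpacked to locals once so the integrator's inner
# loop avoids list traversal. State is the volume (mL) of: la, lv, ra,
# rv, sa, sv, pa, pvn. Flows in mL/s. The algebra is identical to the
# exported chamber_pressure()/pump_flow() (asserted by the test suite).
.lpm_make_derivs <- function(params) {
  period <- 60 / params$heart_rate
  ch <- params$chambers
  unpack <- function(c) {
    list(pi_ = c$peak_isovolumic_pressure, v0 = c$unstressed_volume,
         al = c$edpvr_alpha, be = c$edpvr_exponent,
         on = c$activation_onset, du = c$activation_duration,
         sc = 1 / (c$reference_volume - c$unstressed_volume))
  }
  la <- unpack(ch$la); lv <- unpack(ch$lv)
  ra <- unpack(ch$ra); rv <- unpack(ch$rv)
  vs <- params$vessels
  sa_v0 <- vs$sa$unstressed_volume; sa_c <- vs$sa$compliance
  sv_v0 <- vs$sv$unstressed_volume; sv_c <- vs$sv$compliance
  pa_v0 <- vs$pa$unstressed_volume; pa_c <- vs$pa$compliance
  pv_v0 <- vs$pvn$unstressed_volume; pv_c <- vs$pvn$compliance
  r_sys <- vs$sa$resistance; r_ret <- vs$sv$resistance
  r_pul <- vs$pa$resistance; r_pvla <- vs$pvn$resistance
  rr <- params$valve_resistances
  r_mv <- rr[["mv"]]; r_av <- rr[["av"]]
  r_tv <- rr[["tv"]]; r_pv <- rr[["pv"]]
  hc <- params$pump$head_coeffs
  h1 <- hc[1]; h2 <- hc[2]; h3 <- hc[3]

  cpress <- function(v, phase, c) {
    tau <- (phase - c$on) %% 1
    e <- if (tau < c$du) sin(pi * tau / c$du)^2 else 0
    e * c$pi_ * (v - c$v0) * c$sc + c$al * (expm1(c$be * (v - c$v0)))
  }
  function(t, y, parms) {
    phase <- (t / period) %% 1
    p_la <- cpress(y[1], phase, la)
    p_lv <- cpress(y[2], phase, lv)
    p_ra <- cpress(y[3], phase, ra)
    p_rv <- cpress(y[4], phase, rv)
    p_sa <- (y[5] - sa_v0) / sa_c
    p_sv <- (y[6] - sv_v0) / sv_c
    p_pa <- (y[7] - pa_v0) / pa_c
    p_pvn <- (y[8] - pv_v0) / pv_c

    q_mv <- max(0, p_la - p_lv) / r_mv
    q_av <- max(0, p_lv - p_sa) / r_av
    q_tv <- max(0, p_ra - p_rv) / r_tv
    q_pv <- max(0, p_rv - p_pa) / r_pv
    dp <- p_sa - p_lv
    disc <- h2 * h2 - 4 * h3 * (h1 - dp)
    if (disc < 0) stop("pump head outside the head-flow characteristic")
    q_pump <- (-h2 - sqrt(disc)) / (2 * h3) * (1000 / 60)
    q_sys <- (p_sa - p_sv) / r_sys
    q_ret <- (p_sv - p_ra) / r_ret
    q_pul <- (p_pa - p_pvn) / r_pul
    q_pvla <- (p_pvn - p_la) / r_pvla

    list(c(q_pvla - q_mv,
           q_mv - q_av - q_pump,
           q_ret - q_tv,
           q_tv - q_pv,
           q_av + q_pump - q_sys,
           q_sys - q_ret,
           q_pv - q_pul,
           q_pul - q_pvla))
  }
}

# Resting state: every node at the mean circulatory pressure. This is
# how the MCP parameter fixes the total (stressed) blood volume.
.lpm_initial_state <- function(params) {
  mcp <- params$mean_circulatory_pressure
  vs <- params$vessels
  ch <- params$chambers
  chamber_v <- function(c) {
    c$unstressed_volume + log(mcp / c$edpvr_alpha + 1) / c$edpvr_exponent
  }
  c(
    la = chamber_v(ch$la), lv = chamber_v(ch$lv),
    ra = chamber_v(ch$ra), rv = chamber_v(ch$rv),
    sa = vs$sa$unstressed_volume + mcp * vs$sa$compliance,
    sv = vs$sv$unstressed_volume + mcp * vs$sv$compliance,
    pa = vs$pa$unstressed_volume + mcp * vs$pa$compliance,
    pvn = vs$pvn$unstressed_volume + mcp * vs$pvn$compliance
  )
}

# Vectorized reconstruction of pressures and flows from a state matrix
# (rows = time points), used to assemble the output waveforms.
.lpm_outputs <- function(times, states, params) {
  p <- params
  ch <- p$chambers
  vs <- p$vessels
  rv_ <- p$valve_resistances
  p_la <- chamber_pressure(states[, "la"], times, ch$la, p$heart_rate)
  p_lv <- chamber_pressure(states[, "lv"], times, ch$lv, p$heart_rate)
  p_ra <- chamber_pressure(states[, "ra"], times, ch$ra, p$heart_rate)
  p_rv <- chamber_pressure(states[, "rv"], times, ch$rv, p$heart_rate)
  p_sa <- (states[, "sa"] - vs$sa$unstressed_volume) / vs$sa$compliance
  p_sv <- (states[, "sv"] - vs$sv$unstressed_volume) / vs$sv$compliance
  p_pa <- (states[, "pa"] - vs$pa$unstressed_volume) / vs$pa$compliance
  p_pvn <- (states[, "pvn"] - vs$pvn$unstressed_volume) / vs$pvn$compliance
  data.frame(
    time_s = times,
    v_la = states[, "la"], v_lv = states[, "lv"],
    v_ra = states[, "ra"], v_rv = states[, "rv"],
    v_sa = states[, "sa"], v_sv = states[, "sv"],
    v_pa = states[, "pa"], v_pvn = states[, "pvn"],
    p_la = p_la, p_lv = p_lv, p_ra = p_ra, p_rv = p_rv,
    p_sa = p_sa, p_sv = p_sv, p_pa = p_pa, p_pvn = p_pvn,
    q_mv = pmax(0, p_la - p_lv) / rv_[["mv"]],
    q_av = pmax(0, p_lv - p_sa) / rv_[["av"]],
    q_tv = pmax(0, p_ra - p_rv) / rv_[["tv"]],
    q_pv = pmax(0, p_rv - p_pa) / rv_[["pv"]],
    q_pump = pump_flow(p_lv, p_sa, p$pump) * 1000 / 60,
    q_pvla = (p_pvn - p_la) / vs$pvn$resistance
  )
}

#' Simulate the closed-loop circulation to periodic steady state
#'
#' Integrates the eight-compartment volume ODE with a fixed-step
#' fourth-order Runge-Kutta scheme (750 steps per cardiac cycle by
#' default), cycle by cycle, until the state at the cycle boundary
#' changes by less than `tol` relative between consecutive cycles. The
#' returned waveforms cover the final converged cycle at full
#' resolution.
#'
#' @param params A [scenario_params()] object.
#' @param n_cycles Maximum number of cycles to integrate (at least 1).
#' @param dt Time step, s. Defaults to `cycle length / 750`; must divide
#'   the cycle into at least 750 steps.
#' @param tol Relative cycle-to-cycle convergence tolerance. The
#'   default 0.001 converges well inside the 0.5% periodicity
#'   contract, tight enough that cycle integrals balance to under 1%.
#' @return A `waveform_set`: a data frame with one row per time sample
#'   (`time_s`, chamber/vessel volumes `v_*` in mL, pressures `p_*` in
#'   mmHg, flows `q_*` in mL/s) and attributes `heart_rate`,
#'   `cycles_run`, `residual`.
#' @export
simulate_lpm <- function(params, n_cycles = 40, dt = NULL, tol = 0.001) {
  stopifnot(inherits(params, "scenario_params"), n_cycles >= 1)
  period <- 60 / params$heart_rate
  if (is.null(dt)) dt <- period / 750
  n_steps <- round(period / dt)
  if (n_steps < 750) {
    stop("dt must divide the cycle length into at least 750 steps")
  }
  times <- seq(0, period, length.out = n_steps + 1)
  state <- .lpm_initial_state(params)
  derivs <- .lpm_make_derivs(params)
  residual <- Inf
  cycles_run <- 0
  sol <- NULL
  for (cycle in seq_len(n_cycles)) {
    sol <- deSolve::rk4(y = state, times = times, func = derivs,
                        parms = NULL)
    new_state <- sol[nrow(sol), -1]
    names(new_state) <- names(state)
    residual <- max(abs(new_state - state) / pmax(abs(state), 1))
    state <- new_state
    cycles_run <- cycle
    if (cycle > 1 && residual < tol) break
  }
  if (residual >= tol) {
    stop(sprintf(
      "circulation failed to reach periodic steady state in %d cycles (cycle-to-cycle residual %.3g, tolerance %.3g)",
      n_cycles, residual, tol))
  }
  out <- .lpm_outputs(sol[, 1], sol[, -1, drop = FALSE], params)
  structure(out,
            class = c("waveform_set", "data.frame"),
            heart_rate = params$heart_rate,
            cycles_run = cycles_run,
            residual = residual)
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf(
    "<waveform_set> %d samples over one cycle at %g bpm (converged in %d cycles, residual %.2g)\n",
    nrow(x), attr(x, "heart_rate"), attr(x, "cycles_run"),
    attr(x, "residual")))
  invisible(x)
}

#' Mitral E/A ratio from a mitral inflow waveform
#'
#' Detects the early-diastolic (E) and atrial-contraction (A) peaks of
#' the mitral valve flow over one cycle and returns their ratio. With
#' absent atrial contraction (atrial fibrillation) only a single
#' diastolic peak exists and a "no A wave" sentinel is returned.
#'
#' @param mitral_flow Either a `waveform_set` (its `q_mv` column is
#'   used) or a numeric vector of mitral flow over one cycle, mL/s.
#' @param min_prominence Peaks smaller than this fraction of the global
#'   maximum are ignored (default 0.05).
#' @return A list with elements `ratio` (E/A, `NA` if no A wave),
#'   `e_peak` and `a_peak` (mL/s), and `no_a_wave` (logical).
#' @export
compute_ea_ratio <- function(mitral_flow, min_prominence = 0.05) {
  q <- if (inherits(mitral_flow, "waveform_set")) {
    mitral_flow$q_mv
  } else {
    as.numeric(mitral_flow)
  }
  if (max(q) <= 0) stop("no diastolic mitral flow in the waveform")
  pk <- pracma::findpeaks(q, minpeakheight = min_prominence * max(q),
                          zero = "+")
  if (is.null(pk)) {
    # monotone-edge degenerate case: treat the global maximum as E
    pk <- matrix(c(max(q), which.max(q), NA, NA), nrow = 1)
  }
  pk <- pk[order(pk[, 2]), , drop = FALSE]
  if (nrow(pk) < 2) {
    return(list(ratio = NA_real_, e_peak = pk[1, 1], a_peak = NA_real_,
                no_a_wave = TRUE))
  }
  e <- pk[1, 1]
  a <- pk[nrow(pk), 1]
  list(ratio = e / a, e_peak = e, a_peak = a, no_a_wave = FALSE)
}

#' Cycle-level hemodynamic summary
#'
#' Summarizes one converged cycle: mean arterial pressure, cardiac
#' output (aortic valve plus pump), pump flow, chamber stroke volumes
#' and the mitral E/A ratio.
#'
#' @param w A `waveform_set` from [simulate_lpm()].
#' @return A list of class `hemo_summary` with entries
#'   `mean_arterial_pressure_mmHg`, `cardiac_output_l_min`,
#'   `pump_flow_l_min`, `mitral_stroke_volume_ml`,
#'   `lv_stroke_volume_ml`, `la_stroke_volume_ml`, `ea_ratio`,
#'   `heart_rate_bpm`.
#' @export
summarize_hemodynamics <- function(w) {
  if (!inherits(w, "waveform_set")) stop("input must be a waveform_set")
  state_cols <- grep("^v_", names(w), value = TRUE)
  first <- as.numeric(w[1, state_cols])
  last <- as.numeric(w[nrow(w), state_cols])
  if (max(abs(last - first) / pmax(abs(first), 1)) > 0.02) {
    stop("waveform is not cyclic; summarize only converged cycles")
  }
  t <- w$time_s
  cyc_mean <- function(x) pracma::trapz(t, x) / (t[length(t)] - t[1])
  ea <- compute_ea_ratio(w)
  structure(list(
    mean_arterial_pressure_mmHg = cyc_mean(w$p_sa),
    cardiac_output_l_min = cyc_mean(w$q_av + w$q_pump) * 60 / 1000,
    pump_flow_l_min = cyc_mean(w$q_pump) * 60 / 1000,
    mitral_stroke_volume_ml = pracma::trapz(t, w$q_mv),
    lv_stroke_volume_ml = max(w$v_lv) - min(w$v_lv),
    la_stroke_volume_ml = max(w$v_la) - min(w$v_la),
    ea_ratio = ea$ratio,
    no_a_wave = ea$no_a_wave,
    heart_rate_bpm = attr(w, "heart_rate")
  ), class = "hemo_summary")
}

#' @export
print.hemo_summary <- function(x, ...) {
  cat("<hemo_summary>\n")
  cat(sprintf("  MAP: %.1f mmHg | pump flow: %.2f L/min | CO: %.2f L/min\n",
              x$mean_arterial_pressure_mmHg, x$pump_flow_l_min,
              x$cardiac_output_l_min))
  cat(sprintf("  mitral SV: %.1f mL | LV SV: %.1f mL | E/A: %s\n",
              x$mitral_stroke_volume_ml, x$lv_stroke_volume_ml,
              if (x$no_a_wave) "no A wave" else sprintf("%.2f", x$ea_ratio)))
  invisible(x)
}
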
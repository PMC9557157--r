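#' Elastance chamber parameters
#'
#' Parameter set for one heart chamber modelled with a time-varying
#' elastance: the instantaneous pressure blends an active component,
#' scaled by the periodic activation waveform, with the passive
#' exponential end-diastolic pressure-volume relation (EDPVR).
#'
#' The active component is
#' \deqn{P_{act}(V,t) = e(t)\, P_{iso} \frac{V - V_0}{V_{ref} - V_0}}
#' so that at full activation (\eqn{e = 1}) and the reference volume
#' \eqn{V_{ref}} the active pressure equals `peak_isovolumic_pressure`.
#' The passive component is
#' \deqn{P_{pass}(V) = \alpha\,(e^{\beta (V - V_0)} - 1).}
#'
#' @param peak_isovolumic_pressure Peak isovolumic pressure at the
#'   reference volume, mmHg. Zero deactivates active contraction.
#' @param unstressed_volume Volume at zero passive pressure \eqn{V_0}, mL.
#' @param edpvr_alpha EDPVR scale \eqn{\alpha}, mmHg.
#' @param edpvr_exponent EDPVR exponent \eqn{\beta}, 1/mL.
#' @param activation_onset Onset of activation as a fraction of the
#'   cardiac cycle in `[0, 1)`.
#' @param activation_duration Duration of activation as a fraction of the
#'   cycle in `(0, 1]`. Activation may wrap across the cycle boundary.
#' @param reference_volume Volume \eqn{V_{ref}} at which the fully
#'   activated chamber develops `peak_isovolumic_pressure`, mL.
#' @return An object of class `chamber_params`.
#' @export
chamber_params <- function(peak_isovolumic_pressure,
                           unstressed_volume,
                           edpvr_alpha,
                           edpvr_exponent,
                           activation_onset,
                           activation_duration,
                           reference_volume) {
  stopifnot(
    is.numeric(peak_isovolumic_pressure), peak_isovolumic_pressure >= 0,
    edpvr_alpha > 0, edpvr_exponent > 0,
    activation_onset >= 0, activation_onset < 1,
    activation_duration > 0, activation_duration <= 1,
    reference_volume > unstressed_volume
  )
  structure(
    list(
      peak_isovolumic_pressure = peak_isovolumic_pressure,
      unstressed_volume = unstressed_volume,
      edpvr_alpha = edpvr_alpha,
      edpvr_exponent = edpvr_exponent,
      activation_onset = activation_onset,
      activation_duration = activation_duration,
      reference_volume = reference_volume
    ),
    class = "chamber_params"
  )
}

#' Windkessel vessel parameters
#'
#' A compliant vessel node. `resistance` is the resistance of the
#' vessel's outflow branch (e.g. the systemic arterioles for the
#' systemic arterial node, the venous return path for the venous node).
#'
#' @param resistance Outflow resistance, mmHg s/mL. Must be positive.
#' @param compliance Compliance, mL/mmHg. Must be positive.
#' @param unstressed_volume Volume at zero pressure, mL.
#' @return An object of class `vessel_params`.
#' @export
vessel_params <- function(resistance, compliance, unstressed_volume) {
  stopifnot(resistance > 0, compliance > 0, unstressed_volume >= 0)
  structure(
    list(
      resistance = resistance,
      compliance = compliance,
      unstressed_volume = unstressed_volume
    ),
    class = "vessel_params"
  )
}

#' Continuous-flow pump parameters
#'
#' Static head-flow characteristic of a centrifugal assist device at a
#' fixed operating speed, \eqn{H(Q) = h_0 + h_1 Q + h_2 Q^2} with the
#' head \eqn{H} in mmHg and the flow \eqn{Q} in L/min. The curve must be
#' monotonically decreasing over the operating range 0-10 L/min.
#'
#' @param speed Pump speed the coefficients refer to, rpm.
#' @param head_coeffs Numeric length-3 vector `c(h0, h1, h2)` in units of
#'   mmHg, mmHg min/L and mmHg min^2/L^2.
#' @return An object of class `pump_params`.
#' @export
pump_params <- function(speed, head_coeffs) {
  stopifnot(length(head_coeffs) == 3, is.numeric(head_coeffs), speed > 0)
  h <- as.numeric(head_coeffs)
  dH <- h[2] + 2 * h[3] * c(0, 10)
  if (any(dH >= 0)) {
    stop("pump head must decrease monotonically with flow over 0-10 L/min")
  }
  structure(list(speed = speed, head_coeffs = h), class = "pump_params")
}

#' Full closed-loop scenario parameter set
#'
#' Bundles the four elastance chambers, the four Windkessel vessel
#' nodes, the valve resistances, the pump characteristic, the mean
#' circulatory pressure (which sets the total stressed blood volume),
#' and the scenario flags.
#'
#' @param heart_rate Heart rate, bpm.
#' @param chambers Named list with `chamber_params` entries `la`, `lv`,
#'   `ra`, `rv`.
#' @param vessels Named list with `vessel_params` entries `sa` (systemic
#'   arteries), `sv` (systemic veins), `pa` (pulmonary arteries), `pvn`
#'   (pulmonary veins).
#' @param valve_resistances Named numeric vector with entries `mv`, `av`,
#'   `tv`, `pv` (mitral, aortic, tricuspid, pulmonary), mmHg s/mL.
#' @param pump `pump_params` for the assist device.
#' @param mean_circulatory_pressure Equilibrium pressure of the stopped
#'   circulation, mmHg; determines the total stressed volume via the
#'   summed compliances.
#' @param af_flag `TRUE` for atrial fibrillation (no active atrial
#'   contraction).
#' @param laao_flag `TRUE` when the left atrial appendage is occluded in
#'   the downstream flow domain; does not alter the circulation model.
#' @return An object of class `scenario_params`.
#' @export
scenario_params <- function(heart_rate, chambers, vessels, valve_resistances,
                            pump, mean_circulatory_pressure,
                            af_flag = FALSE, laao_flag = FALSE) {
  stopifnot(
    heart_rate > 0,
    all(c("la", "lv", "ra", "rv") %in% names(chambers)),
    all(c("sa", "sv", "pa", "pvn") %in% names(vessels)),
    all(c("mv", "av", "tv", "pv") %in% names(valve_resistances)),
    inherits(pump, "pump_params"),
    mean_circulatory_pressure > 0
  )
  for (ch in chambers) stopifnot(inherits(ch, "chamber_params"))
  for (vs in vessels) stopifnot(inherits(vs, "vessel_params"))
  structure(
    list(
      heart_rate = heart_rate,
      chambers = chambers,
      vessels = vessels,
      valve_resistances = valve_resistances,
      pump = pump,
      mean_circulatory_pressure = mean_circulatory_pressure,
      af_flag = af_flag,
      laao_flag = laao_flag
    ),
    class = "scenario_params"
  )
}

#' Committed baseline parameter set
#'
#' The package's default closed-loop configuration: a chronic
#' heart-failure circulation before the assist-device scenario
#' adjustments of [apply_scenario()] are applied. The baseline was
#' calibrated once, by deterministic least squares on pump head scale,
#' systemic resistance, venous compliance, left-atrial contraction
#' strength and ventricular EDPVR exponent, such that the adjusted
#' sinus-rhythm LVAD scenario reproduces the clinical operating point:
#' cycle-mean pump flow 5.2 L/min, mean arterial pressure 83.8 mmHg and
#' mitral E/A ratio 1.2 at 80 bpm.
#'
#' @return A `scenario_params` object.
#' @export
default_scenario_params <- function() {
  scenario_params(
    heart_rate = 70,
    chambers = list(
      la = chamber_params(
        peak_isovolumic_pressure = .lpm_calibrated$la_peak_pressure,
        unstressed_volume = 110, edpvr_alpha = 4.2, edpvr_exponent = 0.020,
        activation_onset = 0.83, activation_duration = 0.17,
        reference_volume = 190
      ),
      lv = chamber_params(
        peak_isovolumic_pressure = 100,
        unstressed_volume = 120, edpvr_alpha = 0.92,
        edpvr_exponent = .lpm_calibrated$lv_edpvr_exponent,
        activation_onset = 0, activation_duration = 0.40,
        reference_volume = 340
      ),
      ra = chamber_params(
        peak_isovolumic_pressure = 8,
        unstressed_volume = 60, edpvr_alpha = 0.30, edpvr_exponent = 0.020,
        activation_onset = 0.83, activation_duration = 0.17,
        reference_volume = 130
      ),
      rv = chamber_params(
        peak_isovolumic_pressure = 80,
        unstressed_volume = 90, edpvr_alpha = 0.35, edpvr_exponent = 0.015,
        activation_onset = 0, activation_duration = 0.40,
        reference_volume = 260
      )
    ),
    vessels = list(
      sa = vessel_params(
        resistance = .lpm_calibrated$systemic_resistance,
        compliance = 1.4, unstressed_volume = 600
      ),
      sv = vessel_params(
        resistance = 0.030,
        compliance = .lpm_calibrated$venous_compliance,
        unstressed_volume = 2400
      ),
      pa = vessel_params(resistance = 0.070, compliance = 4.5,
                         unstressed_volume = 120),
      pvn = vessel_params(resistance = 0.040, compliance = 9.0,
                          unstressed_volume = 300)
    ),
    valve_resistances = c(mv = 0.004, av = 0.006, tv = 0.003, pv = 0.003),
    pump = pump_params(
      speed = 2700,
      head_coeffs = .lpm_calibrated$pump_head_scale * c(100, -3.2, -0.05)
    ),
    mean_circulatory_pressure = 12.5,
    af_flag = FALSE,
    laao_flag = FALSE
  )
}

#' Apply a named scenario to a baseline parameter set
#'
#' For the LVAD-patient scenarios the five standard adjustments are
#' applied to the baseline: heart rate set to 80 bpm, LV peak isovolumic
#' pressure reduced from 100 to 80 mmHg, RV peak isovolumic pressure
#' reduced from 80 to 50 mmHg, mean circulatory pressure reduced from
#' 12.5 to 10 mmHg, systemic arterial resistance reduced by 6%, and the
#' ventricular EDPVR constant alpha increased by 70%. For the atrial
#' fibrillation scenarios, additionally, active left atrial contraction
#' is deactivated so the atrium behaves purely passively. The occlusion
#' flag only marks the downstream flow-domain variant; it does not alter
#' the circulation parameters.
#'
#' @param baseline A `scenario_params` object (see
#'   [default_scenario_params()]).
#' @param scenario_name One of `"SR-LAA"`, `"SR-LAAO"`, `"AF-LAA"`,
#'   `"AF-LAAO"`, `"baseline"`.
#' @return A `scenario_params` object with the adjustments applied.
#' @export
apply_scenario <- function(baseline, scenario_name) {
  stopifnot(inherits(baseline, "scenario_params"))
  valid <- c("SR-LAA", "SR-LAAO", "AF-LAA", "AF-LAAO", "baseline")
  if (!scenario_name %in% valid) {
    stop("unknown scenario name '", scenario_name, "'; expected one of ",
         paste(valid, collapse = ", "))
  }
  if (scenario_name == "baseline") return(baseline)
  p <- baseline
  p$heart_rate <- 80
  p$chambers$lv$peak_isovolumic_pressure <-
    baseline$chambers$lv$peak_isovolumic_pressure * 80 / 100
  p$chambers$rv$peak_isovolumic_pressure <-
    baseline$chambers$rv$peak_isovolumic_pressure * 50 / 80
  p$mean_circulatory_pressure <-
    baseline$mean_circulatory_pressure * 10 / 12.5
  p$vessels$sa$resistance <- baseline$vessels$sa$resistance * 0.94
  p$chambers$lv$edpvr_alpha <- baseline$chambers$lv$edpvr_alpha * 1.70
  if (startsWith(scenario_name, "AF")) {
    p$chambers$la$peak_isovolumic_pressure <- 0
    p$af_flag <- TRUE
  } else {
    p$af_flag <- FALSE
  }
  p$laao_flag <- endsWith(scenario_name, "LAAO")
  p
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("<scenario_params>\n")
  cat(sprintf("  heart rate: %g bpm | MCP: %g mmHg | AF: %s | LAAO: %s\n",
              x$heart_rate, x$mean_circulatory_pressure,
              x$af_flag, x$laao_flag))
  cat(sprintf("  LV peak iso-volumic pressure: %g mmHg (alpha %.3g mmHg)\n",
              x$chambers$lv$peak_isovolumic_pressure,
              x$chambers$lv$edpvr_alpha))
  cat(sprintf("  systemic resistance: %.4g mmHg s/mL | pump speed: %g rpm\n",
              x$vessels$sa$resistance, x$pump$speed))
  invisible(x)
}
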
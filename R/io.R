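#' Write circulation waveforms as CSV
#'
#' One row per time sample, header `time_s,<signal>`; volumes in mL,
#' pressures in mmHg, flows in mL/s.
#'
#' @param w A `waveform_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveforms_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform_set"))
  utils::write.csv(as.data.frame(w), path, row.names = FALSE)
  invisible(path)
}

#' Read circulation waveforms from CSV
#'
#' @param path File written by [write_waveforms_csv()].
#' @return A `waveform_set` (one cycle; the heart rate is recovered
#'   from the time base).
#' @export
read_waveforms_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot("time_s" %in% names(d))
  period <- d$time_s[nrow(d)] - d$time_s[1]
  structure(d, class = c("waveform_set", "data.frame"),
            heart_rate = 60 / period, cycles_run = NA_integer_,
            residual = NA_real_)
}

#' Write a flux program as CSV
#'
#' @param flux A `flux_program`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flux_csv <- function(flux, path) {
  stopifnot(inherits(flux, "flux_program"))
  utils::write.csv(as.data.frame(flux), path, row.names = FALSE)
  invisible(path)
}

# scenario_params <-> plain nested list with unit-suffixed keys
.chamber_to_list <- function(c) {
  list(peak_isovolumic_pressure_mmHg = c$peak_isovolumic_pressure,
       unstressed_volume_ml = c$unstressed_volume,
       edpvr_alpha_mmHg = c$edpvr_alpha,
       edpvr_exponent_per_ml = c$edpvr_exponent,
       activation_onset_fraction = c$activation_onset,
       activation_duration_fraction = c$activation_duration,
       reference_volume_ml = c$reference_volume)
}
.chamber_from_list <- function(l) {
  chamber_params(l$peak_isovolumic_pressure_mmHg, l$unstressed_volume_ml,
                 l$edpvr_alpha_mmHg, l$edpvr_exponent_per_ml,
                 l$activation_onset_fraction, l$activation_duration_fraction,
                 l$reference_volume_ml)
}
.vessel_to_list <- function(v) {
  list(resistance_mmHg_s_per_ml = v$resistance,
       compliance_ml_per_mmHg = v$compliance,
       unstressed_volume_ml = v$unstressed_volume)
}
.vessel_from_list <- function(l) {
  vessel_params(l$resistance_mmHg_s_per_ml, l$compliance_ml_per_mmHg,
                l$unstressed_volume_ml)
}

#' Write a scenario parameter set as YAML
#'
#' All keys carry explicit unit suffixes (e.g.
#' `resistance_mmHg_s_per_ml`).
#'
#' @param params A `scenario_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_yaml <- function(params, path) {
  stopifnot(inherits(params, "scenario_params"))
  out <- list(
    heart_rate_bpm = params$heart_rate,
    mean_circulatory_pressure_mmHg = params$mean_circulatory_pressure,
    af = params$af_flag, laao = params$laao_flag,
    chambers = lapply(params$chambers, .chamber_to_list),
    vessels = lapply(params$vessels, .vessel_to_list),
    valve_resistances_mmHg_s_per_ml = as.list(params$valve_resistances),
    pump = list(speed_rpm = params$pump$speed,
                head_coeffs = as.list(params$pump$head_coeffs))
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read a scenario parameter set from YAML
#'
#' @param path File written by [write_scenario_yaml()].
#' @return A `scenario_params` object.
#' @export
read_scenario_yaml <- function(path) {
  l <- yaml::read_yaml(path)
  scenario_params(
    heart_rate = l$heart_rate_bpm,
    chambers = lapply(l$chambers, .chamber_from_list),
    vessels = lapply(l$vessels, .vessel_from_list),
    valve_resistances = unlist(l$valve_resistances_mmHg_s_per_ml),
    pump = pump_params(l$pump$speed_rpm, unlist(l$pump$head_coeffs)),
    mean_circulatory_pressure = l$mean_circulatory_pressure_mmHg,
    af_flag = isTRUE(l$af), laao_flag = isTRUE(l$laao)
  )
}
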
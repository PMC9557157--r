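# Frozen results of the one-off baseline calibration (deterministic least
# squares on the adjusted sinus-rhythm LVAD scenario; see the methods
# vignette). These constants parameterize default_scenario_params().
.lpm_calibrated <- list(
  pump_head_scale     = 0.5913673,
  systemic_resistance = 0.9679350,
  venous_compliance   = 60,
  la_peak_pressure    = 16.13575,
  lv_edpvr_exponent   = 0.012
)
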
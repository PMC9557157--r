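test_that("activation waveform is periodic, vanishes at onset and peaks at 1", {
  lv <- default_scenario_params()$chambers$lv
  la <- default_scenario_params()$chambers$la
  hr <- 80
  period <- 60 / hr
  t <- seq(0, period, length.out = 101)
  expect_equal(activation_waveform(t, hr, lv),
               activation_waveform(t + period, hr, lv))
  expect_equal(activation_waveform(lv$activation_onset * period, hr, lv), 0)
  # atrial activation wraps across the cycle boundary
  expect_gt(activation_waveform(0.99 * period, hr, la), 0)
  t_dense <- seq(0, period, length.out = 10001)
  expect_equal(max(activation_waveform(t_dense, hr, lv)), 1,
               tolerance = 1e-6)
  expect_error(activation_waveform(0.1, -10, lv), "positive")

  # quadrature refinement oracle: the cycle integral at 750 points
  # matches the 7500-point quadrature
  q_of <- function(n) {
    tt <- seq(0, period, length.out = n + 1)
    pracma::trapz(tt, activation_waveform(tt, hr, lv))
  }
  expect_equal(q_of(750), q_of(7500), tolerance = 1e-4)
})

test_that("chamber pressure decomposes into active and passive elastance parts", {
  p <- apply_scenario(default_scenario_params(), "SR-LAA")
  lv <- p$chambers$lv
  hr <- p$heart_rate
  period <- 60 / hr
  t_full <- (lv$activation_onset + lv$activation_duration / 2) * period
  passive <- function(v) {
    lv$edpvr_alpha * (exp(lv$edpvr_exponent * (v - lv$unstressed_volume)) - 1)
  }
  # at full activation and the reference volume the active term equals
  # the adjusted LV peak isovolumic pressure (100 -> 80 mmHg)
  active_term <- chamber_pressure(lv$reference_volume, t_full, lv, hr) -
    passive(lv$reference_volume)
  expect_equal(active_term, 80, tolerance = 1e-9)
  # passive pressure vanishes at the unstressed volume, zero activation
  t_rest <- 0.7 * period
  expect_equal(chamber_pressure(lv$unstressed_volume, t_rest, lv, hr), 0)
  # closed-form EDPVR at V0 + 50 mL
  expect_equal(chamber_pressure(lv$unstressed_volume + 50, t_rest, lv, hr),
               passive(lv$unstressed_volume + 50))
  expect_error(chamber_pressure(-1, 0, lv, hr), "positive")
})

test_that("pump flow solves the head-flow law: shut-off, bisection oracle, retrograde", {
  pump <- default_scenario_params()$pump
  h <- pump$head_coeffs
  # shut-off point: head equal to the zero-flow head gives zero flow
  expect_equal(pump_flow(0, h[1], pump), 0, tolerance = 1e-12)
  # bisection oracle on the head function
  for (dp in c(10, 30, 47, 55)) {
    q_ref <- uniroot(function(q) h[1] + h[2] * q + h[3] * q^2 - dp,
                     c(-50, 60), tol = 1e-13)$root
    expect_equal(pump_flow(0, dp, pump), q_ref, tolerance = 1e-9)
  }
  # retrograde flow above the shut-off head is allowed, not clipped
  expect_lt(pump_flow(0, h[1] + 5, pump), 0)
  # monotonicity guard in the constructor
  expect_error(pump_params(2700, c(100, 2, -0.1)), "monotonically")
})

test_that("scenario adjustments follow the LVAD-patient deltas", {
  base <- default_scenario_params()
  expect_identical(apply_scenario(base, "baseline"), base)
  sr <- apply_scenario(base, "SR-LAA")
  expect_equal(sr$heart_rate, 80)
  expect_equal(sr$chambers$lv$peak_isovolumic_pressure, 80)
  expect_equal(sr$chambers$rv$peak_isovolumic_pressure, 50)
  expect_equal(sr$mean_circulatory_pressure, 10)
  expect_equal(sr$vessels$sa$resistance, base$vessels$sa$resistance * 0.94)
  expect_equal(sr$chambers$lv$edpvr_alpha, base$chambers$lv$edpvr_alpha * 1.70)
  expect_false(sr$af_flag); expect_false(sr$laao_flag)
  expect_true(apply_scenario(base, "SR-LAAO")$laao_flag)
  # AF: left atrial active contraction fully deactivated
  af <- apply_scenario(base, "AF-LAA")
  la <- af$chambers$la
  tt <- seq(0, 0.75, length.out = 40)
  passive <- la$edpvr_alpha * (exp(la$edpvr_exponent * 60) - 1)
  expect_equal(chamber_pressure(la$unstressed_volume + 60, tt, la, 80),
               rep(passive, 40))
  expect_error(apply_scenario(base, "nonsense"), "unknown scenario")
})

test_that("converged circulation conserves volume and respects the valve diodes", {
  w <- sr_waveforms()
  vol_cols <- grep("^v_", names(w), value = TRUE)
  total <- rowSums(as.data.frame(w)[, vol_cols])
  expect_lt(max(abs(total - total[1])) / total[1], 0.001)
  expect_true(all(w$q_mv >= 0))
  expect_true(all(w$q_av >= 0))
  expect_true(all(w$q_tv >= 0))
  # mitral flow identically zero whenever LV pressure exceeds LA pressure
  expect_true(all(w$q_mv[w$p_lv > w$p_la] == 0))
  # and in particular throughout mid-systole
  sys <- w$time_s > 0.05 & w$time_s < 0.25
  expect_true(all(w$q_mv[sys] == 0))
  # cyclic: first and last samples agree
  drift <- abs(as.numeric(w[nrow(w), vol_cols]) - as.numeric(w[1, vol_cols]))
  expect_lt(max(drift / as.numeric(w[1, vol_cols])), 0.005)
  # conservation oracle: cardiac output equals mitral stroke volume x HR
  s <- summarize_hemodynamics(w)
  expect_equal(s$cardiac_output_l_min,
               s$mitral_stroke_volume_ml * s$heart_rate_bpm / 1000,
               tolerance = 0.01)
})

test_that("inactive chambers with a null pump sit in static equilibrium", {
  base <- default_scenario_params()
  p <- base
  for (nm in names(p$chambers)) p$chambers[[nm]]$peak_isovolumic_pressure <- 0
  p$pump <- pump_params(2700, c(0, -1, -0.01))
  w <- simulate_lpm(p, n_cycles = 3)
  expect_lt(max(abs(w$q_mv), abs(w$q_av), abs(w$q_tv), abs(w$q_pv),
                abs(w$q_pump)), 1e-9)
  expect_lt(max(abs(w$v_lv - w$v_lv[1])), 1e-9)
})

test_that("E/A detection: symmetric peaks, calibrated SR, AF sentinel", {
  tt <- seq(0, 1, length.out = 751)
  two_peaks <- exp(-((tt - 0.3) / 0.05)^2) + exp(-((tt - 0.7) / 0.05)^2)
  expect_equal(compute_ea_ratio(two_peaks)$ratio, 1.0, tolerance = 1e-6)
  sr <- compute_ea_ratio(sr_waveforms())
  expect_false(sr$no_a_wave)
  expect_gt(sr$e_peak, sr$a_peak)
  af <- compute_ea_ratio(af_waveforms())
  expect_true(af$no_a_wave)
  expect_true(is.na(af$ratio))
  expect_error(compute_ea_ratio(rep(0, 100)), "no diastolic")
})

test_that("AF removes the active atrial stroke and reduces mitral filling", {
  s_sr <- summarize_hemodynamics(sr_waveforms())
  s_af <- summarize_hemodynamics(af_waveforms())
  expect_lt(s_af$la_stroke_volume_ml, s_sr$la_stroke_volume_ml)
  expect_lte(s_af$mitral_stroke_volume_ml, s_sr$mitral_stroke_volume_ml)
})

test_that("E/A falls monotonically as the ventricular EDPVR alpha rises", {
  base <- default_scenario_params()
  eas <- vapply(c(0.5, 1, 1.5), function(f) {
    b <- base
    b$chambers$lv$edpvr_alpha <- base$chambers$lv$edpvr_alpha * f
    summarize_hemodynamics(
      simulate_lpm(apply_scenario(b, "SR-LAA")))$ea_ratio
  }, numeric(1))
  expect_true(all(diff(eas) < 0))
})

test_that("halving the time step leaves the cycle-mean pump flow unchanged to 0.2%", {
  p <- apply_scenario(default_scenario_params(), "SR-LAA")
  s1 <- summarize_hemodynamics(sr_waveforms())
  s2 <- summarize_hemodynamics(simulate_lpm(p, dt = (60 / 80) / 1500))
  expect_lt(abs(s2$pump_flow_l_min - s1$pump_flow_l_min) /
              s1$pump_flow_l_min, 0.002)
  expect_error(simulate_lpm(p, dt = 0.01), "at least 750")
})

test_that("compiled ODE right-hand side matches the public elastance and pump laws", {
  p <- apply_scenario(default_scenario_params(), "SR-LAA")
  derivs <- laaoflow:::.lpm_make_derivs(p)
  y0 <- laaoflow:::.lpm_initial_state(p)
  for (t in c(0.05, 0.31, 0.6)) {
    y <- y0 * (1 + 0.03 * sin(seq_along(y0) + t))
    got <- derivs(t, y, NULL)[[1]]
    pr <- c(
      la = chamber_pressure(y[["la"]], t, p$chambers$la, p$heart_rate),
      lv = chamber_pressure(y[["lv"]], t, p$chambers$lv, p$heart_rate),
      ra = chamber_pressure(y[["ra"]], t, p$chambers$ra, p$heart_rate),
      rv = chamber_pressure(y[["rv"]], t, p$chambers$rv, p$heart_rate),
      sa = (y[["sa"]] - p$vessels$sa$unstressed_volume) / p$vessels$sa$compliance,
      sv = (y[["sv"]] - p$vessels$sv$unstressed_volume) / p$vessels$sv$compliance,
      pa = (y[["pa"]] - p$vessels$pa$unstressed_volume) / p$vessels$pa$compliance,
      pvn = (y[["pvn"]] - p$vessels$pvn$unstressed_volume) / p$vessels$pvn$compliance
    )
    r <- p$valve_resistances
    q_mv <- max(0, pr[["la"]] - pr[["lv"]]) / r[["mv"]]
    q_av <- max(0, pr[["lv"]] - pr[["sa"]]) / r[["av"]]
    q_tv <- max(0, pr[["ra"]] - pr[["rv"]]) / r[["tv"]]
    q_pv <- max(0, pr[["rv"]] - pr[["pa"]]) / r[["pv"]]
    q_pump <- pump_flow(pr[["lv"]], pr[["sa"]], p$pump) * 1000 / 60
    q_sys <- (pr[["sa"]] - pr[["sv"]]) / p$vessels$sa$resistance
    q_ret <- (pr[["sv"]] - pr[["ra"]]) / p$vessels$sv$resistance
    q_pul <- (pr[["pa"]] - pr[["pvn"]]) / p$vessels$pa$resistance
    q_pvla <- (pr[["pvn"]] - pr[["la"]]) / p$vessels$pvn$resistance
    want <- c(q_pvla - q_mv, q_mv - q_av - q_pump, q_ret - q_tv,
              q_tv - q_pv, q_av + q_pump - q_sys, q_sys - q_ret,
              q_pv - q_pul, q_pul - q_pvla)
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
})

test_that("hemodynamic summary rejects non-cyclic input and averages constants", {
  w <- sr_waveforms()
  const <- as.data.frame(w)
  const$p_sa <- 90
  const_w <- structure(const, class = class(w),
                       heart_rate = attr(w, "heart_rate"),
                       cycles_run = 1L, residual = 0)
  expect_equal(summarize_hemodynamics(const_w)$mean_arterial_pressure_mmHg, 90)
  bad <- as.data.frame(w)
  bad$v_lv[nrow(bad)] <- bad$v_lv[nrow(bad)] * 1.2
  bad_w <- structure(bad, class = class(w), heart_rate = 80)
  expect_error(summarize_hemodynamics(bad_w), "not cyclic")
})

test_that("waveform CSV and scenario YAML round-trips preserve the model", {
  w <- sr_waveforms()
  f <- tempfile(fileext = ".csv")
  write_waveforms_csv(w, f)
  w2 <- read_waveforms_csv(f)
  expect_equal(as.data.frame(w2), as.data.frame(w), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(w2, "heart_rate"), 80, tolerance = 1e-6)

  p <- apply_scenario(default_scenario_params(), "AF-LAAO")
  fy <- tempfile(fileext = ".yaml")
  write_scenario_yaml(p, fy)
  p2 <- read_scenario_yaml(fy)
  expect_equal(p2$chambers, p$chambers, tolerance = 1e-9)
  expect_equal(p2$vessels, p$vessels, tolerance = 1e-9)
  expect_equal(p2$pump$head_coeffs, p$pump$head_coeffs, tolerance = 1e-9)
  expect_true(p2$af_flag); expect_true(p2$laao_flag)
  unlink(c(f, fy))
})
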
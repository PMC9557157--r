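# Shared, lazily computed fixtures (memoized for the whole test run).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Converged calibrated waveforms of the two rhythms.
sr_waveforms <- function() {
  fixture("sr_waves",
          simulate_lpm(apply_scenario(default_scenario_params(), "SR-LAA")))
}
af_waveforms <- function() {
  fixture("af_waves",
          simulate_lpm(apply_scenario(default_scenario_params(), "AF-LAA")))
}

# Low-Reynolds straight-channel solve used by the Poiseuille oracles:
# width 5 mm, 20 cells across, mean velocity 5 mm/s, run to steady state.
poiseuille_field <- function() {
  fixture("poiseuille", {
    ch <- channel_domain(width = 5, length = 40, grid_spacing = 0.25)
    fp <- constant_flux_program(ch, q_ml_s = 0.25, period = 1, n = 11)
    solve_flow(ch, fp, n_cycles = 6, n_init_cycles = 2, dt = 0.0025,
               store_per_cycle = 10)
  })
}

# Default four-scenario experiment (the study conditions); used by the
# acceptance properties.
four_scenario_reports <- function() {
  fixture("four_reports", run_four_scenarios(quiet = TRUE))
}

# Hand-built flow_field with prescribed staggered velocities: one
# stored instant per entry of u_list/v_list, `per_cycle` instants per
# cycle of length `period`, starting at t = period / per_cycle.
synthetic_field <- function(domain, u_list, v_list, per_cycle,
                            period = 1, n_init_cycles = 0) {
  n <- length(u_list)
  stopifnot(length(v_list) == n, n %% per_cycle == 0)
  structure(list(
    u = u_list, v = v_list,
    times = period * seq_len(n) / per_cycle,
    residuals = data.frame(time_s = numeric(0),
                           continuity_max_div = numeric(0),
                           x_momentum = numeric(0),
                           y_momentum = numeric(0)),
    dt = period / per_cycle, period = period,
    n_cycles = n %/% per_cycle + n_init_cycles,
    n_init_cycles = n_init_cycles, store_per_cycle = per_cycle,
    stored_per_cycle = per_cycle, domain = domain, fluid = fluid_props()
  ), class = "flow_field")
}

# Synthetic field spanning `cycles` cycles, every stored instant equal
# to the staggered pair (U, V).
steady_synthetic_field <- function(domain, U, V, cycles = 1,
                                   per_cycle = 10, period = 1) {
  n <- cycles * per_cycle
  synthetic_field(domain, rep(list(U), n), rep(list(V), n),
                  per_cycle = per_cycle, period = period)
}

# Zero staggered arrays for a domain.
zero_uv <- function(domain) {
  nx <- domain$dims[["nx"]]; ny <- domain$dims[["ny"]]
  list(u = matrix(0, nx + 1, ny), v = matrix(0, nx, ny + 1))
}

# Independent plain-loop time-averaged-speed/stagnation computation
# (the enumeration oracle for the vectorized metrics).
enumerate_stagnation <- function(field, domain, threshold_mm_s, idx) {
  nx <- domain$dims[["nx"]]; ny <- domain$dims[["ny"]]
  out <- 0
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      if (domain$label[i, j] == 0L) next
      sp <- 0
      for (k in idx) {
        uc <- 0.5 * (field$u[[k]][i, j] + field$u[[k]][i + 1, j])
        vc <- 0.5 * (field$v[[k]][i, j] + field$v[[k]][i, j + 1])
        sp <- sp + sqrt(uc^2 + vc^2)
      }
      if (sp / length(idx) < threshold_mm_s * 1e-3) {
        out <- out + domain$cell_volume
      }
    }
  }
  out / 1000   # cm^3
}
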
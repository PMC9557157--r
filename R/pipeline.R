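#' Default end-to-end run configuration
#'
#' Bundles the knobs of the four-scenario experiment: the baseline
#' circulation parameters, the synthetic-domain configuration, solver
#' settings and the washout length. The defaults are the package's
#' committed study conditions: 2d domain at 2.5 mm spacing with 40 mm
#' out-of-plane depth, 12 cycles at 750 steps/cycle with 4
#' initialization cycles, 50 stored fields per cycle, 8 washout
#' cycles.
#'
#' @param baseline A `scenario_params` baseline (default
#'   [default_scenario_params()]).
#' @param domain Arguments for [domain_config()] as a named list
#'   (`occluded` is set per scenario).
#' @param n_cycles,n_init_cycles,store_per_cycle Solver settings, see
#'   [solve_flow()].
#' @param washout_cycles Cycles of ink transport, see
#'   [transport_ink()].
#' @param fluid A [fluid_props()] object.
#' @return A list of class `run_config`.
#' @export
run_config <- function(baseline = default_scenario_params(),
                       domain = list(mode = "2d"),
                       n_cycles = 12, n_init_cycles = 4,
                       store_per_cycle = 50, washout_cycles = 8,
                       fluid = fluid_props()) {
  structure(list(baseline = baseline, domain = domain,
                 n_cycles = n_cycles, n_init_cycles = n_init_cycles,
                 store_per_cycle = store_per_cycle,
                 washout_cycles = washout_cycles, fluid = fluid),
            class = "run_config")
}

# stable digest of an R object (md5 of its canonical serialization)
.config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Run one scenario end to end
#'
#' Executes the full pipeline for one scenario: circulation simulation
#' to periodic steady state, synthetic-domain construction (occluded
#' for the LAAO scenarios), flux-program translation, pulsatile flow
#' solve, thrombosis metrics, and virtual-ink washout. The run is
#' fully deterministic for a given configuration.
#'
#' @param config A [run_config()] (default configuration if `NULL`).
#' @param scenario_name One of `"SR-LAA"`, `"SR-LAAO"`, `"AF-LAA"`,
#'   `"AF-LAAO"`.
#' @param cache_dir Optional directory for stage caching: when set, a
#'   completed report is stored keyed by the configuration hash and
#'   reused on identical re-runs.
#' @param keep_fields Keep the (large) `flow_field` and `ink_field`
#'   objects in the returned report (default `FALSE`).
#' @return A list of class `scenario_report`: `scenario`, `hemo`
#'   (hemodynamic summary), `metrics` (stagnation volumes, WSS areas,
#'   velocity statistics, recirculation), `washout` (old-blood series
#'   and LAA residence), `provenance`.
#' @export
run_scenario <- function(config = NULL, scenario_name,
                         cache_dir = NULL, keep_fields = FALSE) {
  if (is.null(config)) config <- run_config()
  stopifnot(inherits(config, "run_config"))
  hash <- .config_hash(list(config = config, scenario = scenario_name))
  if (!is.null(cache_dir)) {
    cache_file <- file.path(cache_dir, paste0("report-", hash, ".rds"))
    if (file.exists(cache_file)) return(readRDS(cache_file))
  }

  params <- apply_scenario(config$baseline, scenario_name)
  waves <- simulate_lpm(params)
  hemo <- summarize_hemodynamics(waves)

  dom_args <- config$domain
  dom_args$occluded <- params$laao_flag
  dom <- build_domain(do.call(domain_config, dom_args))
  flux <- make_flux_program(waves, dom)
  field <- solve_flow(dom, flux, config$fluid,
                      n_cycles = config$n_cycles,
                      n_init_cycles = config$n_init_cycles,
                      store_per_cycle = config$store_per_cycle)

  stag <- stagnation_volume(field)
  wss <- wss_classify(field)
  vel <- list(atrium = velocity_stats(field, region = "atrium"),
              lv = velocity_stats(field, region = "lv"),
              laa = if (!params$laao_flag)
                velocity_stats(field, region = "laa") else NULL,
              la = velocity_stats(field, region = "la"))
  recirc <- if (!params$laao_flag) {
    detect_laa_recirculation(field, flux)
  } else NULL

  ink <- transport_ink(field, n_cycles = config$washout_cycles)
  washout <- list(
    atrium_old_blood_pct = old_blood_fraction(ink, region = "atrium"),
    lv_old_blood_pct = old_blood_fraction(ink, region = "lv"),
    residence = laa_residence(ink, n_cycles = config$washout_cycles),
    budget = ink$budget
  )

  report <- structure(list(
    scenario = scenario_name,
    hemo = hemo,
    metrics = list(stagnation_cm3 = stag, wss = wss, velocity = vel,
                   recirculation = recirc),
    washout = washout,
    provenance = list(config_hash = hash,
                      package_version = as.character(
                        utils::packageVersion("laaoflow")),
                      n_cycles = config$n_cycles,
                      n_init_cycles = config$n_init_cycles,
                      grid_spacing_mm = dom$h,
                      convergence = check_convergence(field))
  ), class = "scenario_report")
  if (keep_fields) {
    report$field <- field
    report$ink <- ink
    report$waveforms <- waves
    report$flux <- flux
    report$domain <- dom
  }
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(report, cache_file)
  }
  report
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> %s\n", x$scenario))
  cat(sprintf("  pump %.2f L/min | MAP %.1f mmHg | atrial stagnation %.2f cm^3 | low-WSS (atrium) %.1f cm^2\n",
              x$hemo$pump_flow_l_min, x$hemo$mean_arterial_pressure_mmHg,
              x$metrics$stagnation_cm3[["atrium"]],
              x$metrics$wss$areas$low[x$metrics$wss$areas$region == "atrium"]))
  invisible(x)
}

#' Run the four-scenario experiment
#'
#' @param config A [run_config()]; `NULL` for the defaults.
#' @param cache_dir Optional cache directory, see [run_scenario()].
#' @param quiet Suppress progress messages.
#' @return Named list of four `scenario_report`s (`SR-LAA`, `SR-LAAO`,
#'   `AF-LAA`, `AF-LAAO`).
#' @export
run_four_scenarios <- function(config = NULL, cache_dir = NULL,
                               quiet = FALSE) {
  scenarios <- c("SR-LAA", "SR-LAAO", "AF-LAA", "AF-LAAO")
  reports <- lapply(scenarios, function(sc) {
    if (!quiet) message("running scenario ", sc)
    run_scenario(config, sc, cache_dir = cache_dir)
  })
  names(reports) <- scenarios
  reports
}

#' Integer percent change between two reported values
#'
#' Relative change of `to` with respect to `from`, reported as an
#' integer percentage using the ceiling convention (the smallest
#' integer not below the signed percentage): increases round up and
#' reductions are stated conservatively by their truncated magnitude.
#'
#' @param from Reference value.
#' @param to New value.
#' @return Integer percent change; `NA` where the reference is zero.
#' @export
percent_change <- function(from, to) {
  out <- rep(NA_integer_, length(from))
  ok <- is.finite(from) & from != 0
  out[ok] <- as.integer(ceiling(100 * (to[ok] - from[ok]) / from[ok]))
  out
}

#' Compare the four scenario reports
#'
#' Tabulates the thrombosis-related metrics of the four scenarios and
#' the percent changes of the paired comparisons (SR vs AF with intact
#' appendage; occlusion effect within each rhythm), using the
#' [percent_change()] reporting convention.
#'
#' @param reports Named list of four `scenario_report`s as produced by
#'   [run_four_scenarios()].
#' @return A list of class `scenario_comparison`: `table` (metric x
#'   scenario data frame of absolute values) and `changes` (data frame
#'   of integer percent changes per paired comparison).
#' @export
compare_scenarios <- function(reports) {
  need <- c("SR-LAA", "SR-LAAO", "AF-LAA", "AF-LAAO")
  if (!all(need %in% names(reports))) {
    stop("reports must contain the four scenarios: ",
         paste(need, collapse = ", "))
  }
  grab <- function(r) {
    wss_a <- r$metrics$wss$areas
    c(atrial_stagnation_cm3 = unname(r$metrics$stagnation_cm3[["atrium"]]),
      ventricular_stagnation_cm3 = unname(r$metrics$stagnation_cm3[["lv"]]),
      atrial_low_wss_cm2 = wss_a$low[wss_a$region == "atrium"],
      ventricular_low_wss_cm2 = wss_a$low[wss_a$region == "lv"],
      atrial_mean_velocity_cm_s = unname(r$metrics$velocity$atrium[["mean_cm_s"]]),
      atrial_old_blood_final_pct = unname(utils::tail(r$washout$atrium_old_blood_pct, 1)),
      laa_residence_final_pct = if (r$washout$residence$no_laa) NA_real_ else
        unname(utils::tail(r$washout$residence$percent_of_cycle1, 1)),
      pump_flow_l_min = r$hemo$pump_flow_l_min,
      map_mmHg = r$hemo$mean_arterial_pressure_mmHg)
  }
  tab <- vapply(reports[need], grab, grab(reports[[1]]))
  tab <- data.frame(metric = rownames(tab), tab, check.names = FALSE,
                    row.names = NULL)
  pairs <- list(
    `SR-LAA vs AF-LAA` = c("SR-LAA", "AF-LAA"),
    `SR-LAA vs SR-LAAO` = c("SR-LAA", "SR-LAAO"),
    `AF-LAA vs AF-LAAO` = c("AF-LAA", "AF-LAAO")
  )
  comparable <- c("atrial_stagnation_cm3", "ventricular_stagnation_cm3",
                  "atrial_low_wss_cm2", "ventricular_low_wss_cm2",
                  "atrial_mean_velocity_cm_s")
  changes <- lapply(names(pairs), function(nm) {
    ab <- pairs[[nm]]
    from <- tab[[ab[1]]][match(comparable, tab$metric)]
    to <- tab[[ab[2]]][match(comparable, tab$metric)]
    data.frame(comparison = nm, metric = comparable,
               from = from, to = to,
               change_pct = percent_change(from, to))
  })
  structure(list(table = tab, changes = do.call(rbind, changes)),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("<scenario_comparison>\n")
  print(x$table, digits = 3)
  cat("\npercent changes:\n")
  print(x$changes, digits = 3)
  invisible(x)
}

#' Write a scenario report (or comparison) as JSON
#'
#' @param x A `scenario_report` or `scenario_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  x <- unclass(x)
  # the bulky simulation objects are not part of the serialized report
  x[c("field", "ink", "waveforms", "flux", "domain")] <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
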
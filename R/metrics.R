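# Stored-instant indices inside the evaluation window (post-
# initialization cycles by default).
.window_indices <- function(field, window = NULL) {
  if (is.null(window)) {
    t0 <- field$n_init_cycles * field$period
    idx <- which(field$times > t0 + 1e-12)
  } else {
    stopifnot(length(window) == 2, window[1] >= 0)
    idx <- which(field$times > (window[1] - 1) * field$period + 1e-12 &
                   field$times <= window[2] * field$period + 1e-12)
  }
  if (!length(idx)) stop("empty evaluation window")
  idx
}

.region_mask <- function(domain, region) {
  switch(region,
    la = domain$label == .lab[["la"]],
    laa = domain$label == .lab[["laa"]],
    lv = domain$label == .lab[["lv"]],
    atrium = domain$label == .lab[["la"]] | domain$label == .lab[["laa"]],
    stop("unknown region '", region, "'; expected la, laa, lv or atrium")
  )
}

# Per-cell time-averaged speed (m/s) over the window; either the time
# average of the magnitude (default) or the magnitude of the
# time-averaged velocity vector.
.time_avg_speed <- function(field, idx, average = "magnitude") {
  nx <- field$domain$dims[["nx"]]; ny <- field$domain$dims[["ny"]]
  if (average == "magnitude") {
    acc <- matrix(0, nx, ny)
    for (k in idx) acc <- acc + cell_speed(field, k)
    acc / length(idx)
  } else {
    uacc <- matrix(0, nx + 1, ny); vacc <- matrix(0, nx, ny + 1)
    for (k in idx) {
      uacc <- uacc + field$u[[k]]
      vacc <- vacc + field$v[[k]]
    }
    uacc <- uacc / length(idx); vacc <- vacc / length(idx)
    uc <- 0.5 * (uacc[1:nx, , drop = FALSE] + uacc[2:(nx + 1), , drop = FALSE])
    vc <- 0.5 * (vacc[, 1:ny, drop = FALSE] + vacc[, 2:(ny + 1), drop = FALSE])
    sp <- sqrt(uc^2 + vc^2)
    sp[field$domain$label == 0L] <- NA_real_
    sp
  }
}

#' Stagnation volume per region
#'
#' Fluid volume whose time-averaged velocity magnitude over the
#' evaluation window falls below the stagnation threshold (default
#' 1 mm/s), reported per region. The evaluation window excludes the
#' initialization cycles by default.
#'
#' @param field A `flow_field` from [solve_flow()].
#' @param domain The `flow_domain` the field was solved on (defaults to
#'   the one embedded in `field`).
#' @param threshold Stagnation threshold, mm/s. Default 1.
#' @param window Optional `c(first_cycle, last_cycle)` evaluation
#'   window (1-based cycles); default all post-initialization cycles.
#' @param average `"magnitude"` (default) averages the speed over time;
#'   `"vector"` takes the magnitude of the time-averaged velocity
#'   vector instead.
#' @return Named numeric vector of stagnation volumes in cm^3: `la`,
#'   `laa`, `lv`, `atrium`.
#' @export
stagnation_volume <- function(field, domain = field$domain, threshold = 1,
                              window = NULL,
                              average = c("magnitude", "vector")) {
  stopifnot(inherits(field, "flow_field"), threshold > 0)
  average <- match.arg(average)
  idx <- .window_indices(field, window)
  sp <- .time_avg_speed(field, idx, average)
  stag <- !is.na(sp) & sp < threshold * 1e-3
  vol <- function(region) {
    sum(stag & .region_mask(domain, region)) * domain$cell_volume / 1000
  }
  c(la = vol("la"), laa = vol("laa"), lv = vol("lv"), atrium = vol("atrium"))
}

# Wall-face table for a 2d domain: one row per wall face with the
# adjacent fluid cell, its region, and the face orientation ("x" for a
# vertical wall, "y" for a horizontal wall). Inlet and outlet openings
# are not walls.
.wall_faces <- function(domain) {
  nx <- domain$dims[["nx"]]; ny <- domain$dims[["ny"]]
  lab <- domain$label
  fluid <- lab != 0L
  solid_at <- function(di, dj) {
    out <- matrix(TRUE, nx, ny)   # outside the grid counts as solid
    xs <- max(1, 1 + di):min(nx, nx + di)
    ys <- max(1, 1 + dj):min(ny, ny + dj)
    out[xs - di, ys - dj] <- !fluid[xs, ys]
    out
  }
  faces <- list()
  add <- function(mask, orientation, side) {
    w <- which(mask, arr.ind = TRUE)
    if (nrow(w)) {
      faces[[length(faces) + 1]] <<- data.frame(
        i = w[, 1], j = w[, 2], orientation = orientation, side = side,
        region = lab[w])
    }
  }
  add(fluid & solid_at(-1, 0), "x", "left")
  add(fluid & solid_at(1, 0), "x", "right")
  dn <- fluid & solid_at(0, -1)
  up <- fluid & solid_at(0, 1)
  # openings in the domain roof/floor are flow boundaries, not walls
  open_top <- c(domain$inlets$pv_right$cells, domain$inlets$pv_left$cells)
  up[cbind(open_top, ny)] <- FALSE
  dn[cbind(domain$outlet$cells, 1L)] <- FALSE
  add(dn, "y", "down")
  add(up, "y", "up")
  do.call(rbind, faces)
}

#' Classify wall area by time-averaged wall shear stress
#'
#' Computes the time-averaged wall shear stress magnitude on every
#' wall face as \eqn{\tau = \mu\,|u_t|/(h/2)} where \eqn{u_t} is the
#' tangential velocity at the first cell center off the wall (the
#' linear wall-gradient consistent with the solver's no-slip ghost
#' discretization), then bins the wall area: low non-physiological
#' (0-0.2 Pa), physiological (0.2-9 Pa) and high (>9 Pa).
#'
#' @inheritParams stagnation_volume
#' @param fluid A [fluid_props()] (defaults to the one the field was
#'   solved with).
#' @param bins Numeric bin edges in Pa, default `c(0, 0.2, 9)`.
#' @return A list with `areas`: data frame of per-region and total
#'   areas (cm^2) in each bin (`low`, `physiological`, `high`), and
#'   `total_wall_area` (cm^2).
#' @export
wss_classify <- function(field, domain = field$domain,
                         fluid = field$fluid, bins = c(0, 0.2, 9),
                         window = NULL) {
  stopifnot(inherits(field, "flow_field"), length(bins) == 3,
            all(diff(bins) > 0))
  idx <- .window_indices(field, window)
  wf <- .wall_faces(domain)
  nx <- domain$dims[["nx"]]
  mu <- fluid$dynamic_viscosity
  h <- domain$h / 1000
  cell_lin <- wf$i + (wf$j - 1L) * nx
  is_x <- wf$orientation == "x"
  tau_acc <- numeric(nrow(wf))
  for (k in idx) {
    U <- field$u[[k]]; V <- field$v[[k]]
    vc <- 0.5 * (V[, 1:(ncol(V) - 1), drop = FALSE] +
                   V[, 2:ncol(V), drop = FALSE])
    uc <- 0.5 * (U[1:nx, , drop = FALSE] +
                   U[2:nrow(U), , drop = FALSE])
    ut <- ifelse(is_x, vc[cell_lin], uc[cell_lin])
    tau_acc <- tau_acc + mu * abs(ut) / (h / 2)
  }
  tau <- tau_acc / length(idx)
  face_area <- domain$h * (if (domain$mode == "2d") domain$depth else domain$h) / 100  # cm^2
  bin_of <- cut(tau, breaks = c(bins, Inf), labels = c("low", "physiological", "high"),
                right = FALSE, include.lowest = TRUE)
  regions <- list(la = .lab[["la"]], laa = .lab[["laa"]], lv = .lab[["lv"]])
  rows <- lapply(c(regions, list(atrium = c(.lab[["la"]], .lab[["laa"]]),
                                 total = c(.lab[["la"]], .lab[["laa"]], .lab[["lv"]]))),
                 function(codes) {
    sel <- wf$region %in% codes
    vapply(levels(bin_of), function(b) sum(sel & bin_of == b) * face_area,
           numeric(1))
  })
  areas <- as.data.frame(do.call(rbind, rows))
  areas$region <- rownames(areas)
  rownames(areas) <- NULL
  list(areas = areas[, c("region", "low", "physiological", "high")],
       total_wall_area = nrow(wf) * face_area,
       bins_pa = bins)
}

#' Mean velocity and temporal velocity standard deviation per region
#'
#' The mean is the volume-weighted, time-averaged velocity magnitude
#' over the evaluation window; the standard deviation is the
#' volume-weighted average of each cell's temporal (population)
#' standard deviation of velocity magnitude.
#'
#' @inheritParams stagnation_volume
#' @param region One of `"la"`, `"laa"`, `"lv"`, `"atrium"`.
#' @return Named numeric vector `c(mean_cm_s, sd_cm_s)`.
#' @export
velocity_stats <- function(field, domain = field$domain, region = "atrium",
                           window = NULL) {
  stopifnot(inherits(field, "flow_field"))
  mask <- .region_mask(domain, region)
  if (!any(mask)) stop("region '", region, "' contains no cells")
  idx <- .window_indices(field, window)
  nx <- domain$dims[["nx"]]; ny <- domain$dims[["ny"]]
  acc <- matrix(0, nx, ny); acc2 <- matrix(0, nx, ny)
  for (k in idx) {
    sp <- cell_speed(field, k)
    sp[is.na(sp)] <- 0
    acc <- acc + sp
    acc2 <- acc2 + sp^2
  }
  m <- acc / length(idx)
  v <- pmax(acc2 / length(idx) - m^2, 0)
  # equal cell volumes: the volume weighting reduces to a plain mean
  c(mean_cm_s = mean(m[mask]) * 100,
    sd_cm_s = mean(sqrt(v[mask])) * 100)
}

#' Detect the appendage recirculation pocket during diastasis
#'
#' Phase-averages the stored velocity fields over the diastasis window
#' (the low-transmitral-flow interval between the E and A waves,
#' located from the flux program's mitral-plane diagnostic) and tests
#' the unoccluded appendage for a recirculation pocket: bidirectional
#' exchange across the neck plane (both inflow and outflow faces
#' simultaneously) combined with a sub-threshold mean speed inside the
#' pouch relative to the atrial mean.
#'
#' @param field A `flow_field` solved on an unoccluded domain.
#' @param flux The `flux_program` that drove the solve.
#' @param domain The `flow_domain` (defaults to the embedded one).
#' @param phase_halfwidth Half-width of the diastasis phase window, as
#'   a fraction of the cycle (default 0.06).
#' @return A list: `recirculating` (logical), `laa_mean_speed_cm_s`,
#'   `atrium_mean_speed_cm_s`, `neck_u_min`, `neck_u_max` (m/s),
#'   `diastasis_phase`.
#' @export
detect_laa_recirculation <- function(field, flux, domain = field$domain,
                                     phase_halfwidth = 0.06) {
  stopifnot(inherits(field, "flow_field"), inherits(flux, "flux_program"))
  if (!any(domain$label == .lab[["laa"]])) {
    stop("domain has no appendage region (occluded?)")
  }
  q <- flux$mitral_diagnostic
  period <- attr(flux, "period")
  phase <- (flux$time_s - flux$time_s[1]) / period
  # diastasis: the transmitral minimum between the E peak and the
  # following flow maximum (A wave, or cycle end in AF)
  pk <- pracma::findpeaks(q, minpeakheight = 0.05 * max(q), zero = "+")
  if (is.null(pk)) stop("no diastolic flow in the mitral diagnostic")
  pk <- pk[order(pk[, 2]), , drop = FALSE]
  i_e <- pk[1, 2]
  i_end <- if (nrow(pk) > 1) pk[nrow(pk), 2] else length(q)
  seg <- i_e:i_end
  i_dia <- seg[which.min(q[seg])]
  ph_dia <- phase[i_dia]

  idx_all <- .window_indices(field)
  ph_field <- (field$times / field$period) %% 1
  dph <- abs(ph_field - ph_dia)
  dph <- pmin(dph, 1 - dph)
  idx <- idx_all[dph[idx_all] <= phase_halfwidth]
  if (!length(idx)) idx <- idx_all

  nx <- domain$dims[["nx"]]; ny <- domain$dims[["ny"]]
  uacc <- matrix(0, nx + 1, ny); vacc <- matrix(0, nx, ny + 1)
  for (k in idx) {
    uacc <- uacc + field$u[[k]]; vacc <- vacc + field$v[[k]]
  }
  uacc <- uacc / length(idx); vacc <- vacc / length(idx)
  uc <- 0.5 * (uacc[1:nx, , drop = FALSE] + uacc[2:(nx + 1), , drop = FALSE])
  vc <- 0.5 * (vacc[, 1:ny, drop = FALSE] + vacc[, 2:(ny + 1), drop = FALSE])
  sp <- sqrt(uc^2 + vc^2)
  laa_mask <- .region_mask(domain, "laa")
  atr_mask <- .region_mask(domain, "atrium")

  # u faces separating LA cells from LAA cells = the neck plane
  lab <- domain$label
  left_laa <- lab[1:(nx - 1), ] == .lab[["laa"]] & lab[2:nx, ] == .lab[["la"]]
  neck_u <- uacc[2:nx, ][left_laa]
  if (!length(neck_u)) {
    right_laa <- lab[2:nx, ] == .lab[["laa"]] & lab[1:(nx - 1), ] == .lab[["la"]]
    neck_u <- uacc[2:nx, ][right_laa]
  }
  laa_speed <- mean(sp[laa_mask])
  atr_speed <- mean(sp[atr_mask])
  list(
    recirculating = length(neck_u) > 0 && min(neck_u) < 0 && max(neck_u) > 0 &&
      laa_speed < atr_speed,
    laa_mean_speed_cm_s = laa_speed * 100,
    atrium_mean_speed_cm_s = atr_speed * 100,
    neck_u_min = if (length(neck_u)) min(neck_u) else NA_real_,
    neck_u_max = if (length(neck_u)) max(neck_u) else NA_real_,
    diastasis_phase = ph_dia
  )
}
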
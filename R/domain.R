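#' Configuration of the synthetic left-heart flow domain
#'
#' Describes the idealized left atrium + appendage (+ ventricular
#' outflow path) geometry: a circular/spherical atrium with a blind
#' single-lobe ("windsock") appendage pouch attached through a narrow
#' neck, two pulmonary-vein inlet channels at the atrial roof, a mitral
#' orifice channel to the ventricle, and an apical cannula outlet. The
#' chamber sizes default to the study patient's end-systolic volumes
#' (atrium 169 cm^3 including the appendage, ventricle 295 cm^3).
#'
#' @param mode `"2d"` (planar domain with an out-of-plane depth, the
#'   default solver scale) or `"3d"` (voxel domain, used for
#'   volume-faithful geometry checks).
#' @param grid_spacing Cell size, mm.
#' @param target_atrial_volume Target atrium + appendage volume, cm^3.
#' @param target_ventricular_volume Target ventricle volume, cm^3.
#' @param neck_width Appendage neck (ostium) width, mm; must be smaller
#'   than the pouch width.
#' @param neck_length Appendage neck length, mm.
#' @param pouch_depth Appendage pouch depth along its axis, mm
#'   (semi-axis in 2d, cylinder length in 3d).
#' @param pouch_width Appendage pouch width, mm (full width in 2d,
#'   cylinder diameter in 3d).
#' @param mitral_width Mitral orifice width/diameter, mm.
#' @param pv_width Pulmonary-vein inlet channel width/diameter, mm.
#' @param cannula_width Inflow-cannula outlet channel width/diameter, mm.
#' @param occluded `TRUE` builds the occluded (LAAO) variant: the
#'   appendage cells are replaced by wall at the neck plane.
#' @param out_of_plane_depth Depth used to convert areas to volumes in
#'   2d mode, mm.
#' @return An object of class `domain_config`.
#' @export
domain_config <- function(mode = c("2d", "3d"),
                          grid_spacing = if (match.arg(mode) == "2d") 2.5 else 2,
                          target_atrial_volume = 169,
                          target_ventricular_volume = 295,
                          neck_width = 12,
                          neck_length = 6,
                          pouch_depth = 20,
                          pouch_width = 18,
                          mitral_width = 26,
                          pv_width = 12,
                          cannula_width = 14,
                          occluded = FALSE,
                          out_of_plane_depth = 40) {
  mode <- match.arg(mode)
  stopifnot(grid_spacing > 0, target_atrial_volume > 0,
            target_ventricular_volume > 0, neck_width > 0,
            pouch_depth > 0, pouch_width > 0,
            mitral_width > 0, pv_width > 0, cannula_width > 0,
            out_of_plane_depth > 0)
  if (neck_width >= pouch_width) {
    stop("neck_width must be smaller than the pouch width")
  }
  if (neck_width / grid_spacing < 4) {
    stop("grid spacing too coarse: the appendage neck must be resolved by at least 4 cells")
  }
  structure(list(
    mode = mode, grid_spacing = grid_spacing,
    target_atrial_volume = target_atrial_volume,
    target_ventricular_volume = target_ventricular_volume,
    neck_width = neck_width, neck_length = neck_length,
    pouch_depth = pouch_depth, pouch_width = pouch_width,
    mitral_width = mitral_width, pv_width = pv_width,
    cannula_width = cannula_width, occluded = occluded,
    out_of_plane_depth = out_of_plane_depth
  ), class = "domain_config")
}

# Region label codes shared by the domain, solver and metrics layers.
.lab <- c(outside = 0L, la = 1L, laa = 2L, lv = 3L)

#' Build the labeled synthetic flow domain
#'
#' Discretizes the idealized geometry onto a uniform grid of cell
#' centers and labels each cell `outside`, `la`, `laa` or `lv`. The
#' atrial and ventricular sizes are calibrated (by a secant iteration
#' on the discretized volume) so that the labeled volumes match the
#' configured targets; with `occluded = TRUE` the appendage pouch and
#' neck are replaced by wall, leaving the rest of the domain unchanged
#' cell by cell.
#'
#' @param config A [domain_config()] object.
#' @return An object of class `flow_domain`: grid metadata (`h` mm,
#'   `depth` mm, `origin`, `dims`), the integer `label` array, the
#'   per-cell volume `cell_volume` (mm^3), inlet/outlet boundary-cell
#'   lists (2d mode) and the originating `config`.
#' @export
build_domain <- function(config) {
  stopifnot(inherits(config, "domain_config"))
  if (config$mode == "2d") .build_domain_2d(config) else .build_domain_3d(config)
}

# --- 2d construction ---------------------------------------------------

# Geometry report: all lengths mm. y axis points from the cannula
# outlet (bottom) to the pulmonary-vein inlets (top).
.domain_layout_2d <- function(cfg, r_la_scale = 1, r_lv_scale = 1) {
  # half-ellipse pouch (semi-axes pouch_depth x pouch_width/2) + neck
  area_laa <- pi * cfg$pouch_depth * (cfg$pouch_width / 2) / 2 +
    cfg$neck_width * cfg$neck_length
  a_target <- cfg$target_atrial_volume * 1000 / cfg$out_of_plane_depth
  v_target <- cfg$target_ventricular_volume * 1000 / cfg$out_of_plane_depth
  r_la <- sqrt(max(a_target - area_laa, 1) / pi) * r_la_scale
  r_lv <- sqrt(v_target / pi) * r_lv_scale
  cannula_len <- 8
  gap <- 6
  pv_len <- 8
  y_lv <- cannula_len + r_lv
  y_la <- y_lv + r_lv + gap + r_la
  y_top <- y_la + r_la + pv_len
  list(r_la = r_la, r_lv = r_lv, y_lv = y_lv, y_la = y_la,
       y_top = y_top, gap = gap, cannula_len = cannula_len,
       y_mitral = y_lv + r_lv + gap / 2,
       pv_offset = 16)
}

# Label grid of the 2d geometry for a given layout.
.labels_2d <- function(cfg, lay) {
  h <- cfg$grid_spacing
  xmin <- -(lay$r_la + cfg$neck_length + cfg$pouch_depth + 3 * h)
  xmax <- max(lay$r_la, lay$r_lv) + 3 * h
  nx <- ceiling((xmax - xmin) / h)
  ny <- ceiling(lay$y_top / h)
  xc <- xmin + (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)

  in_la <- (X^2 + (Y - lay$y_la)^2) <= lay$r_la^2
  in_lv <- (X^2 + (Y - lay$y_lv)^2) <= lay$r_lv^2
  # mitral channel between the chambers
  mitral <- abs(X) <= cfg$mitral_width / 2 &
    Y > lay$y_lv & Y < lay$y_la
  # pulmonary-vein inlet channels through the atrial roof
  pv_r <- abs(X - lay$pv_offset) <= cfg$pv_width / 2 & Y > lay$y_la
  pv_l <- abs(X + lay$pv_offset) <= cfg$pv_width / 2 & Y > lay$y_la
  # apical cannula outlet channel
  cann <- abs(X) <= cfg$cannula_width / 2 & Y < lay$y_lv
  # appendage: neck rectangle plus half-ellipse pouch on the left flank
  x_att <- -lay$r_la
  neck <- X <= x_att + 2 * h & X >= x_att - cfg$neck_length &
    abs(Y - lay$y_la) <= cfg$neck_width / 2
  x_pc <- x_att - cfg$neck_length
  pouch <- ((X - x_pc) / cfg$pouch_depth)^2 +
    ((Y - lay$y_la) / (cfg$pouch_width / 2))^2 <= 1 & X <= x_pc
  laa <- (neck | pouch) & !in_la

  label <- matrix(.lab[["outside"]], nx, ny)
  label[in_la | (mitral & Y >= lay$y_mitral) | pv_r | pv_l] <- .lab[["la"]]
  label[in_lv | (mitral & Y < lay$y_mitral) | cann] <- .lab[["lv"]]
  label[laa] <- .lab[["laa"]]
  if (cfg$occluded) label[label == .lab[["laa"]]] <- .lab[["outside"]]
  list(label = label, origin = c(xmin, 0), nx = nx, ny = ny, xc = xc)
}

.build_domain_2d <- function(cfg) {
  h <- cfg$grid_spacing
  # secant iterations on the chamber scales so the labeled areas (cells
  # x depth, channels included) hit the configured volume targets; the
  # occluded variant is calibrated with the pouch present so both
  # variants share the same geometry outside the appendage
  vol_of <- function(s_la, s_lv) {
    cfg_open <- cfg
    cfg_open$occluded <- FALSE
    g <- .labels_2d(cfg_open, .domain_layout_2d(cfg, s_la, s_lv))
    n_cell <- h * h * cfg$out_of_plane_depth / 1000
    c(atr = sum(g$label == .lab[["la"]] | g$label == .lab[["laa"]]) * n_cell,
      ven = sum(g$label == .lab[["lv"]]) * n_cell)
  }
  s_la <- 1; s_lv <- 1
  for (it in 1:3) {
    v <- vol_of(s_la, s_lv)
    ds <- 0.01
    slope_la <- (vol_of(s_la + ds, s_lv)[["atr"]] - v[["atr"]]) / ds
    slope_lv <- (vol_of(s_la, s_lv + ds)[["ven"]] - v[["ven"]]) / ds
    s_la <- s_la + (cfg$target_atrial_volume - v[["atr"]]) / slope_la
    s_lv <- s_lv + (cfg$target_ventricular_volume - v[["ven"]]) / slope_lv
  }
  lay <- .domain_layout_2d(cfg, s_la, s_lv)
  g <- .labels_2d(cfg, lay)
  label <- g$label
  nx <- g$nx; ny <- g$ny; xc <- g$xc

  # boundary cells: inlets on the top edge, outlet on the bottom edge
  top_open <- which(label[, ny] != 0L)
  bot_open <- which(label[, 1] != 0L)
  pvr_cells <- top_open[abs(xc[top_open] - lay$pv_offset) <= cfg$pv_width / 2]
  pvl_cells <- top_open[abs(xc[top_open] + lay$pv_offset) <= cfg$pv_width / 2]
  out_cells <- bot_open[abs(xc[bot_open]) <= cfg$cannula_width / 2]
  if (!length(pvr_cells) || !length(pvl_cells) || !length(out_cells)) {
    stop("degenerate domain: an inlet or outlet channel contains no cells")
  }

  dom <- structure(list(
    mode = "2d", h = h, depth = cfg$out_of_plane_depth,
    origin = g$origin, dims = c(nx = nx, ny = ny),
    label = label, cell_volume = h * h * cfg$out_of_plane_depth,
    inlets = list(
      pv_right = list(cells = pvr_cells, side = "top", split = 0.55),
      pv_left = list(cells = pvl_cells, side = "top", split = 0.45)
    ),
    outlet = list(cells = out_cells, side = "bottom"),
    layout = lay, config = cfg
  ), class = "flow_domain")
  .check_connectivity(dom)
  dom
}

# --- 3d voxel construction --------------------------------------------

.voxelize_3d <- function(cfg, r_la, r_lv) {
  h <- cfg$grid_spacing
  cannula_len <- 8; gap <- 6; pv_len <- 8; pv_offset <- 16
  y_lv <- cannula_len + r_lv
  y_la <- y_lv + r_lv + gap + r_la
  y_top <- y_la + r_la + pv_len
  xmin <- -(r_la + cfg$neck_length + cfg$pouch_depth + 3 * h)
  xmax <- max(r_la, r_lv) + 3 * h
  zext <- max(r_la, r_lv) + 3 * h
  nx <- ceiling((xmax - xmin) / h)
  ny <- ceiling(y_top / h)
  nz <- ceiling(2 * zext / h)
  xc <- xmin + (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  zc <- -zext + (seq_len(nz) - 0.5) * h
  X <- array(rep(xc, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(yc, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(zc, each = nx * ny), c(nx, ny, nz))

  in_la <- X^2 + (Y - y_la)^2 + Z^2 <= r_la^2
  in_lv <- X^2 + (Y - y_lv)^2 + Z^2 <= r_lv^2
  mitral <- X^2 + Z^2 <= (cfg$mitral_width / 2)^2 & Y > y_lv & Y < y_la
  pv_r <- (X - pv_offset)^2 + Z^2 <= (cfg$pv_width / 2)^2 & Y > y_la
  pv_l <- (X + pv_offset)^2 + Z^2 <= (cfg$pv_width / 2)^2 & Y > y_la
  cann <- X^2 + Z^2 <= (cfg$cannula_width / 2)^2 & Y < y_lv
  x_att <- -r_la
  neck <- X <= x_att + 2 * h & X >= x_att - cfg$neck_length &
    (Y - y_la)^2 + Z^2 <= (cfg$neck_width / 2)^2
  # cylindrical windsock pouch, radius pouch_width/2, length pouch_depth
  x_pc <- x_att - cfg$neck_length
  pouch <- X <= x_pc & X >= x_pc - cfg$pouch_depth &
    (Y - y_la)^2 + Z^2 <= (cfg$pouch_width / 2)^2
  laa <- (neck | pouch) & !in_la

  label <- array(.lab[["outside"]], c(nx, ny, nz))
  y_mitral <- y_lv + r_lv + gap / 2
  label[in_la | (mitral & Y >= y_mitral) | pv_r | pv_l] <- .lab[["la"]]
  label[in_lv | (mitral & Y < y_mitral) | cann] <- .lab[["lv"]]
  label[laa] <- .lab[["laa"]]
  if (cfg$occluded) label[label == .lab[["laa"]]] <- .lab[["outside"]]
  list(label = label, origin = c(xmin, 0, -zext),
       dims = c(nx = nx, ny = ny, nz = nz))
}

.build_domain_3d <- function(cfg) {
  h <- cfg$grid_spacing
  # analytic first guesses, then secant iterations on the voxel-counted
  # volumes so the labeled regions hit the configured targets
  v_laa_analytic <- pi * (cfg$pouch_width / 2)^2 * cfg$pouch_depth +
    pi * (cfg$neck_width / 2)^2 * cfg$neck_length
  r_la <- ((cfg$target_atrial_volume * 1000 - v_laa_analytic) * 3 /
             (4 * pi))^(1 / 3)
  r_lv <- (cfg$target_ventricular_volume * 1000 * 3 / (4 * pi))^(1 / 3)

  vol_of <- function(r_la, r_lv) {
    vox <- .voxelize_3d(cfg, r_la, r_lv)
    n_cell <- h^3
    c(atr = sum(vox$label == .lab[["la"]] | vox$label == .lab[["laa"]]) *
        n_cell / 1000,
      ven = sum(vox$label == .lab[["lv"]]) * n_cell / 1000)
  }
  for (it in 1:3) {
    v <- vol_of(r_la, r_lv)
    dr <- 0.25
    v_la2 <- vol_of(r_la + dr, r_lv)[["atr"]]
    v_lv2 <- vol_of(r_la, r_lv + dr)[["ven"]]
    slope_la <- (v_la2 - v[["atr"]]) / dr
    slope_lv <- (v_lv2 - v[["ven"]]) / dr
    r_la <- r_la + (cfg$target_atrial_volume - v[["atr"]]) / slope_la
    r_lv <- r_lv + (cfg$target_ventricular_volume - v[["ven"]]) / slope_lv
  }
  vox <- .voxelize_3d(cfg, r_la, r_lv)
  structure(list(
    mode = "3d", h = h, depth = NA_real_,
    origin = vox$origin, dims = vox$dims,
    label = vox$label, cell_volume = h^3,
    inlets = NULL, outlet = NULL,
    layout = list(r_la = r_la, r_lv = r_lv), config = cfg
  ), class = "flow_domain")
}

# Flood fill over face neighbours; every fluid cell must be reachable
# from the first inlet cell.
.check_connectivity <- function(dom) {
  lab <- dom$label
  nx <- dom$dims[["nx"]]; ny <- dom$dims[["ny"]]
  fluid <- lab != 0L
  seen <- matrix(FALSE, nx, ny)
  start <- cbind(dom$inlets$pv_right$cells[1], ny)
  seen[start] <- TRUE
  frontier <- start
  while (nrow(frontier)) {
    nb <- rbind(
      cbind(frontier[, 1] + 1L, frontier[, 2]),
      cbind(frontier[, 1] - 1L, frontier[, 2]),
      cbind(frontier[, 1], frontier[, 2] + 1L),
      cbind(frontier[, 1], frontier[, 2] - 1L)
    )
    ok <- nb[, 1] >= 1 & nb[, 1] <= nx & nb[, 2] >= 1 & nb[, 2] <= ny
    nb <- nb[ok, , drop = FALSE]
    ok <- fluid[nb] & !seen[nb]
    nb <- unique(nb[ok, , drop = FALSE])
    seen[nb] <- TRUE
    frontier <- nb
  }
  if (any(fluid & !seen)) {
    stop(sprintf("domain is not connected: %d fluid cells unreachable from the inlets",
                 sum(fluid & !seen)))
  }
  invisible(TRUE)
}

#' Labeled region volumes of a flow domain
#'
#' @param domain A `flow_domain`.
#' @return Named numeric vector of volumes in cm^3: `la`, `laa`, `lv`,
#'   and `atrium` (= la + laa).
#' @export
region_volumes <- function(domain) {
  stopifnot(inherits(domain, "flow_domain"))
  n <- c(la = sum(domain$label == .lab[["la"]]),
         laa = sum(domain$label == .lab[["laa"]]),
         lv = sum(domain$label == .lab[["lv"]]))
  v <- n * domain$cell_volume / 1000
  c(v, atrium = unname(v[["la"]] + v[["laa"]]))
}

#' @export
print.flow_domain <- function(x, ...) {
  v <- region_volumes(x)
  cat(sprintf(
    "<flow_domain> %s, h = %g mm, dims %s | atrium %.1f cm^3 (LAA %.1f), ventricle %.1f cm^3%s\n",
    x$mode, x$h, paste(x$dims, collapse = "x"),
    v[["atrium"]], v[["laa"]], v[["lv"]],
    if (x$config$occluded) " [occluded]" else ""))
  invisible(x)
}

#' Translate circulation waveforms into a boundary flux program
#'
#' Converts one converged cycle of the lumped-parameter waveforms into
#' the mass-consistent boundary fluxes that drive the rigid synthetic
#' domain: the pulmonary-vein inflow (the circulation model's venous
#' return into the atrium, which equals the cannula flow plus the flux
#' equivalent of the atrial + ventricular volume change) is split
#' exactly 55/45 between the right and left inlet, and the outlet flow
#' balances the total inflow at every instant so the rigid surrogate
#' sees the same through-flow and phasic modulation as the moving-wall
#' original. The mitral-plane flow is carried along as a diagnostic; it
#' is zero throughout systole.
#'
#' @param w A converged `waveform_set` from [simulate_lpm()].
#' @param domain A `flow_domain` (provides the inlet split fractions).
#' @return An object of class `flux_program`: a data frame with columns
#'   `time_s`, `inflow_pv_right`, `inflow_pv_left`, `outlet`,
#'   `mitral_diagnostic` (mL/s), with attribute `period`.
#' @export
make_flux_program <- function(w, domain) {
  stopifnot(inherits(w, "waveform_set"), inherits(domain, "flow_domain"))
  state_cols <- grep("^v_", names(w), value = TRUE)
  drift <- max(abs(as.numeric(w[nrow(w), state_cols]) -
                     as.numeric(w[1, state_cols])))
  if (drift > 0.02 * max(w$v_lv)) {
    stop("waveforms are not cyclic; supply a converged cycle")
  }
  total_in <- w$q_pvla
  split_r <- domain$inlets$pv_right$split
  split_l <- domain$inlets$pv_left$split
  structure(
    data.frame(
      time_s = w$time_s,
      inflow_pv_right = split_r * total_in,
      inflow_pv_left = split_l * total_in,
      outlet = total_in,
      mitral_diagnostic = w$q_mv
    ),
    class = c("flux_program", "data.frame"),
    period = w$time_s[nrow(w)] - w$time_s[1]
  )
}

#' Export a 2d flow domain as legacy ASCII VTK structured points
#'
#' Region labels are written as cell data (`region`: 0 outside, 1 LA,
#' 2 LAA, 3 LV).
#'
#' @param domain A `flow_domain` (2d mode).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_domain_vtk <- function(domain, path) {
  stopifnot(inherits(domain, "flow_domain"))
  if (domain$mode != "2d") stop("VTK export is implemented for 2d domains")
  nx <- domain$dims[["nx"]]; ny <- domain$dims[["ny"]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0", "laaoflow domain", "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d 1", nx + 1L, ny + 1L),
    sprintf("ORIGIN %g %g 0", domain$origin[1], domain$origin[2]),
    sprintf("SPACING %g %g %g", domain$h, domain$h, domain$depth),
    sprintf("CELL_DATA %d", nx * ny),
    "SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", as.integer(domain$label)), con)
  invisible(path)
}
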
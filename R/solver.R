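#' Blood fluid properties
#'
#' @param density Density, kg/m^3. Default 1060.
#' @param dynamic_viscosity Dynamic viscosity, Pa s. Default 0.0035
#'   (Newtonian blood).
#' @return An object of class `fluid_props`.
#' @export
fluid_props <- function(density = 1060, dynamic_viscosity = 0.0035) {
  stopifnot(density > 0, dynamic_viscosity > 0)
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_props")
}

#' Straight-channel validation domain
#'
#' A vertical rectangular channel with a full-width inlet at the top
#' and a full-width outlet at the bottom; used to validate the solver
#' against the plane-Poiseuille solution and the ink transport against
#' the one-dimensional method of characteristics.
#'
#' @param width Channel width, mm.
#' @param length Channel length, mm.
#' @param grid_spacing Cell size, mm.
#' @param out_of_plane_depth Depth for area-volume conversion, mm.
#' @return A `flow_domain` (2d) whose single region is labeled `la`.
#' @export
channel_domain <- function(width = 10, length = 60, grid_spacing = 0.5,
                           out_of_plane_depth = 10) {
  h <- grid_spacing
  nx <- round(width / h)
  ny <- round(length / h)
  stopifnot(nx >= 3, ny >= 3)
  label <- matrix(.lab[["la"]], nx, ny)
  structure(list(
    mode = "2d", h = h, depth = out_of_plane_depth,
    origin = c(0, 0), dims = c(nx = nx, ny = ny),
    label = label, cell_volume = h * h * out_of_plane_depth,
    inlets = list(
      pv_right = list(cells = seq_len(nx), side = "top", split = 1),
      pv_left = list(cells = integer(0), side = "top", split = 0)
    ),
    outlet = list(cells = seq_len(nx), side = "bottom"),
    layout = NULL,
    config = list(occluded = FALSE, out_of_plane_depth = out_of_plane_depth)
  ), class = "flow_domain")
}

#' Constant-flow flux program
#'
#' Steady boundary program (useful for validation runs): total inflow
#' `q_ml_s` split between the domain's inlets by their configured
#' fractions, balanced by the outlet.
#'
#' @param domain A `flow_domain`.
#' @param q_ml_s Total through-flow, mL/s.
#' @param period Nominal "cycle" length used for storage cadence, s.
#' @param n Number of samples.
#' @return A `flux_program`.
#' @export
constant_flux_program <- function(domain, q_ml_s, period = 0.75, n = 751) {
  tt <- seq(0, period, length.out = n)
  structure(
    data.frame(
      time_s = tt,
      inflow_pv_right = rep(domain$inlets$pv_right$split * q_ml_s, n),
      inflow_pv_left = rep(domain$inlets$pv_left$split * q_ml_s, n),
      outlet = rep(q_ml_s, n),
      mitral_diagnostic = rep(0, n)
    ),
    class = c("flux_program", "data.frame"), period = period
  )
}

# Precomputed discrete operators for the staggered (MAC) grid:
# cell numbering, sparse pressure Laplacian with its Cholesky factor,
# dof masks and index vectors for the velocity correction.
.solver_setup <- function(domain) {
  nx <- domain$dims[["nx"]]; ny <- domain$dims[["ny"]]
  fluid <- domain$label != 0L
  h <- domain$h / 1000                      # m

  idx <- matrix(0L, nx, ny)
  idx[fluid] <- seq_len(sum(fluid))
  nf <- sum(fluid)

  u_dof <- matrix(FALSE, nx + 1, ny)
  u_dof[2:nx, ] <- fluid[1:(nx - 1), ] & fluid[2:nx, ]
  v_dof <- matrix(FALSE, nx, ny + 1)
  v_dof[, 2:ny] <- fluid[, 1:(ny - 1)] & fluid[, 2:ny]

  # assemble -Laplacian over fluid cells (couplings across interior faces)
  iu <- which(u_dof, arr.ind = TRUE)
  a_u <- cbind(idx[cbind(iu[, 1] - 1L, iu[, 2])], idx[iu])
  iv <- which(v_dof, arr.ind = TRUE)
  a_v <- cbind(idx[cbind(iv[, 1], iv[, 2] - 1L)], idx[iv])
  pairs <- rbind(a_u, a_v)
  ii <- c(pairs[, 1], pairs[, 2], pairs[, 1], pairs[, 2])
  jj <- c(pairs[, 2], pairs[, 1], pairs[, 1], pairs[, 2])
  vv <- c(rep(-1, 2 * nrow(pairs)), rep(1, 2 * nrow(pairs))) / h^2
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nf, nf))
  A[1, 1] <- A[1, 1] + 1 / h^2             # remove the constant null space
  chol_A <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)

  # wall masks for tangential no-slip ghosts (full-size, valid at dofs)
  pad_f <- function(di, dj) {
    out <- matrix(FALSE, nx, ny)
    xs <- max(1, 1 + di):min(nx, nx + di)
    ys <- max(1, 1 + dj):min(ny, ny + dj)
    out[xs - di, ys - dj] <- fluid[xs, ys]
    out
  }
  f_up <- pad_f(0, 1); f_dn <- pad_f(0, -1)
  f_rt <- pad_f(1, 0); f_lt <- pad_f(-1, 0)
  u_wall_up <- matrix(TRUE, nx + 1, ny)
  u_wall_up[2:nx, ] <- !(f_up[1:(nx - 1), ] & f_up[2:nx, ])
  u_wall_dn <- matrix(TRUE, nx + 1, ny)
  u_wall_dn[2:nx, ] <- !(f_dn[1:(nx - 1), ] & f_dn[2:nx, ])
  v_wall_rt <- matrix(TRUE, nx, ny + 1)
  v_wall_rt[, 2:ny] <- !(f_rt[, 1:(ny - 1)] & f_rt[, 2:ny])
  v_wall_lt <- matrix(TRUE, nx, ny + 1)
  v_wall_lt[, 2:ny] <- !(f_lt[, 1:(ny - 1)] & f_lt[, 2:ny])

  # index vectors for the pressure-gradient correction
  u_cl <- idx[cbind(iu[, 1] - 1L, iu[, 2])]
  u_cr <- idx[iu]
  u_lin <- iu[, 1] + (iu[, 2] - 1L) * (nx + 1L)
  v_cd <- idx[cbind(iv[, 1], iv[, 2] - 1L)]
  v_cu <- idx[iv]
  v_lin <- iv[, 1] + (iv[, 2] - 1L) * nx

  list(nx = nx, ny = ny, h = h, fluid = fluid, idx = idx, nf = nf,
       u_dof = u_dof, v_dof = v_dof, chol_A = chol_A,
       u_wall_up = u_wall_up, u_wall_dn = u_wall_dn,
       v_wall_rt = v_wall_rt, v_wall_lt = v_wall_lt,
       u_cl = u_cl, u_cr = u_cr, u_lin = u_lin,
       v_cd = v_cd, v_cu = v_cu, v_lin = v_lin,
       inlet_r = domain$inlets$pv_right$cells,
       inlet_l = domain$inlets$pv_left$cells,
       outlet = domain$outlet$cells,
       depth = domain$depth / 1000)
}

# periodic linear interpolants of the flux program, m^3/s
.flux_interp <- function(flux) {
  period <- attr(flux, "period")
  tt <- flux$time_s - flux$time_s[1]
  mk <- function(col) {
    f <- stats::approxfun(tt, flux[[col]] * 1e-6, rule = 2)
    function(t) f(t %% period)
  }
  list(r = mk("inflow_pv_right"), l = mk("inflow_pv_left"),
       period = period)
}

.shift <- function(M, di, dj) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(0, nr, nc)
  xs <- max(1, 1 + di):min(nr, nr + di)
  ys <- max(1, 1 + dj):min(nc, nc + dj)
  out[xs - di, ys - dj] <- M[xs, ys]
  out
}

#' Solve the pulsatile incompressible flow on a masked staggered grid
#'
#' Chorin-style fractional-step (projection) scheme on the 2d marker-
#' and-cell grid: explicit first-order-upwind advection and centered
#' diffusion, plug inflow profiles at the pulmonary-vein inlets, a
#' flux-balancing plug outflow at the cannula outlet, no-slip walls,
#' and an exact pressure projection by sparse Cholesky factorization.
#' The time step is sub-stepped automatically whenever the advective
#' CFL condition requires it.
#'
#' @param domain A 2d `flow_domain` from [build_domain()] or
#'   [channel_domain()].
#' @param flux A `flux_program` (see [make_flux_program()]).
#' @param fluid A [fluid_props()] object.
#' @param n_cycles Number of cardiac cycles to run (default 12).
#' @param n_init_cycles Leading cycles flagged as initialization and
#'   excluded from metric evaluation windows (default 4).
#' @param dt Time step, s; defaults to `period / 750`.
#' @param store_per_cycle Number of uniformly spaced velocity fields
#'   retained per cycle (default 50).
#' @param cfl CFL number targeted by the sub-stepping (default 0.7).
#' @param max_substeps Cap on sub-steps per step before erroring.
#' @return An object of class `flow_field`: stored staggered velocity
#'   fields `u` (m/s, `(nx+1) x ny`) and `v` (`nx x (ny+1)`), stored
#'   `times`, per-step residual history, and solver metadata.
#' @export
solve_flow <- function(domain, flux, fluid = fluid_props(),
                       n_cycles = 12, n_init_cycles = 4, dt = NULL,
                       store_per_cycle = 50, cfl = 0.7,
                       max_substeps = 50) {
  stopifnot(inherits(domain, "flow_domain"), inherits(flux, "flux_program"),
            inherits(fluid, "fluid_props"), n_cycles >= 1,
            n_init_cycles >= 0, n_init_cycles < n_cycles)
  if (domain$mode != "2d") {
    stop("the flow solver operates on 2d domains; 3d voxel domains serve geometry checks only")
  }
  s <- .solver_setup(domain)
  fx <- .flux_interp(flux)
  period <- fx$period
  if (is.null(dt)) dt <- period / 750
  n_steps_cycle <- round(period / dt)
  dt <- period / n_steps_cycle
  nu <- fluid$dynamic_viscosity / fluid$density
  h <- s$h
  if (nu * dt / h^2 > 0.2) {
    stop("time step violates the explicit diffusion stability limit on this grid")
  }
  a_in_r <- length(s$inlet_r) * h * s$depth
  a_in_l <- length(s$inlet_l) * h * s$depth
  a_out <- length(s$outlet) * h * s$depth

  nx <- s$nx; ny <- s$ny
  U <- matrix(0, nx + 1, ny)
  V <- matrix(0, nx, ny + 1)
  rho <- fluid$density

  store_every <- n_steps_cycle / store_per_cycle
  if (store_every != round(store_every)) {
    store_every <- max(1, floor(store_every))
  }
  n_store <- 0
  u_store <- list(); v_store <- list(); t_store <- numeric(0)
  res_time <- res_cont <- res_mu <- res_mv <- numeric(0)

  total_steps <- n_steps_cycle * n_cycles
  u_ref <- max(abs(c(flux$inflow_pv_right, flux$inflow_pv_left,
                     flux$outlet)) * 1e-6) / min(a_in_r, a_out)
  u_ref <- max(u_ref, 1e-9)

  div_of <- function(U, V) {
    (U[2:(nx + 1), , drop = FALSE] - U[1:nx, , drop = FALSE] +
       V[, 2:(ny + 1), drop = FALSE] - V[, 1:ny, drop = FALSE]) / h
  }

  for (step in seq_len(total_steps)) {
    t_now <- (step - 1) * dt
    q_r <- fx$r(t_now); q_l <- fx$l(t_now)
    # plug inflow (downward) at the roof, flux-balancing plug outflow
    if (length(s$inlet_r)) V[cbind(s$inlet_r, ny + 1)] <- -q_r / a_in_r
    if (length(s$inlet_l)) V[cbind(s$inlet_l, ny + 1)] <- -q_l / a_in_l
    V[cbind(s$outlet, 1L)] <- -(q_r + q_l) / a_out

    vmax <- max(abs(U)) + max(abs(V))
    nsub <- max(1L, ceiling(vmax * dt / (cfl * h)))
    if (nsub > max_substeps) {
      stop(sprintf("CFL sub-stepping cap exceeded at t = %.4f s (needed %d sub-steps)",
                   t_now, nsub))
    }
    dts <- dt / nsub
    U_prev <- U; V_prev <- V
    for (sub in seq_len(nsub)) {
      # -- u momentum --
      Uw <- .shift(U, -1, 0); Ue <- .shift(U, 1, 0)
      Uup <- .shift(U, 0, 1); Udn <- .shift(U, 0, -1)
      UupG <- ifelse(s$u_wall_up, -U, Uup)
      UdnG <- ifelse(s$u_wall_dn, -U, Udn)
      Uup0 <- ifelse(s$u_wall_up, 0, Uup)
      Udn0 <- ifelse(s$u_wall_dn, 0, Udn)
      Vp <- rbind(V, 0)                      # V at (i-1..) padded to nx+1
      Vbar <- 0.25 * (.shift(Vp[, 1:ny, drop = FALSE], -1, 0) +
                        .shift(Vp[, 2:(ny + 1), drop = FALSE], -1, 0) +
                        Vp[, 1:ny, drop = FALSE] +
                        Vp[, 2:(ny + 1), drop = FALSE])
      adv_u <- pmax(U, 0) * (U - Uw) / h + pmin(U, 0) * (Ue - U) / h +
        pmax(Vbar, 0) * (U - Udn0) / h + pmin(Vbar, 0) * (Uup0 - U) / h
      diff_u <- nu * (Ue - 2 * U + Uw + UupG - 2 * U + UdnG) / h^2
      # -- v momentum --
      Vdn <- .shift(V, 0, -1); Vup <- .shift(V, 0, 1)
      Vlt <- .shift(V, -1, 0); Vrt <- .shift(V, 1, 0)
      VltG <- ifelse(s$v_wall_lt, -V, Vlt)
      VrtG <- ifelse(s$v_wall_rt, -V, Vrt)
      Vlt0 <- ifelse(s$v_wall_lt, 0, Vlt)
      Vrt0 <- ifelse(s$v_wall_rt, 0, Vrt)
      # U at v-face (i,j): average of U[i,j-1], U[i+1,j-1], U[i,j], U[i+1,j]
      Uc1 <- U[1:nx, , drop = FALSE]; Uc2 <- U[2:(nx + 1), , drop = FALSE]
      Uy <- matrix(0, nx, ny + 1)
      Uy[, 2:ny] <- 0.25 * (Uc1[, 1:(ny - 1)] + Uc2[, 1:(ny - 1)] +
                              Uc1[, 2:ny] + Uc2[, 2:ny])
      adv_v <- pmax(Uy, 0) * (V - Vlt0) / h + pmin(Uy, 0) * (Vrt0 - V) / h +
        pmax(V, 0) * (V - Vdn) / h + pmin(V, 0) * (Vup - V) / h
      diff_v <- nu * (VrtG - 2 * V + VltG + Vup - 2 * V + Vdn) / h^2

      U[s$u_dof] <- U[s$u_dof] + dts * (-adv_u[s$u_dof] + diff_u[s$u_dof])
      V[s$v_dof] <- V[s$v_dof] + dts * (-adv_v[s$v_dof] + diff_v[s$v_dof])

      # -- projection --
      div <- div_of(U, V)
      b <- -(rho / dts) * div[s$fluid]
      p <- as.numeric(Matrix::solve(s$chol_A, b))
      U[s$u_lin] <- U[s$u_lin] - dts / rho * (p[s$u_cr] - p[s$u_cl]) / h
      V[s$v_lin] <- V[s$v_lin] - dts / rho * (p[s$v_cu] - p[s$v_cd]) / h
    }

    if (step %% store_every == 0) {
      n_store <- n_store + 1
      u_store[[n_store]] <- U
      v_store[[n_store]] <- V
      t_store[n_store] <- step * dt
      dv <- div_of(U, V)
      res_time[n_store] <- step * dt
      res_cont[n_store] <- max(abs(dv[s$fluid]))
      res_mu[n_store] <- max(abs(U - U_prev)) / u_ref
      res_mv[n_store] <- max(abs(V - V_prev)) / u_ref
    }
  }

  structure(list(
    u = u_store, v = v_store, times = t_store,
    residuals = data.frame(time_s = res_time,
                           continuity_max_div = res_cont,
                           x_momentum = res_mu, y_momentum = res_mv),
    dt = dt, period = period, n_cycles = n_cycles,
    n_init_cycles = n_init_cycles, store_per_cycle = store_per_cycle,
    stored_per_cycle = round(n_steps_cycle / store_every),
    domain = domain, fluid = fluid
  ), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field> %d stored instants over %d cycles (%d initialization), dt = %g s, max |div u| = %.2g 1/s\n",
    length(x$times), x$n_cycles, x$n_init_cycles, x$dt,
    max(x$residuals$continuity_max_div)))
  invisible(x)
}

#' Discrete divergence of a stored velocity field
#'
#' Recomputes the divergence of stored instant `k` directly from the
#' staggered velocity arrays; the projection contract is that its
#' maximum absolute value over fluid cells is at solver tolerance.
#'
#' @param field A `flow_field`.
#' @param k Stored-instant index.
#' @return An `nx x ny` matrix of divergence values, 1/s (`NA` outside
#'   the fluid).
#' @export
divergence_field <- function(field, k) {
  stopifnot(inherits(field, "flow_field"), k >= 1, k <= length(field$times))
  nx <- field$domain$dims[["nx"]]; ny <- field$domain$dims[["ny"]]
  h <- field$domain$h / 1000
  U <- field$u[[k]]; V <- field$v[[k]]
  d <- (U[2:(nx + 1), , drop = FALSE] - U[1:nx, , drop = FALSE] +
          V[, 2:(ny + 1), drop = FALSE] - V[, 1:ny, drop = FALSE]) / h
  d[field$domain$label == 0L] <- NA_real_
  d
}

#' Cell-centered speed of a stored velocity field
#'
#' @param field A `flow_field`.
#' @param k Stored-instant index.
#' @return An `nx x ny` matrix of velocity magnitude, m/s (`NA`
#'   outside the fluid).
#' @export
cell_speed <- function(field, k) {
  stopifnot(inherits(field, "flow_field"))
  nx <- field$domain$dims[["nx"]]; ny <- field$domain$dims[["ny"]]
  U <- field$u[[k]]; V <- field$v[[k]]
  uc <- 0.5 * (U[1:nx, , drop = FALSE] + U[2:(nx + 1), , drop = FALSE])
  vc <- 0.5 * (V[, 1:ny, drop = FALSE] + V[, 2:(ny + 1), drop = FALSE])
  sp <- sqrt(uc^2 + vc^2)
  sp[field$domain$label == 0L] <- NA_real_
  sp
}

#' Convergence report for a solved flow field
#'
#' Summarizes the per-step residual history: the continuity residual is
#' the maximum absolute discrete divergence (1/s), the momentum
#' residuals are the maximum velocity change per step normalized by the
#' boundary-program reference velocity.
#'
#' @param field A `flow_field`.
#' @param threshold Residual acceptance threshold for the normalized
#'   momentum residuals (default `1e-3`, the conventional CFD per-step
#'   criterion).
#' @return A list of class `convergence_report`.
#' @export
check_convergence <- function(field, threshold = 1e-3) {
  stopifnot(inherits(field, "flow_field"))
  r <- field$residuals
  n <- nrow(r)
  structure(list(
    threshold = threshold,
    max_continuity_div = max(r$continuity_max_div),
    max_x_momentum = max(r$x_momentum),
    max_y_momentum = max(r$y_momentum),
    all_below = all(r$x_momentum < threshold & r$y_momentum < threshold),
    final_below = r$x_momentum[n] < threshold & r$y_momentum[n] < threshold,
    history = r
  ), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf(
    "<convergence_report> max |div u| %.2g 1/s; momentum residuals x %.2g, y %.2g (threshold %g: %s)\n",
    x$max_continuity_div, x$max_x_momentum, x$max_y_momentum,
    x$threshold, if (x$all_below) "met" else "not met"))
  invisible(x)
}
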
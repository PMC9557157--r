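test_that("stagnation volume equals direct cell enumeration", {
  dom <- channel_domain(width = 2, length = 4, grid_spacing = 0.5,
                        out_of_plane_depth = 10)
  nx <- dom$dims[["nx"]]; ny <- dom$dims[["ny"]]
  # column-wise vertical speeds: two columns at 0.5 mm/s, two at 5 mm/s
  V <- matrix(rep(c(5e-4, 5e-4, 5e-3, 5e-3), ny + 1), nx, ny + 1)
  U <- matrix(0, nx + 1, ny)
  ff <- steady_synthetic_field(dom, U, V, cycles = 2, per_cycle = 5)
  got <- stagnation_volume(ff, threshold = 1)
  expect_equal(got[["la"]], nx * ny / 2 * dom$cell_volume / 1000)
  # independent plain-loop oracle
  idx <- which(ff$times > 0)
  expect_equal(got[["la"]], enumerate_stagnation(ff, dom, 1, idx))
  # uniform 10 mm/s: nothing stagnant; zero flow: everything stagnant
  ff_fast <- steady_synthetic_field(dom, U, matrix(1e-2, nx, ny + 1))
  expect_equal(stagnation_volume(ff_fast)[["la"]], 0)
  ff_zero <- steady_synthetic_field(dom, U, matrix(0, nx, ny + 1))
  expect_equal(stagnation_volume(ff_zero)[["la"]],
               nx * ny * dom$cell_volume / 1000)
  expect_error(stagnation_volume(ff, window = c(5, 6)), "empty")
})

test_that("magnitude vs vector time-averaging convention is exposed", {
  dom <- channel_domain(width = 2, length = 4, grid_spacing = 0.5,
                        out_of_plane_depth = 10)
  nx <- dom$dims[["nx"]]; ny <- dom$dims[["ny"]]
  U <- matrix(0, nx + 1, ny)
  Vp <- matrix(5e-3, nx, ny + 1)
  # oscillating but moving blood: +5 / -5 mm/s alternating instants
  ff <- synthetic_field(dom, rep(list(U), 4), list(Vp, -Vp, Vp, -Vp),
                        per_cycle = 4)
  expect_equal(stagnation_volume(ff, average = "magnitude")[["la"]], 0)
  expect_equal(stagnation_volume(ff, average = "vector")[["la"]],
               nx * ny * dom$cell_volume / 1000)
})

test_that("wall shear classification matches the analytic channel value", {
  ff <- poiseuille_field()
  dom <- ff$domain
  w <- wss_classify(ff)
  # bin completeness: areas sum exactly to the total wall area
  tot_row <- w$areas[w$areas$region == "total", c("low", "physiological", "high")]
  expect_equal(sum(tot_row), w$total_wall_area)
  # the developed channel at 5 mm/s mean has tau = 6 mu U / w = 0.021 Pa:
  # every wall face sits in the low non-physiological bin
  expect_equal(tot_row$low, w$total_wall_area)
  expect_equal(tot_row$high, 0)
  # expected wall area: two side walls of length ny*h at the configured depth
  ny <- dom$dims[["ny"]]
  expect_equal(w$total_wall_area, 2 * ny * dom$h * dom$depth / 100)

  # zero flow: everything in the low bin
  nx <- dom$dims[["nx"]]
  ff0 <- steady_synthetic_field(dom, matrix(0, nx + 1, ny),
                                matrix(0, nx, ny + 1))
  w0 <- wss_classify(ff0, fluid = fluid_props())
  expect_equal(w0$areas$low[w0$areas$region == "total"], w0$total_wall_area)
})

test_that("velocity statistics: hand-computable case and brute-force weighting", {
  dom <- channel_domain(width = 2, length = 3, grid_spacing = 0.5,
                        out_of_plane_depth = 10)
  nx <- dom$dims[["nx"]]; ny <- dom$dims[["ny"]]
  U <- matrix(0, nx + 1, ny)
  # speeds 1 cm/s then 3 cm/s everywhere: mean 2, population sd 1
  ff <- synthetic_field(dom, list(U, U),
                        list(matrix(0.01, nx, ny + 1),
                             matrix(0.03, nx, ny + 1)),
                        per_cycle = 2)
  vs <- velocity_stats(ff, region = "la")
  expect_equal(vs[["mean_cm_s"]], 2)
  expect_equal(vs[["sd_cm_s"]], 1)
  expect_error(velocity_stats(ff, region = "pouch"), "unknown region")

  # random fields against a plain-loop accumulation
  set.seed(42)
  v_list <- lapply(1:3, function(k) matrix(runif(nx * (ny + 1), 0, 0.02),
                                           nx, ny + 1))
  u_list <- lapply(1:3, function(k) matrix(runif((nx + 1) * ny, 0, 0.02),
                                           nx + 1, ny))
  ffr <- synthetic_field(dom, u_list, v_list, per_cycle = 3)
  got <- velocity_stats(ffr, region = "la")
  sp <- sapply(1:3, function(k) {
    uc <- 0.5 * (u_list[[k]][1:nx, ] + u_list[[k]][2:(nx + 1), ])
    vc <- 0.5 * (v_list[[k]][, 1:ny] + v_list[[k]][, 2:(ny + 1)])
    as.numeric(sqrt(uc^2 + vc^2))
  })
  want_mean <- mean(rowMeans(sp)) * 100
  want_sd <- mean(apply(sp, 1, function(x) sqrt(mean((x - mean(x))^2)))) * 100
  expect_equal(got[["mean_cm_s"]], want_mean)
  expect_equal(got[["sd_cm_s"]], want_sd, tolerance = 1e-12)
})

test_that("recirculation detector requires bidirectional neck exchange and slow pouch", {
  dom <- fixture("domain2d", build_domain(domain_config("2d")))
  nx <- dom$dims[["nx"]]; ny <- dom$dims[["ny"]]
  lab <- dom$label
  U <- matrix(0, nx + 1, ny)
  V <- matrix(0, nx, ny + 1)
  # brisk atrium, slow pouch (set the lower face of every LA cell)
  V[which(lab == 1L, arr.ind = TRUE)] <- -0.05
  # neck faces between LAA (left) and LA cells
  neck <- which(lab[1:(nx - 1), ] == 2L & lab[2:nx, ] == 1L, arr.ind = TRUE)
  stopifnot(nrow(neck) >= 2)
  flip <- rep(c(1e-3, -1e-3), length.out = nrow(neck))
  U[cbind(neck[, 1] + 1L, neck[, 2])] <- flip
  ff <- steady_synthetic_field(dom, U, V, cycles = 2, per_cycle = 10)

  # synthetic sinus-rhythm mitral diagnostic with E and A waves
  tt <- seq(0, 0.75, length.out = 101)
  q <- 300 * exp(-((tt - 0.42) / 0.05)^2) + 250 * exp(-((tt - 0.66) / 0.04)^2)
  fx <- structure(
    data.frame(time_s = tt, inflow_pv_right = 0.55 * q,
               inflow_pv_left = 0.45 * q, outlet = q,
               mitral_diagnostic = q),
    class = c("flux_program", "data.frame"), period = 0.75)

  det <- detect_laa_recirculation(ff, fx)
  expect_true(det$recirculating)
  expect_lt(det$laa_mean_speed_cm_s, det$atrium_mean_speed_cm_s)
  expect_gt(det$diastasis_phase, 0.42 / 0.75)
  expect_lt(det$diastasis_phase, 0.66 / 0.75)

  # unidirectional neck flow is not a recirculation pocket
  U2 <- U
  U2[cbind(neck[, 1] + 1L, neck[, 2])] <- 1e-3
  ff2 <- steady_synthetic_field(dom, U2, V, cycles = 2, per_cycle = 10)
  expect_false(detect_laa_recirculation(ff2, fx)$recirculating)

  occl <- build_domain(domain_config("2d", occluded = TRUE))
  z <- zero_uv(occl)
  expect_error(
    detect_laa_recirculation(steady_synthetic_field(occl, z$u, z$v), fx),
    "no appendage")
})
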
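#' Mitral valve shape parameters
#'
#' Parameters of the parametric open mitral-valve surface. The surface
#' is swept by an angular coordinate `theta` around the annulus and a
#' leaflet coordinate `s` from the annulus (`s = 0`) to the free edge
#' (`s = 1`).
#'
#' @param R Annulus radius, mm. The default, 13 mm, is half the
#'   synthetic flow domain's default mitral orifice diameter (see
#'   [domain_config()]).
#' @param epsilon Symmetry ratio between anterior and posterior leaflet,
#'   dimensionless, in `[0, 1)`. Default 0.35.
#' @param k Ellipticity of the valvular free edge, dimensionless, in
#'   `(0, 1]`. Default 0.6.
#' @param phi Opening angle, degrees, in `(0, 90)`. Default 60.
#' @param n_theta Number of angular samples over `[0, 2*pi)`. Default 100.
#' @param n_s Number of leaflet samples over `[0, 1]`. Default 40.
#' @param z_grouping Reading of the axial profile equation: `"half-s"`
#'   (default, the committed convention: a leading factor `s/2` with
#'   squared ellipticity terms) or `"half-k"` (alternative reading with
#'   `(1 + k)/2` and `(1 - k)/2` coefficients).
#' @return An object of class `valve_shape_params`.
#' @export
valve_shape_params <- function(R = 13, epsilon = 0.35, k = 0.6, phi = 60,
                               n_theta = 100, n_s = 40,
                               z_grouping = c("half-s", "half-k")) {
  z_grouping <- match.arg(z_grouping)
  stopifnot(R > 0, epsilon >= 0, epsilon < 1, k > 0, k <= 1,
            phi > 0, phi < 90, n_theta >= 3, n_s >= 2)
  structure(list(R = R, epsilon = epsilon, k = k, phi = phi,
                 n_theta = n_theta, n_s = n_s, z_grouping = z_grouping),
            class = "valve_shape_params")
}

#' Evaluate the parametric valve surface at (theta, s)
#'
#' The surface is, with `phi` in radians and writing `e` for `epsilon`:
#' \deqn{x = R\cos\theta\,(1 - s\cos\varphi) - e R s \cos\varphi}
#' \deqn{y = R\sin\theta\,(1 - s k \cos\varphi)}
#' \deqn{z = -\tfrac{s}{2}\left[(1 + k^2) + e\cos\theta +
#'   (1 - k^2)\cos 2\theta\right] R \sin\varphi}
#' At `s = 0` all leaflet terms vanish and the point lies on the
#' circular annulus of radius `R` in the `z = 0` plane.
#'
#' @param theta Angular coordinate, radians (vectorized).
#' @param s Leaflet coordinate in `[0, 1]` (vectorized, recycled
#'   against `theta`).
#' @param p A [valve_shape_params()] object.
#' @return A matrix with columns `x`, `y`, `z` in mm.
#' @export
valve_point <- function(theta, s, p) {
  stopifnot(all(s >= 0), all(s <= 1))
  phi <- p$phi * pi / 180
  cphi <- cos(phi)
  sphi <- sin(phi)
  x <- p$R * cos(theta) * (1 - s * cphi) - p$epsilon * p$R * s * cphi
  y <- p$R * sin(theta) * (1 - s * p$k * cphi)
  zprof <- if (p$z_grouping == "half-s") {
    (s / 2) * ((1 + p$k^2) + p$epsilon * cos(theta) +
                 (1 - p$k^2) * cos(2 * theta))
  } else {
    s * ((1 + p$k) / 2 + p$epsilon * cos(theta) +
           (1 - p$k) / 2 * cos(2 * theta))
  }
  z <- -zprof * p$R * sphi
  cbind(x = x, y = y, z = z)
}

#' Build the triangulated valve surface mesh
#'
#' Samples the parametric surface on an `n_theta` x `n_s` grid
#' (`theta` uniform over `[0, 2*pi)`, `s` uniform over `[0, 1]`) and
#' triangulates each grid quad, closing the strip in `theta`.
#'
#' @param p A [valve_shape_params()] object.
#' @return An object of class `valve_surface`: a list with `vertices`
#'   (`n_theta * n_s` x 3 matrix, mm), `faces` (triangle index matrix,
#'   1-based), `params`, and `placement` (4x4 rigid transform, identity
#'   until [place_valve()] is applied).
#' @export
build_valve_mesh <- function(p) {
  stopifnot(inherits(p, "valve_shape_params"))
  theta <- seq(0, 2 * pi, length.out = p$n_theta + 1)[-(p$n_theta + 1)]
  s <- seq(0, 1, length.out = p$n_s)
  grid <- expand.grid(theta = theta, s = s)
  verts <- valve_point(grid$theta, grid$s, p)
  idx <- function(i, j) (j - 1) * p$n_theta + i   # i in theta, j in s
  i <- rep(seq_len(p$n_theta), p$n_s - 1)
  j <- rep(seq_len(p$n_s - 1), each = p$n_theta)
  ip1 <- ifelse(i == p$n_theta, 1L, i + 1L)
  faces <- rbind(
    cbind(idx(i, j), idx(ip1, j), idx(ip1, j + 1)),
    cbind(idx(i, j), idx(ip1, j + 1), idx(i, j + 1))
  )
  areas <- .triangle_areas(verts, faces)
  if (any(areas <= 0)) {
    # shrinking free edge can produce needle triangles for extreme params
    warning(sprintf("%d degenerate (zero-area) faces in valve mesh",
                    sum(areas <= 0)))
  }
  structure(list(vertices = verts, faces = faces, params = p,
                 placement = diag(4)),
            class = "valve_surface")
}

.triangle_areas <- function(v, f) {
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a valve mesh
#'
#' @param mesh A `valve_surface`.
#' @return Area in mm^2.
#' @export
valve_surface_area <- function(mesh) {
  sum(.triangle_areas(mesh$vertices, mesh$faces))
}

#' Rigidly place a valve mesh at an anatomical position
#'
#' Moves the valve so that its annulus center sits at `origin` with the
#' annulus plane perpendicular to `normal`; `reference_direction`
#' (projected onto the annulus plane) fixes the in-plane rotation of
#' the `theta = 0` axis. The transform is rigid: all pairwise distances
#' are preserved.
#'
#' @param mesh A `valve_surface`.
#' @param origin Length-3 target position of the annulus center, mm.
#' @param normal Length-3 annulus plane normal (need not be unit).
#' @param reference_direction Length-3 direction (not parallel to
#'   `normal`) that the local x axis is aligned with in the plane.
#' @return The transformed `valve_surface` with its `placement` updated.
#' @export
place_valve <- function(mesh, origin = c(0, 0, 0), normal = c(0, 0, 1),
                        reference_direction = c(1, 0, 0)) {
  stopifnot(inherits(mesh, "valve_surface"),
            length(origin) == 3, length(normal) == 3,
            length(reference_direction) == 3)
  n <- normal / sqrt(sum(normal^2))
  r <- reference_direction - sum(reference_direction * n) * n
  if (sqrt(sum(r^2)) < 1e-12) {
    stop("reference_direction must not be parallel to normal")
  }
  ex <- r / sqrt(sum(r^2))
  ey <- c(n[2] * ex[3] - n[3] * ex[2],
          n[3] * ex[1] - n[1] * ex[3],
          n[1] * ex[2] - n[2] * ex[1])
  rot <- cbind(ex, ey, n)
  tf <- diag(4)
  tf[1:3, 1:3] <- rot
  tf[1:3, 4] <- origin
  out <- mesh
  out$vertices <- sweep(mesh$vertices %*% t(rot), 2, origin, `+`)
  colnames(out$vertices) <- c("x", "y", "z")
  out$placement <- tf %*% mesh$placement
  out
}

#' Write a triangulated surface as ASCII STL
#'
#' @param mesh A `valve_surface` (or any list with `vertices`/`faces`).
#' @param path Output file path.
#' @param name Solid name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_stl_ascii <- function(mesh, path, name = "surface") {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  ny <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  nz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  nrm <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (t in seq_len(nrow(f))) {
    writeLines(c(
      sprintf("  facet normal %g %g %g", nx[t] / nrm[t], ny[t] / nrm[t],
              nz[t] / nrm[t]),
      "    outer loop",
      sprintf("      vertex %g %g %g", v[f[t, 1:3], 1], v[f[t, 1:3], 2],
              v[f[t, 1:3], 3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Write a triangulated surface as legacy ASCII VTK polydata
#'
#' @inheritParams write_stl_ascii
#' @return `path`, invisibly.
#' @export
write_vtk_polydata <- function(mesh, path, name = "surface") {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", name, "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
  invisible(path)
}

#' @export
print.valve_surface <- function(x, ...) {
  cat(sprintf(
    "<valve_surface> %d vertices, %d triangles (R = %g mm, epsilon = %g, k = %g, phi = %g deg)\n",
    nrow(x$vertices), nrow(x$faces), x$params$R, x$params$epsilon,
    x$params$k, x$params$phi))
  invisible(x)
}
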
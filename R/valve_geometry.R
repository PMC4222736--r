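# Parametric one-sixth aortic-root geometry: validated scalar parameters,
# the revolved sinus-wall profile, and surface-mesh export for inspection.
# Only the annulus area feeds the ejection model; leaflet dimensions are
# validated and carried as metadata (leaflet behaviour is abstracted into the
# ejection model's opening state, so leaflet surfaces are never meshed).

#' Parametric aortic valve/root geometry
#'
#' Scalar parameters of the aortic root and valve measured at maximum valve
#' opening: annulus base radius, commissure radius, valve and sinus heights,
#' leaflet height and free-edge length, the sinus-of-Valsalva maximum radius
#' and its axial location, and the uniform leaflet thickness. All in mm.
#'
#' @param base_radius_mm radius of the annulus base (Rb).
#' @param commissure_radius_mm radius at the commissures (Rc).
#' @param valve_height_mm valve height (H).
#' @param sinus_height_mm sinus height (Hs); the profile spans `[0, Hs]`.
#' @param leaflet_height_mm leaflet height (metadata only).
#' @param leaflet_free_edge_mm leaflet free-edge length (metadata only).
#' @param sinus_max_radius_mm maximum sinus radius (Ds).
#' @param sinus_max_location_mm axial location of the sinus bulge (Zs < Hs).
#' @param leaflet_thickness_mm uniform leaflet thickness (metadata only).
#' @return a validated `valve_geometry_params` list.
#' @export
#' @examples
#' load_fixture("table1")
valve_geometry_params <- function(base_radius_mm,
                                  commissure_radius_mm,
                                  valve_height_mm,
                                  sinus_height_mm,
                                  leaflet_height_mm,
                                  leaflet_free_edge_mm,
                                  sinus_max_radius_mm,
                                  sinus_max_location_mm,
                                  leaflet_thickness_mm = 0.6) {
  p <- list(base_radius_mm = base_radius_mm,
            commissure_radius_mm = commissure_radius_mm,
            valve_height_mm = valve_height_mm,
            sinus_height_mm = sinus_height_mm,
            leaflet_height_mm = leaflet_height_mm,
            leaflet_free_edge_mm = leaflet_free_edge_mm,
            sinus_max_radius_mm = sinus_max_radius_mm,
            sinus_max_location_mm = sinus_max_location_mm,
            leaflet_thickness_mm = leaflet_thickness_mm)
  for (nm in names(p)) check_positive(p[[nm]], nm)
  if (sinus_max_location_mm >= sinus_height_mm) {
    stop("sinus_max_location_mm must be below sinus_height_mm", call. = FALSE)
  }
  if (sinus_max_radius_mm < commissure_radius_mm ||
      sinus_max_radius_mm < base_radius_mm) {
    stop("sinus_max_radius_mm must be >= both base and commissure radii",
         call. = FALSE)
  }
  if (leaflet_height_mm >= 2 * sinus_max_radius_mm ||
      leaflet_free_edge_mm >= 2 * sinus_max_radius_mm) {
    stop("leaflet dimensions exceed the sinus diameter", call. = FALSE)
  }
  structure(p, class = "valve_geometry_params")
}

#' Annulus (maximum effective orifice) area
#'
#' Circular annulus area `pi * Rb^2`, returned in SI units. This is the
#' maximum effective orifice area used by the ejection model.
#'
#' @param params a [valve_geometry_params()].
#' @return area in m^2.
#' @export
#' @examples
#' annulus_area(load_fixture("table1"))
annulus_area <- function(params) {
  stopifnot(inherits(params, "valve_geometry_params"))
  pi * (params$base_radius_mm * 1e-3)^2
}

#' Sinus-wall radius profile
#'
#' Smooth radial profile of the aortic-root wall versus axial position: a
#' shape-preserving piecewise-cubic (pchip) interpolant through the three
#' measured anchors, `r(0) = Rb`, `r(Zs) = Ds`, `r(Hs) = Rc`. The interpolant
#' is continuously differentiable, monotone on each side of the bulge, and
#' attains its maximum exactly at `z = Zs` (the slope vanishes there because
#' the adjacent secant slopes change sign).
#'
#' @param params a [valve_geometry_params()].
#' @param z axial position(s) in mm, within `[0, Hs]`.
#' @return wall radius in mm at each `z`.
#' @export
#' @examples
#' p <- load_fixture("table1")
#' sinus_profile(p, c(0, p$sinus_max_location_mm, p$sinus_height_mm))
sinus_profile <- function(params, z) {
  stopifnot(inherits(params, "valve_geometry_params"))
  if (any(!is.finite(z)) || any(z < 0) || any(z > params$sinus_height_mm)) {
    stop(sprintf("z must lie within [0, %g] mm", params$sinus_height_mm),
         call. = FALSE)
  }
  zi <- c(0, params$sinus_max_location_mm, params$sinus_height_mm)
  ri <- c(params$base_radius_mm, params$sinus_max_radius_mm,
          params$commissure_radius_mm)
  signal::pchip(zi, ri, z)
}

#' Build a surface mesh of one 60-degree root wedge
#'
#' Revolves [sinus_profile()] through a 60-degree wedge (one-sixth of the
#' root, matching the tri-leaflet symmetry) into a structured triangle mesh.
#' Deterministic for fixed inputs; intended for inspection and export, not
#' for simulation.
#'
#' @param params a [valve_geometry_params()].
#' @param resolution segments per edge (axial and angular); at least 4.
#' @param replicas number of 60-degree wedges to tile about the axis (1-6).
#' @return a `valve_mesh` list with `vertices` (n x 3 matrix, mm),
#'   `faces` (m x 3 integer matrix, 1-based), `wedge_angle_deg` and
#'   `angular_span_deg`.
#' @export
#' @examples
#' m <- build_wedge_mesh(load_fixture("table1"), resolution = 8)
#' range(sqrt(m$vertices[, 1]^2 + m$vertices[, 2]^2))
build_wedge_mesh <- function(params, resolution = 32, replicas = 1) {
  stopifnot(inherits(params, "valve_geometry_params"))
  if (!is.numeric(resolution) || resolution < 4) {
    stop("resolution must be >= 4 segments per edge", call. = FALSE)
  }
  if (!replicas %in% 1:6) stop("replicas must be 1..6", call. = FALSE)
  resolution <- as.integer(resolution)
  z <- seq(0, params$sinus_height_mm, length.out = resolution + 1)
  r <- sinus_profile(params, z)
  wedge <- pi / 3
  theta <- seq(0, replicas * wedge, length.out = replicas * resolution + 1)
  nz <- length(z); nt <- length(theta)
  grid_idx <- function(i, j) (j - 1L) * nz + i  # i axial, j angular
  verts <- cbind(
    x = rep(r, times = nt) * cos(rep(theta, each = nz)),
    y = rep(r, times = nt) * sin(rep(theta, each = nz)),
    z = rep(z, times = nt)
  )
  faces <- matrix(0L, nrow = 2L * (nz - 1L) * (nt - 1L), ncol = 3L)
  k <- 1L
  for (j in seq_len(nt - 1L)) {
    for (i in seq_len(nz - 1L)) {
      a <- grid_idx(i, j); b <- grid_idx(i + 1L, j)
      c2 <- grid_idx(i + 1L, j + 1L); d <- grid_idx(i, j + 1L)
      faces[k, ] <- c(a, b, c2); faces[k + 1L, ] <- c(a, c2, d)
      k <- k + 2L
    }
  }
  structure(list(vertices = verts, faces = faces,
                 wedge_angle_deg = 60,
                 angular_span_deg = replicas * 60),
            class = "valve_mesh")
}

#' Export a valve mesh to OFF or ASCII STL
#'
#' Plain-text surface formats readable by standard mesh viewers.
#'
#' @param mesh a `valve_mesh` from [build_wedge_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "valve_mesh"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    sprintf("%.6f %.6f %.6f", v[1], v[2], v[3])), con)
  writeLines(apply(mesh$faces, 1, function(f)
    sprintf("3 %d %d %d", f[1] - 1L, f[2] - 1L, f[3] - 1L)), con)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
write_mesh_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "valve_mesh"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid valve_wedge", con)
  v <- mesh$vertices
  for (k in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[k, ]
    p1 <- v[f[1], ]; p2 <- v[f[2], ]; p3 <- v[f[3], ]
    n <- c((p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
           (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
           (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(sprintf("  facet normal %.6e %.6e %.6e", n[1], n[2], n[3]), con)
    writeLines("    outer loop", con)
    for (p in list(p1, p2, p3)) {
      writeLines(sprintf("      vertex %.6e %.6e %.6e", p[1], p[2], p[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid valve_wedge", con)
  invisible(path)
}
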
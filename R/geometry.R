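# Synthetic vessel geometry: tetrahedral tube/sinusoid generators emulating
# the reconstructed bone-marrow vessel anatomies, plus simplified surface
# operators (inward offset, volume-preserving smoothing) standing in for the
# CAD surface-processing chain.
#
# Coordinate convention: vessel axis = z, origin at end_A; all lengths in um.

#' Vessel specification
#'
#' Describes a synthetic vessel for the mesh generators. Per-class defaults
#' follow the study geometries: artery L = 200 um with 14.3 um wall,
#' arteriole L = 200 um with 5 um wall, sinusoid L = 300 um with the wall
#' ignored and a surrounding marrow annulus. Lumen radii default to
#' artery 15, arteriole 10, sinusoid 20 um (configuration, not measured
#' values). The default marrow annulus outer radius is 100 um, a desk-scale
#' truncation of the much larger marrow cavity justified by far-field decay.
#'
#' @param vessel_class `"artery"`, `"arteriole"` or `"sinusoid"`.
#' @param length vessel length (um).
#' @param lumen_radius lumen radius (um).
#' @param wall_thickness wall thickness (um); forced to 0 for sinusoids.
#' @param marrow_outer_radius outer radius of the marrow annulus (sinusoid
#'   only, um).
#' @param resolution optional integer triple
#'   `c(n_radial, n_circumferential, n_axial)` of element layers; derived
#'   from `characteristic_edge` when `NULL`.
#' @param characteristic_edge target element edge length (um), default 3.
#' @param centerline_wiggle_amplitude amplitude (um) of the smooth random
#'   centerline irregularity applied after meshing (0 = straight).
#' @param wiggle_wavelength axial wavelength (um) of the irregularity.
#' @param seed integer seed controlling the irregularity field.
#' @return object of class `vessel_spec`.
#' @export
vesselSpec <- function(vessel_class,
                       length = NULL, lumen_radius = NULL,
                       wall_thickness = NULL, marrow_outer_radius = NULL,
                       resolution = NULL, characteristic_edge = 3,
                       centerline_wiggle_amplitude = 0,
                       wiggle_wavelength = 80, seed = 1L) {
  if (!vessel_class %in% c("artery", "arteriole", "sinusoid"))
    stop("invalid spec: unknown vessel_class '", vessel_class, "'")
  defaults <- switch(vessel_class,
    artery    = list(length = 200, lumen_radius = 15, wall_thickness = 14.3,
                     marrow_outer_radius = NA_real_),
    arteriole = list(length = 200, lumen_radius = 10, wall_thickness = 5,
                     marrow_outer_radius = NA_real_),
    sinusoid  = list(length = 300, lumen_radius = 20, wall_thickness = 0,
                     marrow_outer_radius = 100))
  if (is.null(length)) length <- defaults$length
  if (is.null(lumen_radius)) lumen_radius <- defaults$lumen_radius
  if (is.null(wall_thickness)) wall_thickness <- defaults$wall_thickness
  if (is.null(marrow_outer_radius)) marrow_outer_radius <- defaults$marrow_outer_radius
  if (vessel_class == "sinusoid") wall_thickness <- 0
  if (length <= 0 || lumen_radius <= 0)
    stop("invalid spec: length and lumen_radius must be positive")
  if (wall_thickness < 0) stop("invalid spec: wall_thickness must be >= 0")
  if (centerline_wiggle_amplitude < 0)
    stop("invalid spec: wiggle amplitude must be >= 0")
  structure(list(vessel_class = vessel_class, length = length,
                 lumen_radius = lumen_radius, wall_thickness = wall_thickness,
                 marrow_outer_radius = marrow_outer_radius,
                 resolution = resolution,
                 characteristic_edge = characteristic_edge,
                 centerline_wiggle_amplitude = centerline_wiggle_amplitude,
                 wiggle_wavelength = wiggle_wavelength,
                 seed = as.integer(seed)),
            class = "vessel_spec")
}

# ---- cross-section triangulation and prism extrusion ------------------------

# Triangulated disk/annulus cross-section: a centre node (when filled) plus
# concentric rings, all rings sharing the same n_circ angular positions.
# Returns list(points (P x 2), tris (T x 3), ring_radius per node, region per tri).
cross_section <- function(ring_radii, n_circ, regions_between, filled = TRUE) {
  K <- length(ring_radii)
  ang <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  pts <- matrix(0, nrow = (if (filled) 1 else 0) + K * n_circ, ncol = 2)
  rad <- numeric(nrow(pts))
  off <- if (filled) 1L else 0L
  for (k in seq_len(K)) {
    idx <- off + (k - 1L) * n_circ + seq_len(n_circ)
    pts[idx, 1] <- ring_radii[k] * cos(ang)
    pts[idx, 2] <- ring_radii[k] * sin(ang)
    rad[idx] <- ring_radii[k]
  }
  ring_id <- function(k, i) off + (k - 1L) * n_circ + ((i - 1L) %% n_circ) + 1L
  tris <- list(); region <- character(0)
  if (filled) {
    i <- seq_len(n_circ)
    tris[[1]] <- cbind(1L, ring_id(1, i), ring_id(1, i + 1))
    region <- c(region, rep(regions_between[1], n_circ))
  }
  for (k in seq_len(K - 1)) {
    i <- seq_len(n_circ)
    a <- ring_id(k, i); b <- ring_id(k, i + 1)
    cc <- ring_id(k + 1, i + 1); d <- ring_id(k + 1, i)
    # fixed diagonal a-cc
    tris[[length(tris) + 1]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
    reg <- regions_between[if (filled) k + 1 else k]
    region <- c(region, rep(reg, 2 * n_circ))
  }
  list(points = pts, tris = do.call(rbind, tris), radius = rad, region = region)
}

# Split a straight prism (bottom b1 b2 b3, top t1 t2 t3; global node ids)
# into 3 tets using the smallest-global-index diagonal rule, which makes the
# split conformal across shared quad faces of any prism mesh.
split_prisms <- function(bot, top) {
  M <- nrow(bot)
  v <- cbind(bot, top) # columns 1:3 bottom, 4:6 top
  out <- matrix(0L, nrow = 3 * M, ncol = 4)
  for (m in seq_len(M)) {
    p <- v[m, ]
    imin <- which.min(p)
    if (imin > 3) { # mirror so the global minimum lies on the bottom
      p <- p[c(4L, 5L, 6L, 1L, 2L, 3L)]
      imin <- imin - 3L
    }
    rot <- switch(imin, c(1L, 2L, 3L, 4L, 5L, 6L),
                        c(2L, 3L, 1L, 5L, 6L, 4L),
                        c(3L, 1L, 2L, 6L, 4L, 5L))
    p <- p[rot]
    # quad face (p2, p3, p6, p5): diagonal through its smallest index
    q <- p[c(2L, 3L, 5L, 6L)]
    if (which.min(q) %in% c(1L, 4L)) { # diagonal p2-p6
      tets <- rbind(p[c(1L, 2L, 3L, 6L)], p[c(1L, 2L, 6L, 5L)], p[c(1L, 5L, 6L, 4L)])
    } else {                          # diagonal p3-p5
      tets <- rbind(p[c(1L, 2L, 3L, 5L)], p[c(1L, 5L, 3L, 6L)], p[c(1L, 5L, 6L, 4L)])
    }
    out[3L * (m - 1L) + 1:3, ] <- tets
  }
  out
}

#' Signed tetrahedron volumes
#'
#' @param nodes N x 3 node coordinates.
#' @param tets M x 4 node indices.
#' @return length-M vector of signed volumes (positive for well-oriented tets).
#' @export
tetVolumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c3 <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c3[, 2] * d[, 3] - c3[, 3] * d[, 2]) -
   b[, 2] * (c3[, 1] * d[, 3] - c3[, 3] * d[, 1]) +
   b[, 3] * (c3[, 1] * d[, 2] - c3[, 2] * d[, 1])) / 6
}

fix_orientation <- function(nodes, tets) {
  v <- tetVolumes(nodes, tets)
  neg <- v < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  tets
}

# Boundary faces of a tet subset: faces used exactly once, oriented outward,
# with the owning (global) tet index attached as attr "owner".
region_boundary_faces <- function(nodes, tets, tet_ids = seq_len(nrow(tets))) {
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
                 tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  owner <- rep(seq_len(nrow(tets)), 4)
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "_"))
  cnt <- table(key)
  bnd <- cnt[key] == 1
  f <- faces[bnd, , drop = FALSE]
  own <- owner[bnd]
  # orient outward: normal away from owning tet centroid
  cent_t <- (nodes[tets[own, 1], , drop = FALSE] + nodes[tets[own, 2], , drop = FALSE] +
             nodes[tets[own, 3], , drop = FALSE] + nodes[tets[own, 4], , drop = FALSE]) / 4
  p1 <- nodes[f[, 1], , drop = FALSE]
  e1 <- nodes[f[, 2], , drop = FALSE] - p1
  e2 <- nodes[f[, 3], , drop = FALSE] - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cent_f <- (p1 + nodes[f[, 2], , drop = FALSE] + nodes[f[, 3], , drop = FALSE]) / 3
  flip <- rowSums(n * (cent_f - cent_t)) < 0
  f[flip, c(2, 3)] <- f[flip, c(3, 2)]
  attr(f, "owner") <- tet_ids[own]
  f
}

subset_faces <- function(f, keep) {
  out <- f[keep, , drop = FALSE]
  attr(out, "owner") <- attr(f, "owner")[keep]
  out
}

build_vessel_mesh <- function(spec, ring_radii, regions_between, filled,
                              n_circ, n_axial, radius_marks) {
  cs <- cross_section(ring_radii, n_circ, regions_between, filled)
  npts <- nrow(cs$points)
  L <- spec$length
  z <- L * (0:n_axial) / n_axial
  nodes <- cbind(cs$points[rep(seq_len(npts), n_axial + 1), , drop = FALSE],
                 rep(z, each = npts))
  ntri <- nrow(cs$tris)
  tets <- vector("list", n_axial)
  for (iz in seq_len(n_axial)) {
    bot <- cs$tris + (iz - 1L) * npts
    top <- cs$tris + iz * npts
    tets[[iz]] <- split_prisms(bot, top)
  }
  tets <- do.call(rbind, tets)
  region <- rep(rep(cs$region, each = 3), times = n_axial)
  tets <- fix_orientation(nodes, tets)

  rad <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
  tolr <- 1e-8 * max(ring_radii)
  on_radius <- function(f, r) {
    matrix(abs(rad[f] - r) < tolr + 1e-9, ncol = 3)
  }
  all_on <- function(f, r) rowSums(on_radius(f, r)) == 3L

  surface_sets <- list()
  # global boundary faces
  gb <- region_boundary_faces(nodes, tets)
  zb <- matrix(nodes[gb, 3], ncol = 3)
  surface_sets$end_A <- subset_faces(gb, rowSums(abs(zb) < 1e-9 * L) == 3L)
  surface_sets$end_B <- subset_faces(gb, rowSums(abs(zb - L) < 1e-9 * L) == 3L)
  outer_r <- ring_radii[length(ring_radii)]
  outer_faces <- subset_faces(gb, all_on(gb, outer_r))
  if (spec$vessel_class == "sinusoid") {
    surface_sets$marrow_outer <- outer_faces
    # inner lumen: marrow-region boundary faces at the blood/marrow interface
    sel <- which(region == "marrow")
    mb <- region_boundary_faces(nodes, tets[sel, , drop = FALSE], sel)
    surface_sets$inner_lumen <- subset_faces(mb, all_on(mb, spec$lumen_radius))
  } else {
    surface_sets$outer_wall <- outer_faces
    sel <- which(region == "wall")
    wb <- region_boundary_faces(nodes, tets[sel, , drop = FALSE], sel)
    surface_sets$inner_lumen <- subset_faces(wb, all_on(wb, spec$lumen_radius))
  }
  node_sets <- lapply(surface_sets, function(f) sort(unique(as.vector(f))))

  mesh <- structure(list(nodes = nodes, tets = tets, region = region,
                         surface_sets = surface_sets, node_sets = node_sets,
                         characteristic_edge = spec$characteristic_edge,
                         spec = spec, length = L,
                         lumen_radius = spec$lumen_radius,
                         outer_radius = outer_r),
                    class = "vessel_mesh")
  if (spec$centerline_wiggle_amplitude > 0) {
    mesh <- perturbCenterline(mesh, spec$centerline_wiggle_amplitude,
                              spec$wiggle_wavelength, spec$seed)
  }
  mesh
}

#' Synthetic vessel tube mesh (arteriole or artery)
#'
#' Builds a straight tube of length `L`: a blood region filling the lumen
#' plus a hyperelastic wall annulus of the given thickness, meshed by
#' extruding a triangulated disk cross-section into prisms and splitting
#' each prism into three tetrahedra with a deterministic, conformal
#' smallest-index diagonal rule. Surface sets `inner_lumen`, `outer_wall`,
#' `end_A` (z = 0) and `end_B` (z = L) are populated.
#'
#' @param spec a [vesselSpec()] with `vessel_class` `"artery"` or
#'   `"arteriole"` and positive wall thickness.
#' @return object of class `vessel_mesh`.
#' @export
makeTubeMesh <- function(spec) {
  if (!inherits(spec, "vessel_spec")) stop("spec must be a vessel_spec")
  if (!spec$vessel_class %in% c("artery", "arteriole"))
    stop("invalid spec: makeTubeMesh requires an artery or arteriole")
  if (spec$wall_thickness <= 0)
    stop("invalid spec: wall thickness must be positive for ",
         spec$vessel_class)
  h <- spec$characteristic_edge
  rl <- spec$lumen_radius; t <- spec$wall_thickness
  if (is.null(spec$resolution)) {
    n_wall <- max(2L, round(t / h))
    n_blood <- max(1L, round(rl / h))
    n_circ <- max(8L, round(2 * pi * (rl + t / 2) / h))
    n_axial <- max(2L, round(spec$length / h))
  } else {
    res <- spec$resolution
    n_rad <- res[1]; n_circ <- res[2]; n_axial <- res[3]
    n_wall <- round(n_rad * t / (rl + t))
    if (n_wall < 2L)
      stop("invalid spec: resolution too coarse to resolve the wall ",
           "(fewer than 2 radial element layers in the wall)")
    n_blood <- max(1L, n_rad - n_wall)
  }
  ring_radii <- c(rl * seq_len(n_blood) / n_blood,
                  rl + t * seq_len(n_wall) / n_wall)
  regions <- c(rep("blood", n_blood), rep("wall", n_wall))
  build_vessel_mesh(spec, ring_radii, regions, filled = TRUE,
                    n_circ = n_circ, n_axial = n_axial)
}

#' Synthetic sinusoid domain (blood lumen in a marrow annulus)
#'
#' The sinusoid endothelium is mechanically ignored: the domain is a blood
#' cylinder embedded concentrically in a linear-elastic marrow annulus, with
#' surface sets `inner_lumen` (blood/marrow interface), `marrow_outer`,
#' `end_A` and `end_B`.
#'
#' @param spec a [vesselSpec()] with `vessel_class = "sinusoid"` and
#'   `marrow_outer_radius > lumen_radius`.
#' @return object of class `vessel_mesh`.
#' @export
makeSinusoidDomain <- function(spec) {
  if (!inherits(spec, "vessel_spec")) stop("spec must be a vessel_spec")
  if (spec$vessel_class != "sinusoid")
    stop("invalid spec: makeSinusoidDomain requires vessel_class 'sinusoid'")
  rl <- spec$lumen_radius; ro <- spec$marrow_outer_radius
  if (is.na(ro) || ro <= rl)
    stop("invalid spec: marrow_outer_radius must exceed lumen_radius")
  h <- spec$characteristic_edge
  if (is.null(spec$resolution)) {
    n_blood <- max(1L, round(rl / h))
    n_marrow <- max(2L, round((ro - rl) / h))
    n_circ <- max(8L, round(2 * pi * rl / h) * 2L)
    n_axial <- max(2L, round(spec$length / h))
  } else {
    res <- spec$resolution
    n_circ <- res[2]; n_axial <- res[3]
    n_blood <- max(1L, round(res[1] * rl / ro))
    n_marrow <- max(2L, res[1] - n_blood)
  }
  ring_radii <- c(rl * seq_len(n_blood) / n_blood,
                  rl + (ro - rl) * seq_len(n_marrow) / n_marrow)
  regions <- c(rep("blood", n_blood), rep("marrow", n_marrow))
  build_vessel_mesh(spec, ring_radii, regions, filled = TRUE,
                    n_circ = n_circ, n_axial = n_axial)
}

#' Apply a smooth random centerline irregularity
#'
#' Displaces nodes by a transverse sinusoidal field with random direction
#' and phases (deterministic for a fixed seed), normalised so the maximum
#' node displacement equals `amplitude`. Emulates the tortuosity of
#' reconstructed vessels; connectivity and surface sets are unchanged.
#'
#' @param mesh a `vessel_mesh`.
#' @param amplitude maximum transverse displacement (um); 0 returns the mesh
#'   unchanged.
#' @param wavelength axial wavelength of the irregularity (um).
#' @param seed integer seed.
#' @return the perturbed `vessel_mesh`.
#' @export
perturbCenterline <- function(mesh, amplitude, wavelength = 80, seed = 1L) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) return(mesh)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  phase <- runif(2, 0, 2 * pi)
  w <- runif(2, 0.5, 1)
  z <- mesh$nodes[, 3]
  dx <- w[1] * sin(2 * pi * z / wavelength + phase[1])
  dy <- w[2] * sin(2 * pi * z / wavelength + phase[2])
  scale <- amplitude / max(sqrt(dx^2 + dy^2))
  nodes <- mesh$nodes
  nodes[, 1] <- nodes[, 1] + scale * dx
  nodes[, 2] <- nodes[, 2] + scale * dy
  vol <- tetVolumes(nodes, mesh$tets)
  if (any(vol <= 0))
    stop("centerline perturbation of amplitude ", amplitude,
         " inverts ", sum(vol <= 0), " tetrahedra; reduce the amplitude")
  mesh$nodes <- nodes
  mesh$perturbed <- list(amplitude = amplitude, wavelength = wavelength,
                         seed = as.integer(seed))
  mesh
}

#' @export
print.vessel_mesh <- function(x, ...) {
  cat(sprintf("vessel_mesh (%s): %d nodes, %d tets, L=%g um\n",
              x$spec$vessel_class, nrow(x$nodes), nrow(x$tets), x$length))
  cat("  regions:", paste(sprintf("%s=%d", names(table(x$region)),
                                  as.integer(table(x$region))), collapse = ", "), "\n")
  cat("  surface sets:", paste(sprintf("%s=%d", names(x$surface_sets),
                                       vapply(x$surface_sets, nrow, 1L)),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Total volume of a mesh region
#'
#' @param mesh a `vessel_mesh`.
#' @param region region tag (`"wall"`, `"blood"`, `"marrow"`) or `NULL` for
#'   the whole mesh.
#' @return volume in um^3.
#' @export
meshRegionVolume <- function(mesh, region = NULL) {
  keep <- if (is.null(region)) rep(TRUE, nrow(mesh$tets)) else mesh$region == region
  sum(tetVolumes(mesh$nodes, mesh$tets[keep, , drop = FALSE]))
}

# ---- triangulated surfaces --------------------------------------------------

#' Triangulated surface mesh
#'
#' @param vertices V x 3 vertex coordinates (um).
#' @param triangles T x 3 vertex indices.
#' @param label text tag.
#' @param clean drop zero-area triangles and unreferenced vertices.
#' @return object of class `surface_mesh`.
#' @export
surfaceMesh <- function(vertices, triangles, label = "surface", clean = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1 || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  if (clean && nrow(triangles) > 0) {
    a <- triangle_areas(vertices, triangles)
    triangles <- triangles[a > 1e-12 * max(a, 1e-300), , drop = FALSE]
  }
  structure(list(vertices = vertices, triangles = triangles, label = label),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh '%s': %d vertices, %d triangles\n",
              x$label, nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

triangle_areas <- function(v, tr) {
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(n^2))
}

triangle_normals <- function(v, tr, normalize = TRUE) {
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalize) n / pmax(sqrt(rowSums(n^2)), 1e-300) else n
}

#' Volume enclosed by a closed surface
#'
#' Signed volume by the divergence theorem; positive for consistently
#' outward-oriented surfaces.
#'
#' @param surface a `surface_mesh`.
#' @return enclosed volume (um^3).
#' @export
surfaceVolume <- function(surface) {
  v <- surface$vertices; tr <- surface$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c3 <- v[tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

vertex_normals <- function(v, tr) {
  # area-weighted average of incident face normals
  fn <- triangle_normals(v, tr, normalize = FALSE) # length = 2*area
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    n[, 1] <- n[, 1] + unname(rowsum_vec(fn[, 1], tr[, k], nrow(v)))
    n[, 2] <- n[, 2] + unname(rowsum_vec(fn[, 2], tr[, k], nrow(v)))
    n[, 3] <- n[, 3] + unname(rowsum_vec(fn[, 3], tr[, k], nrow(v)))
  }
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Closed cylinder test surface
#'
#' Convenience generator of a capped cylinder along z (used by examples and
#' tests of the surface operators).
#'
#' @param radius,length cylinder dimensions (um).
#' @param n_circ,n_axial tessellation resolution.
#' @return a `surface_mesh` with outward orientation.
#' @export
tubeSurface <- function(radius = 20, length = 100, n_circ = 48, n_axial = 40) {
  ang <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  z <- length * (0:n_axial) / n_axial
  side <- cbind(radius * cos(rep(ang, n_axial + 1)),
                radius * sin(rep(ang, n_axial + 1)),
                rep(z, each = n_circ))
  idx <- function(iz, i) (iz - 1L) * n_circ + ((i - 1L) %% n_circ) + 1L
  tris <- list()
  for (iz in seq_len(n_axial)) {
    i <- seq_len(n_circ)
    a <- idx(iz, i); b <- idx(iz, i + 1)
    cc <- idx(iz + 1, i + 1); d <- idx(iz + 1, i)
    tris[[iz]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  }
  v <- rbind(side, c(0, 0, 0), c(0, 0, length))
  cb <- nrow(side) + 1L; ct <- nrow(side) + 2L
  i <- seq_len(n_circ)
  bot <- cbind(cb, idx(1, i + 1), idx(1, i))
  top <- cbind(ct, idx(n_axial + 1, i), idx(n_axial + 1, i + 1))
  surfaceMesh(v, rbind(do.call(rbind, tris), bot, top), label = "cylinder")
}

#' Offset a closed surface inward by a constant thickness
#'
#' Moves every vertex along its inward vertex normal by `thickness`,
#' emulating constant-thickness wall creation by uniform inward shrinking.
#' Raises an error when the offset self-intersects (flipped faces or
#' intersecting non-adjacent triangle pairs).
#'
#' @param surface a closed, consistently oriented `surface_mesh`.
#' @param thickness offset distance (um); must be below the local minimum
#'   feature radius.
#' @return the inner-shell `surface_mesh`.
#' @export
offsetSurfaceInward <- function(surface, thickness) {
  if (thickness < 0) stop("thickness must be >= 0")
  if (thickness == 0) return(surface)
  v <- surface$vertices; tr <- surface$triangles
  if (surfaceVolume(surface) < 0) tr <- tr[, c(1, 3, 2)]
  n <- vertex_normals(v, tr)
  v2 <- v - thickness * n
  n_old <- triangle_normals(v, tr)
  n_new <- triangle_normals(v2, tr)
  flipped <- which(rowSums(n_old * n_new) <= 0)
  inter <- find_self_intersections(v2, tr)
  if (length(flipped) > 0 || nrow(inter) > 0) {
    msg <- "self-intersection detected in inward offset"
    if (nrow(inter) > 0)
      msg <- paste0(msg, "; intersecting triangle pairs: ",
                    paste(utils::head(apply(inter, 1, paste, collapse = "-"), 20),
                          collapse = ", "))
    if (length(flipped) > 0)
      msg <- paste0(msg, "; flipped triangles: ",
                    paste(utils::head(flipped, 20), collapse = ", "))
    stop(msg)
  }
  out <- surface
  out$vertices <- v2
  out$triangles <- tr
  out$label <- paste0(surface$label, "_inner_shell")
  out
}

# Broad-phase bbox filter + Moller tri-tri intersection on candidate pairs
# that share no vertex.
find_self_intersections <- function(v, tr, max_pairs = 200000L) {
  nt <- nrow(tr)
  lo <- hi <- matrix(0, nt, 3)
  for (d in 1:3) {
    m <- cbind(v[tr[, 1], d], v[tr[, 2], d], v[tr[, 3], d])
    lo[, d] <- apply(m, 1, min); hi[, d] <- apply(m, 1, max)
  }
  # sweep on x
  ord <- order(lo[, 1])
  pairs <- list(); np <- 0L
  for (ii in seq_len(nt - 1)) {
    i <- ord[ii]
    jj <- ii + 1L
    while (jj <= nt && lo[ord[jj], 1] <= hi[i, 1]) {
      j <- ord[jj]
      if (hi[i, 2] >= lo[j, 2] && hi[j, 2] >= lo[i, 2] &&
          hi[i, 3] >= lo[j, 3] && hi[j, 3] >= lo[i, 3] &&
          length(intersect(tr[i, ], tr[j, ])) == 0) {
        np <- np + 1L
        pairs[[np]] <- c(min(i, j), max(i, j))
        if (np > max_pairs) stop("self-intersection check: too many candidate pairs")
      }
      jj <- jj + 1L
    }
  }
  if (np == 0L) return(matrix(0L, 0, 2))
  cand <- unique(do.call(rbind, pairs))
  hit <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    hit[k] <- tri_tri_intersect(v[tr[i, 1], ], v[tr[i, 2], ], v[tr[i, 3], ],
                                v[tr[j, 1], ], v[tr[j, 2], ], v[tr[j, 3], ])
  }
  cand[hit, , drop = FALSE]
}

# Moller (1997) interval-overlap triangle-triangle intersection test.
tri_tri_intersect <- function(p1, q1, r1, p2, q2, r2) {
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  n2 <- cross3(q2 - p2, r2 - p2)
  d2 <- -sum(n2 * p2)
  du <- c(sum(n2 * p1), sum(n2 * q1), sum(n2 * r1)) + d2
  eps <- 1e-12 * max(abs(du), 1)
  du[abs(du) < eps] <- 0
  if (all(du > 0) || all(du < 0)) return(FALSE)
  n1 <- cross3(q1 - p1, r1 - p1)
  d1 <- -sum(n1 * p1)
  dv <- c(sum(n1 * p2), sum(n1 * q2), sum(n1 * r2)) + d1
  dv[abs(dv) < eps] <- 0
  if (all(dv > 0) || all(dv < 0)) return(FALSE)
  if (all(du == 0)) return(FALSE) # coplanar: treated as non-intersecting here
  D <- cross3(n1, n2)
  proj <- function(p) sum(D * p)
  interval <- function(a, b, c3, da, db, dc) {
    # vertices a,b,c with signed distances da,db,dc: c on one side alone
    sel <- if (sign(da) == sign(db) || (da == 0 && db == 0)) c(3, 1, 2)
           else if (sign(da) == sign(dc) || (da == 0 && dc == 0)) c(2, 1, 3)
           else c(1, 2, 3)
    vs <- list(a, b, c3)[sel]
    ds <- c(da, db, dc)[sel]
    pv <- vapply(vs, proj, 0)
    t1 <- pv[2] + (pv[1] - pv[2]) * ds[2] / (ds[2] - ds[1])
    t2 <- pv[3] + (pv[1] - pv[3]) * ds[3] / (ds[3] - ds[1])
    sort(c(t1, t2))
  }
  i1 <- interval(p1, q1, r1, du[1], du[2], du[3])
  i2 <- interval(p2, q2, r2, dv[1], dv[2], dv[3])
  i1[1] <= i2[2] && i2[1] <= i1[2]
}

#' Volume-preserving surface smoothing
#'
#' Two-step band-pass (shrink/expand) Laplacian smoothing with uniform
#' weights, which damps high-frequency vertex noise while changing the
#' enclosed volume by well under 1% per 10 iterations. Optional midpoint
#' subdivision refines the triangulation before smoothing.
#'
#' @param surface a manifold `surface_mesh`.
#' @param iterations number of smoothing passes (each = one shrink + one
#'   expand step). 0 returns the input unchanged.
#' @param lambda,mu positive shrink / negative expand factors.
#' @param subdivide if `TRUE`, apply one round of midpoint subdivision
#'   (4 triangles per input triangle) before smoothing.
#' @return the smoothed `surface_mesh`.
#' @export
smoothSurface <- function(surface, iterations, lambda = 0.5, mu = -0.53,
                          subdivide = FALSE) {
  if (iterations < 0) stop("iterations must be >= 0")
  if (subdivide) surface <- subdivideMidpoint(surface)
  if (iterations == 0) return(surface)
  v <- surface$vertices; tr <- surface$triangles
  edges <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(ekey)
  if (any(cnt > 2)) stop("non-manifold surface: edge shared by > 2 triangles")
  und <- unique(cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])))
  A <- Matrix::sparseMatrix(i = c(und[, 1], und[, 2]),
                            j = c(und[, 2], und[, 1]),
                            x = 1, dims = c(nrow(v), nrow(v)))
  deg <- pmax(Matrix::rowSums(A), 1)
  step <- function(v, f) {
    avg <- as.matrix(A %*% v) / deg
    v + f * (avg - v)
  }
  for (it in seq_len(iterations)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  out <- surface
  out$vertices <- v
  out
}

#' Midpoint subdivision of a triangulated surface
#'
#' Splits every triangle into four by inserting edge midpoints.
#'
#' @param surface a `surface_mesh`.
#' @return the refined `surface_mesh`.
#' @export
subdivideMidpoint <- function(surface) {
  v <- surface$vertices; tr <- surface$triangles
  mid_env <- new.env(hash = TRUE)
  verts <- list(); nv <- nrow(v)
  midpoint <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    id <- mid_env[[key]]
    if (is.null(id)) {
      nv <<- nv + 1L
      verts[[length(verts) + 1L]] <<- (v[a, ] + v[b, ]) / 2
      mid_env[[key]] <- nv
      id <- nv
    }
    id
  }
  newtr <- matrix(0L, 4 * nrow(tr), 3)
  for (t in seq_len(nrow(tr))) {
    a <- tr[t, 1]; b <- tr[t, 2]; c3 <- tr[t, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
    newtr[4 * (t - 1) + 1:4, ] <- rbind(c(a, ab, ca), c(ab, b, bc),
                                        c(ca, bc, c3), c(ab, bc, ca))
  }
  v2 <- rbind(v, do.call(rbind, verts))
  surfaceMesh(v2, newtr, label = surface$label, clean = FALSE)
}
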
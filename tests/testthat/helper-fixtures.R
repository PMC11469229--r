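# Shared coarse fixtures, built once per test run. Resolutions are chosen so
# the whole suite runs on one CPU in minutes; convergence-sensitive checks
# state their own tolerances.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

coarse_artery <- function() fixture("artery6", function() {
  makeTubeMesh(vesselSpec("artery", characteristic_edge = 6))
})

coarse_arteriole <- function() fixture("arteriole5", function() {
  makeTubeMesh(vesselSpec("arteriole", characteristic_edge = 5))
})

coarse_sinusoid <- function() fixture("sinusoid8", function() {
  makeSinusoidDomain(vesselSpec("sinusoid", characteristic_edge = 8))
})

# short linear-elastic tube for oracle benchmarks (Lame, rod wave)
lame_mesh <- function() fixture("lame", function() {
  makeTubeMesh(vesselSpec("artery", length = 16, lumen_radius = 15,
                          wall_thickness = 14.3, characteristic_edge = 3))
})

rod_mesh <- function() fixture("rod", function() {
  makeTubeMesh(vesselSpec("artery", length = 200, lumen_radius = 10,
                          wall_thickness = 6, characteristic_edge = 4))
})

# tiny two-tet patch for kernel consistency checks
two_tet_mesh <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1.1, 1.05, 0.95))
  tets <- rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L))
  v <- tetVolumes(nodes, tets)
  tets[v < 0, c(3, 4)] <- tets[v < 0, c(4, 3)]
  list(nodes = nodes, tets = tets)
}

# in-plane rigid-mode pins for plane-end (z-only) fixtures
plane_end_pins <- function(mesh) {
  na <- mesh$node_sets$end_A
  xy <- mesh$nodes[na, 1:2, drop = FALSE]
  r <- mesh$lumen_radius
  pick <- function(target)
    na[which.min((xy[, 1] - target[1])^2 + (xy[, 2] - target[2])^2)]
  data.frame(node = c(pick(c(r, 0)), pick(c(-r, 0)), pick(c(0, r))),
             comp = c("y", "y", "x"), value = 0)
}

# hoop stress profile of a field_state on a tube wall: volume-weighted layer
# means over radius plus an A + B/r^2 fit evaluated at the inner radius
hoop_profile <- function(mesh, state, nlayers = 5) {
  act <- which(state$active)
  tet <- mesh$tets[act, , drop = FALSE]
  cen <- (mesh$nodes[tet[, 1], ] + mesh$nodes[tet[, 2], ] +
          mesh$nodes[tet[, 3], ] + mesh$nodes[tet[, 4], ]) / 4
  r <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  th <- atan2(cen[, 2], cen[, 1])
  S <- state$stress[act, , drop = FALSE]
  hoop <- S[, 1] * sin(th)^2 - 2 * S[, 4] * sin(th) * cos(th) +
    S[, 2] * cos(th)^2
  v <- tetVolumes(mesh$nodes, tet)
  a <- mesh$lumen_radius; b <- mesh$outer_radius
  lay <- cut(r, breaks = seq(a, b, length.out = nlayers + 1))
  rm_ <- as.numeric(tapply(r * v, lay, sum) / tapply(v, lay, sum))
  hm <- as.numeric(tapply(hoop * v, lay, sum) / tapply(v, lay, sum))
  fit <- stats::lm(hm ~ I(1 / rm_^2))
  list(r = rm_, hoop = hm, at_inner = sum(stats::coef(fit) * c(1, 1 / a^2)))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
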
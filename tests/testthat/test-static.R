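# Quasi-static solver: oracles (Lame), consistency (patch test), linearity,
# and load handling.

test_that("zero load converges immediately to zero displacement", {
  mesh <- coarse_arteriole()
  st <- solveStatic(mesh, load = loadCase(pulse_pressure = 0), n_steps = 1)
  expect_true(st$converged)
  expect_equal(st$iterations, 1)
  expect_equal(max(abs(st$u)), 0)
  expect_equal(max(st$vm, na.rm = TRUE), 0)
})

test_that("patch test: homogeneous stretch gives uniform interior stress", {
  # distorted single-material mesh: perturb interior nodes of a small tube
  mesh <- makeTubeMesh(vesselSpec("artery", length = 20, lumen_radius = 8,
                                  wall_thickness = 6, characteristic_edge = 3))
  set.seed(9)
  bnd <- unique(unlist(mesh$node_sets))
  interior <- setdiff(seq_len(nrow(mesh$nodes)), bnd)
  mesh$nodes[interior, ] <- mesh$nodes[interior, ] +
    matrix(runif(3 * length(interior), -0.25, 0.25), ncol = 3)
  expect_gt(min(tetVolumes(mesh$nodes, mesh$tets)), 0)

  # all boundary nodes of the wall+blood solid get a prescribed uniform strain
  mat <- linear_elastic(E = 5, nu = 0.3)
  active_nodes <- seq_len(nrow(mesh$nodes))
  faces <- vesselmech:::region_boundary_faces(mesh$nodes, mesh$tets)
  bn <- sort(unique(as.vector(faces)))
  eps <- c(x = 2e-3, y = -1e-3, z = 1.5e-3)
  ep <- do.call(rbind, lapply(c("x", "y", "z"), function(cc)
    data.frame(node = bn, comp = cc,
               value = eps[[cc]] * mesh$nodes[bn, match(cc, c("x", "y", "z"))])))
  load <- loadCase(fixed = list(), extra_prescribed = ep)
  st <- solveStatic(mesh, list(wall = mat, blood = mat), load,
                    regions = c("wall", "blood"), n_steps = 1, tol = 1e-12)
  vm <- st$vm[st$active]
  expect_lt(max(vm) - min(vm), 1e-8 * max(vm))
})

test_that("static solve matches the Lame thick-wall solution within 5%", {
  mesh <- lame_mesh()
  mats <- list(wall = linear_elastic(E = 1, nu = 0.3),
               blood = materialFromTable("blood"))
  p <- 0.01
  load <- loadCase(pulse_pressure = p / 1.333224e-4,
                   fixed = list(end_A = "z", end_B = "z"),
                   extra_prescribed = plane_end_pins(mesh), follower = FALSE)
  st <- solveStatic(mesh, mats, load, regions = "wall", n_steps = 1, tol = 1e-8)
  a <- 15; b <- 29.3
  prof <- hoop_profile(mesh, st)
  lame <- function(r) p * a^2 / (b^2 - a^2) * (1 + b^2 / r^2)
  # layer-mean hoop stresses track the Lame profile
  expect_lt(max(abs(prof$hoop / lame(prof$r) - 1)), 0.05)
  # recovered inner-surface hoop stress matches p(a^2+b^2)/(b^2-a^2)
  expect_rel(prof$at_inner, p * (a^2 + b^2) / (b^2 - a^2), 0.05)
})

test_that("Newton converges superlinearly near the Lame solution", {
  mesh <- lame_mesh()
  mats <- list(wall = linear_elastic(E = 1, nu = 0.3),
               blood = materialFromTable("blood"))
  load <- loadCase(pulse_pressure = 50,
                   fixed = list(end_A = "z", end_B = "z"),
                   extra_prescribed = plane_end_pins(mesh), follower = FALSE)
  tr <- capture.output(
    st <- solveStatic(mesh, mats, load, regions = "wall", n_steps = 1,
                      tol = 1e-10, verbose = TRUE), type = "message")
  res <- as.numeric(sub(".*\\|r\\|=([0-9.e+-]+) .*", "\\1", tr))
  # residual drops by orders of magnitude per iteration once near the root
  expect_true(st$converged)
  expect_lte(length(res), 4)
  if (length(res) >= 3) expect_lt(res[3] / res[2], 0.01 * res[2] / res[1] + 0.1)
})

test_that("small pressures give a linear response (doubling check)", {
  mesh <- coarse_arteriole()
  mats <- defaultMaterials(mesh)
  st1 <- solveStatic(mesh, mats, loadCase(pulse_pressure = 1), n_steps = 1)
  st2 <- solveStatic(mesh, mats, loadCase(pulse_pressure = 2), n_steps = 1)
  a <- st1$vm[st1$active]; b <- st2$vm[st2$active]
  expect_lt(max(abs(b - 2 * a)) / max(b), 0.01)
  expect_lt(max(abs(st2$u / 2 - st1$u)) / max(abs(st2$u)), 0.01)
})

test_that("rigid rotation of mesh and load rotates the solution", {
  mesh <- makeTubeMesh(vesselSpec("arteriole", length = 60,
                                  characteristic_edge = 5))
  mats <- defaultMaterials(mesh)
  load <- loadCase(pulse_pressure = 30)
  st0 <- solveStatic(mesh, mats, load, n_steps = 2)
  th <- 0.5
  Q <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  mesh_r <- mesh
  mesh_r$nodes <- mesh$nodes %*% t(Q)
  st1 <- solveStatic(mesh_r, mats, load, n_steps = 2)
  expect_lt(max(abs(st1$u - st0$u %*% t(Q))) / max(abs(st0$u)), 1e-5)
  expect_lt(max(abs(st1$vm - st0$vm), na.rm = TRUE) / max(st0$vm, na.rm = TRUE),
            1e-5)
})

test_that("bending applies the prescribed midspan displacement", {
  mesh <- coarse_arteriole()
  mats <- defaultMaterials(mesh)
  d <- 2.5
  st <- solveStatic(mesh, mats, loadCase(bending = d), n_steps = 5)
  ring <- vesselmech:::midspan_ring(mesh)
  wall_nodes <- sort(unique(as.vector(mesh$tets[mesh$region == "wall", ])))
  ring <- intersect(ring, wall_nodes)
  expect_equal(max(abs(st$u[ring, 1] - d)), 0, tolerance = 1e-12)
  # both ends pinned
  expect_equal(max(abs(st$u[mesh$node_sets$end_A, ])), 0)
  # stress concentrates near midspan
  expect_gt(max(st$vm, na.rm = TRUE), 0)
})

test_that("load-case invariants are enforced", {
  expect_error(loadCase(pulse_pressure = -5), ">= 0")
  expect_error(loadCase(bending = 1, end_pulse = list(amplitude = 1)),
               "at most one")
  mesh <- coarse_arteriole()
  expect_error(solveStatic(mesh, load = loadCase(fixed = list(nope = "xyz"))),
               "unknown node set")
  expect_error(applyPressureLoad(mesh, "missing_set", 1), "empty")
})
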
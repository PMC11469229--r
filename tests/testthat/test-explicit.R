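# Explicit dynamics: CFL step, wave-speed oracle, energy ledger, causality,
# symmetry, coupling with a pre-pressurized state.

test_that("stable timestep follows the dilatational-speed arithmetic", {
  # single regular tet, edge 3: E=10, nu=0, rho=1e-3 -> c = 100 um/us
  a <- 3
  nodes <- rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
                 c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3)))
  tets <- matrix(1:4, 1, 4)
  mesh <- structure(list(nodes = nodes, tets = tets, region = "wall",
                         node_sets = list(), spec = list(vessel_class = "x")),
                    class = "vessel_mesh")
  mats <- list(wall = linear_elastic(E = 10, nu = 0, density = 1e-3))
  v <- tetVolumes(nodes, tets)
  amax <- max(vesselmech:::triangle_areas(nodes, tets[, c(2, 3, 4), drop = FALSE]),
              vesselmech:::triangle_areas(nodes, tets[, c(1, 3, 4), drop = FALSE]),
              vesselmech:::triangle_areas(nodes, tets[, c(1, 2, 4), drop = FALSE]),
              vesselmech:::triangle_areas(nodes, tets[, c(1, 2, 3), drop = FALSE]))
  h <- 3 * v / amax # minimum altitude
  expect_equal(stableTimestep(mesh, mats), 0.5 * h / 100, tolerance = 1e-12)
  # halving densities scales dt by 1/sqrt(2)
  mats2 <- list(wall = linear_elastic(E = 10, nu = 0, density = 0.5e-3))
  expect_equal(stableTimestep(mesh, mats2) / stableTimestep(mesh, mats),
               1 / sqrt(2), tolerance = 1e-12)
  # near-incompressible material of the same mu0 has a smaller dt
  mr <- mooney_rivlin5(density = 1e-3) # kappa/mu0 = 1000
  mu0 <- 2 * (mr$C10 + mr$C01)
  nu0_same_mu <- list(wall = linear_elastic(E = 2 * mu0, nu = 0, density = 1e-3))
  expect_lt(stableTimestep(mesh, list(wall = mr)),
            stableTimestep(mesh, nu0_same_mu))
})

test_that("zero load keeps all fields exactly zero", {
  mesh <- coarse_arteriole()
  ser <- runExplicit(mesh, load = loadCase(fixed = list()), duration = 1,
                     output_times = c(0.5, 1))
  expect_identical(max(abs(ser$U[[2]])), 0)
  expect_identical(max(ser$vm[[2]], na.rm = TRUE), 0)
  expect_identical(max(abs(ser$ledger$KE)), 0)
})

test_that("axial stress front travels at the rod speed sqrt(E/rho)", {
  mesh <- rod_mesh()
  mats <- list(wall = linear_elastic(10, 0, 1e-3),
               blood = linear_elastic(10, 0, 1e-3))
  load <- loadCase(end_pulse = list(amplitude = 0.2, rise = 0.2, direction = "z"),
                   fixed = list())
  ser <- runExplicit(mesh, mats, load, duration = 1.6,
                     output_times = seq(0.3, 1.6, by = 0.1))
  fr <- trackFront(ser, mesh)
  expect_rel(fr$v_s, 100, 0.05)
})

test_that("causality: no signal at the far end before the wave arrives", {
  mesh <- rod_mesh() # L = 200, c = 100 um/us
  mats <- list(wall = linear_elastic(10, 0, 1e-3),
               blood = linear_elastic(10, 0, 1e-3))
  load <- loadCase(end_pulse = list(amplitude = 0.2, rise = 0.2, direction = "z"),
                   fixed = list())
  ser <- runExplicit(mesh, mats, load, duration = 1.5, output_times = c(1, 1.5))
  z <- (mesh$nodes[mesh$tets[, 1], 3] + mesh$nodes[mesh$tets[, 2], 3] +
        mesh$nodes[mesh$tets[, 3], 3] + mesh$nodes[mesh$tets[, 4], 3]) / 4
  # at t = 1 us the front is at ~100 um; the last 60 um must still be quiet
  vm1 <- ser$vm[[1]]
  peak <- max(vm1, na.rm = TRUE)
  expect_lt(max(vm1[z > 140], na.rm = TRUE), 1e-6 * peak)
  # by t = 1.5 us the region has been reached
  expect_gt(max(ser$vm[[2]][z > 140], na.rm = TRUE), 1e-3 * peak)
})

test_that("energy ledger balances within 1% on an undamped artery run", {
  mesh <- coarse_artery()
  load <- loadCase(end_pulse = list(amplitude = 1, rise = 1, direction = "z"),
                   fixed = list())
  ser <- runExplicit(mesh, load = load, duration = 20,
                     output_times = c(1, 2, 5, 10, 20))
  expect_lt(energyDrift(ser), 0.01)
  expect_true(all(diff(ser$times) > 0))
  expect_true(all(is.finite(as.matrix(ser$ledger))))
})

test_that("axisymmetric pulse keeps the response axisymmetric", {
  # at the standard 3 um resolution: coarser meshes show percent-level
  # circumferential imprint of the (non-rotationally-periodic) tet splitting
  mesh <- makeTubeMesh(vesselSpec("arteriole", characteristic_edge = 3))
  load <- loadCase(end_pulse = list(amplitude = 0.5, rise = 0.5, direction = "z"),
                   fixed = list())
  ser <- runExplicit(mesh, load = load, duration = 2, output_times = 2)
  fo <- vesselmech:::facet_owners(mesh, "outer_wall")
  cen <- (mesh$nodes[fo$fac[, 1], ] + mesh$nodes[fo$fac[, 2], ] +
          mesh$nodes[fo$fac[, 3], ]) / 3
  v <- ser$vm[[1]][fo$owner]
  band <- cen[, 3] > 10 & cen[, 3] < 50 # behind the front at t = 2 us
  th <- atan2(cen[band, 2], cen[band, 1])
  sector <- cut(th, breaks = seq(-pi, pi, length.out = 9))
  secmean <- tapply(v[band], sector, mean)
  expect_lt(max(secmean) - min(secmean), 0.01 * mean(v[band]))
})

test_that("halving dt changes the peak-stress trace by < 2%", {
  mesh <- makeTubeMesh(vesselSpec("arteriole", length = 80,
                                  characteristic_edge = 5))
  load <- loadCase(end_pulse = list(amplitude = 1, rise = 1, direction = "z"),
                   fixed = list())
  dt0 <- stableTimestep(mesh, defaultMaterials(mesh))
  s1 <- runExplicit(mesh, load = load, duration = 4, output_times = 1:4, dt = dt0)
  s2 <- runExplicit(mesh, load = load, duration = 4, output_times = 1:4,
                    dt = dt0 / 2)
  p1 <- vapply(s1$vm, max, 0, na.rm = TRUE)
  p2 <- vapply(s2$vm, max, 0, na.rm = TRUE)
  expect_lt(max(abs(p1 - p2) / p2), 0.02)
})

test_that("coupled run: pp = 0 is bitwise the cold start", {
  mesh <- coarse_arteriole()
  then <- loadCase(end_pulse = list(amplitude = 1, rise = 1, direction = "z"),
                   fixed = list())
  a <- couplePrestress(mesh, pp = 0, then = then, duration = 2,
                       output_times = c(1, 2))
  b <- runExplicit(mesh, load = loadCase(
    end_pulse = list(amplitude = 1, rise = 1, direction = "z"),
    fixed = list()), duration = 2, output_times = c(1, 2))
  expect_identical(a$U[[2]], b$U[[2]])
  expect_identical(a$vm[[2]], b$vm[[2]])
})

test_that("pressurized state without a pulse holds static equilibrium", {
  mesh <- makeTubeMesh(vesselSpec("arteriole", length = 60,
                                  characteristic_edge = 5))
  mats <- defaultMaterials(mesh)
  pp <- 50
  st <- solveStatic(mesh, mats, loadCase(pulse_pressure = pp),
                    regions = unique(mesh$region))
  hold <- loadCase(fixed = list(end_A = "xyz", end_B = "xyz"))
  ser <- runExplicit(mesh, mats,
                     loadCase(pulse_pressure = pp,
                              fixed = list(end_A = "xyz", end_B = "xyz")),
                     duration = 5, output_times = c(2.5, 5), u0 = st$u)
  ref <- max(abs(st$u))
  expect_lt(max(abs(ser$U[[2]] - st$u)) / ref, 0.01)
})

test_that("instability is detected and aborts with a diagnostic", {
  mesh <- makeTubeMesh(vesselSpec("arteriole", length = 40,
                                  characteristic_edge = 5))
  load <- loadCase(end_pulse = list(amplitude = 1, rise = 0.5, direction = "z"),
                   fixed = list())
  dt0 <- stableTimestep(mesh, defaultMaterials(mesh))
  expect_error(runExplicit(mesh, load = load, duration = 4,
                           output_times = c(2, 4), dt = 4 * dt0),
               "instability|non-finite|inverted")
})
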
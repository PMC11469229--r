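# Compiled kernels vs the R reference implementations.

test_that("kernel internal force equals -dE/dx of the R-side energy", {
  tm <- two_tet_mesh()
  pre <- fem_precompute(tm$nodes, tm$tets)
  for (kind in c("mr", "svk")) {
    if (kind == "mr") {
      mat <- mooney_rivlin5()
      mtype <- c(0L, 0L)
      mpar <- matrix(rep(c(mat$C10, mat$C01, mat$C20, mat$C11, mat$C02,
                           mat$D1, mat$density), each = 2), 2, 7)
      proj <- c(FALSE, FALSE) # element-local volumetric term for this check
      energy <- function(X) {
        sum(vapply(1:2, function(e) {
          nd <- tm$tets[e, ]
          D0 <- t(tm$nodes[nd[2:4], ] - matrix(tm$nodes[nd[1], ], 3, 3, byrow = TRUE))
          D1_ <- t(X[nd[2:4], ] - matrix(X[nd[1], ], 3, 3, byrow = TRUE))
          Fm <- D1_ %*% solve(D0)
          pre$V0[e] * mrStrainEnergy(Fm, mat)
        }, 0))
      }
    } else {
      mat <- linear_elastic(E = 2, nu = 0.3)
      mtype <- c(1L, 1L)
      mpar <- matrix(rep(c(mat$E, mat$nu, mat$density, 0, 0, 0, mat$density),
                         each = 2), 2, 7)
      proj <- c(FALSE, FALSE)
      energy <- function(X) {
        lam <- mat$E * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu))
        mu <- mat$E / (2 * (1 + mat$nu))
        sum(vapply(1:2, function(e) {
          nd <- tm$tets[e, ]
          D0 <- t(tm$nodes[nd[2:4], ] - matrix(tm$nodes[nd[1], ], 3, 3, byrow = TRUE))
          D1_ <- t(X[nd[2:4], ] - matrix(X[nd[1], ], 3, 3, byrow = TRUE))
          Fm <- D1_ %*% solve(D0)
          Eg <- 0.5 * (t(Fm) %*% Fm - diag(3))
          pre$V0[e] * (0.5 * lam * sum(diag(Eg))^2 + mu * sum(Eg * Eg))
        }, 0))
      }
    }
    set.seed(2)
    X <- tm$nodes + matrix(runif(15, -0.05, 0.05), 5, 3)
    fr <- fem_force(X, tm$nodes, tm$tets, pre$G, pre$V0, mtype, mpar, proj, FALSE)
    expect_true(fr$ok)
    expect_equal(fr$SE, energy(X), tolerance = 1e-10)
    h <- 1e-6
    for (n in c(1L, 5L)) for (k in 1:3) {
      Xp <- X; Xp[n, k] <- Xp[n, k] + h
      Xm <- X; Xm[n, k] <- Xm[n, k] - h
      fd <- (energy(Xp) - energy(Xm)) / (2 * h)
      expect_equal(fr$force[n, k], fd, tolerance = 1e-6)
    }
  }
})

test_that("kernel stress matches the R Mooney-Rivlin stress for one element", {
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  tets <- matrix(1:4, 1, 4)
  pre <- fem_precompute(nodes, tets)
  mat <- mooney_rivlin5()
  mpar <- matrix(c(mat$C10, mat$C01, mat$C20, mat$C11, mat$C02, mat$D1,
                   mat$density), 1, 7)
  Fm <- diag(3) + matrix(c(0.05, 0.02, 0, 0.01, -0.03, 0.02, 0, 0.01, 0.04), 3, 3)
  X <- nodes %*% t(Fm)
  fr <- fem_force(X, nodes, tets, pre$G, pre$V0, 0L, mpar, FALSE, TRUE)
  sig <- mrCauchyStress(Fm, mat)
  expect_equal(fr$stress[1, 1:3], c(sig[1, 1], sig[2, 2], sig[3, 3]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fr$stress[1, 4:6], c(sig[1, 2], sig[2, 3], sig[1, 3]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fr$vm[1], vonMises(sig), tolerance = 1e-10)
})

test_that("pressure load: uniform patch resultant, closed-surface balance, rotation", {
  # flat square patch of area 4 in the xy plane, normal +z
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  fac <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  p <- 0.37
  f <- fem_pressure_force(nodes, fac, p)
  expect_equal(colSums(f), c(0, 0, -p * 4), tolerance = 1e-12)

  # closed surface: net resultant vanishes
  mesh <- coarse_artery()
  fac_all <- do.call(rbind, lapply(mesh$surface_sets, function(x) x[, 1:3]))
  fcl <- fem_pressure_force(mesh$nodes, fac_all, 1)
  area <- sum(triangle_areas <- vesselmech:::triangle_areas(mesh$nodes, fac_all))
  expect_lt(max(abs(colSums(fcl))), 1e-8 * area)

  # follower equivariance: rigid rotation rotates the force field
  th <- 0.6
  Q <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  f0 <- fem_pressure_force(mesh$nodes, mesh$surface_sets$inner_lumen, 2)
  f1 <- fem_pressure_force(mesh$nodes %*% t(Q), mesh$surface_sets$inner_lumen, 2)
  expect_equal(f1, f0 %*% t(Q), tolerance = 1e-12)
})
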
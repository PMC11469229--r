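# Constitutive models: closed-form values, invariances, consistency.

test_that("strain energy matches the closed-form polynomial evaluation", {
  m <- mooney_rivlin5()
  expect_identical(mrStrainEnergy(diag(3), m), 0)

  # incompressible uniaxial stretch 1.2: invariants and deviatoric energy
  lam <- 1.2
  d <- deformation(diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam))))
  expect_equal(d$I1, 3.10667, tolerance = 1e-5)
  expect_equal(d$I2, 3.09444, tolerance = 1e-5)
  expect_equal(mrStrainEnergy(d, m), 0.00928, tolerance = 1e-3)

  # pure volumetric deformation: isochoric part vanishes, penalty closed form
  Fv <- diag(3) * 1.01
  expect_equal(mrStrainEnergy(Fv, m), (1 / m$D1) * (1.01^3 - 1)^2,
               tolerance = 1e-10)
})

test_that("Cauchy stress: zero at identity, closed-form uniaxial, shear limit", {
  m <- mooney_rivlin5()
  expect_equal(mrCauchyStress(diag(3), m), matrix(0, 3, 3))

  # incompressible uniaxial: axial minus lateral stress = 2(l^2-1/l)(W1+W2/l)
  lam <- 1.2
  sig <- mrCauchyStress(diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam))), m)
  expect_equal(sig[1, 1] - sig[2, 2], 0.1239, tolerance = 1e-3)
  expect_equal(sig[2, 2], sig[3, 3], tolerance = 1e-12)

  # small simple shear: stress/gamma -> mu0 = 2(C10+C01) = 0.132 MPa
  g <- 1e-6
  F <- diag(3); F[1, 2] <- g
  sig <- mrCauchyStress(F, m)
  expect_equal(sig[1, 2] / g, 0.132, tolerance = 1e-4)
})

test_that("energy-stress consistency: FD of W reproduces PK1 to 1e-5", {
  m <- mooney_rivlin5()
  set.seed(7)
  for (k in 1:5) {
    F <- diag(3) + matrix(runif(9, -0.15, 0.15), 3, 3)
    if (det(F) <= 0.2) next
    P <- mrPK1(F, m)
    h <- 1e-6
    Pfd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      Pfd[i, j] <- (mrStrainEnergy(Fp, m) - mrStrainEnergy(Fm, m)) / (2 * h)
    }
    expect_lt(max(abs(P - Pfd)) / max(abs(P)), 1e-5)
  }
})

test_that("frame indifference: rotated deformation gives rotated stress", {
  m <- mooney_rivlin5()
  set.seed(11)
  F <- diag(3) + matrix(runif(9, -0.1, 0.1), 3, 3)
  sig <- mrCauchyStress(F, m)
  for (k in 1:4) {
    ax <- runif(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    Q <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    sig_rot <- mrCauchyStress(Q %*% F, m)
    expect_lt(max(abs(sig_rot - Q %*% sig %*% t(Q))), 1e-10)
  }
})

test_that("small-strain tangent moduli approach 2(C10+C01) and 6(C10+C01)", {
  m <- mooney_rivlin5()
  mod <- smallStrainModuli(m)
  expect_equal(mod$mu, 0.132)
  expect_equal(mod$E, 0.396) # incompressible-limit Young's modulus
  # numerically: incompressible uniaxial stress-difference slope at eps -> 0
  eps <- 1e-6
  lam <- 1 + eps
  sig <- mrCauchyStress(diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam))),
                        mooney_rivlin5())
  expect_equal((sig[1, 1] - sig[2, 2]) / eps, 0.396, tolerance = 1e-4)
})

test_that("linear elastic stress inverts the compliance relations", {
  mat <- linear_elastic(E = 0.01, nu = 0) # 10 kPa, nu = 0
  eps <- matrix(0, 3, 3); eps[1, 1] <- 0.001
  sig <- linearStress(eps, mat)
  expect_equal(sig[1, 1], 1e-5) # 0.01 kPa in MPa
  expect_equal(sig[2, 2], 0); expect_equal(sig[3, 3], 0)
  expect_equal(linearStress(matrix(0, 3, 3), mat), matrix(0, 3, 3))

  # hydrostatic strain: sigma = E e / (1 - 2 nu) on the diagonal
  mat2 <- linear_elastic(E = 2, nu = 0.3)
  e <- 1e-3
  sig2 <- linearStress(diag(3) * e, mat2)
  expect_equal(sig2[1, 1], 2 * e / (1 - 0.6), tolerance = 1e-12)
  expect_equal(sig2[1, 2], 0)
})

test_that("von Mises reduction: uniaxial, shear, hydrostatic, rotation", {
  expect_equal(vonMises(diag(c(5, 0, 0))), 5)
  tau <- 2.5
  s <- matrix(0, 3, 3); s[1, 2] <- s[2, 1] <- tau
  expect_equal(vonMises(s), sqrt(3) * tau)
  expect_equal(vonMises(diag(c(3, 3, 3))), 0)
  set.seed(3)
  A <- matrix(runif(9), 3, 3); S <- A + t(A)
  th <- 0.7
  Q <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(vonMises(Q %*% S %*% t(Q)), vonMises(S), tolerance = 1e-12)
})

test_that("tissue table defaults and error handling", {
  marrow <- materialFromTable("marrow")
  expect_s3_class(marrow, "linear_elastic")
  expect_equal(marrow$E, 0.01) # 10 kPa
  blood <- materialFromTable("blood")
  expect_lte(blood$E, 1e-4)
  expect_equal(blood$density, 1.06e-3)
  expect_s3_class(materialFromTable("sinus_wall"), "ignored_material")
  expect_s3_class(materialFromTable("artery_wall"), "mooney_rivlin5")
  expect_error(materialFromTable("osteocyte"), "unknown tissue")
})

test_that("degenerate inputs are rejected", {
  m <- mooney_rivlin5()
  expect_error(deformation(diag(c(-1, 1, 1))), "inverted")
  expect_error(mrStrainEnergy(diag(c(0, 1, 1)), m), "inverted")
  expect_error(linearStress(diag(3) * 0.1, linear_elastic(1, 0.4999999999999)),
               "singular|nu")
  expect_error(linear_elastic(1, 0.5), "nu")
  expect_error(mooney_rivlin5(C10 = 0.01, C01 = -0.02), "shear modulus")
  expect_error(mmHgToMPa("a"))
  expect_equal(mmHgToMPa(0), 0)
  expect_equal(mmHgToMPa(50), 0.00666612)
})
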
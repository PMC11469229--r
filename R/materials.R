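# Constitutive models: 5-parameter Mooney-Rivlin hyperelasticity, linear
# elasticity, and the near-zero-stiffness blood placeholder.
#
# Internal unit system: micrometre - microsecond - megapascal.
# Consequences: density is expressed in 1e6 kg/m^3 (water = 1e-3) and
# velocities come out in um/us, numerically equal to m/s.

#' Mooney-Rivlin 5-parameter hyperelastic material
#'
#' Strain energy density
#' \deqn{W = \sum_{i+j=1}^{2} C_{ij}(\bar I_1-3)^i(\bar I_2-3)^j + \frac{1}{D_1}(J-1)^2}
#' with isochoric invariants \eqn{\bar I_k} computed from the
#' \eqn{J^{-2/3}}-scaled stretches. The default coefficients are the
#' smooth-muscle arterial wall fit used throughout the package
#' (C10 = 0.115, C01 = -0.049, C20 = 1.403, C11 = -3.370, C02 = 2.201 MPa).
#'
#' @param C10,C01,C20,C11,C02 polynomial coefficients (MPa).
#' @param D1 volumetric penalty coefficient (1/MPa). Default gives a bulk to
#'   initial-shear modulus ratio of 1000 (near-incompressible,
#'   effective Poisson ratio about 0.4995).
#' @param density mass density in internal units (1e6 kg/m^3).
#' @return object of class `mooney_rivlin5`.
#' @export
mooney_rivlin5 <- function(C10 = 0.115, C01 = -0.049, C20 = 1.403,
                           C11 = -3.370, C02 = 2.201,
                           D1 = NULL, density = 1.10e-3) {
  mu0 <- 2 * (C10 + C01)
  if (mu0 <= 0) stop("initial shear modulus 2*(C10+C01) must be positive")
  if (is.null(D1)) D1 <- 2 / (1000 * mu0) # kappa = 2/D1 = 1000*mu0
  if (D1 <= 0) stop("D1 must be positive")
  if (density <= 0) stop("density must be positive")
  structure(list(type = "mooney_rivlin5",
                 C10 = C10, C01 = C01, C20 = C20, C11 = C11, C02 = C02,
                 D1 = D1, density = density),
            class = c("mooney_rivlin5", "material_model"))
}

#' Linear elastic material
#'
#' Isotropic Hooke's law parameterised by Young's modulus and Poisson's
#' ratio. Inside the nonlinear solvers it is treated as a Saint
#' Venant-Kirchhoff solid (same moduli, finite-strain measure), which
#' reduces to Hooke's law at small strain.
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio, in (-1, 0.5).
#' @param density mass density (1e6 kg/m^3).
#' @return object of class `linear_elastic`.
#' @export
linear_elastic <- function(E, nu = 0.3, density = 1.00e-3) {
  if (E <= 0) stop("E must be positive")
  if (nu <= -1 || nu >= 0.5) stop("nu must lie in (-1, 0.5)")
  if (density <= 0) stop("density must be positive")
  structure(list(type = "linear_elastic", E = E, nu = nu, density = density),
            class = c("linear_elastic", "material_model"))
}

#' @export
print.material_model <- function(x, ...) {
  if (inherits(x, "mooney_rivlin5")) {
    cat(sprintf("Mooney-Rivlin 5-parameter material (MPa):\n  C10=%g C01=%g C20=%g C11=%g C02=%g\n  D1=%g 1/MPa (kappa=%g MPa), mu0=%g MPa, density=%g\n",
                x$C10, x$C01, x$C20, x$C11, x$C02, x$D1, 2 / x$D1,
                2 * (x$C10 + x$C01), x$density))
  } else if (inherits(x, "linear_elastic")) {
    cat(sprintf("Linear elastic material: E=%g MPa, nu=%g, density=%g\n",
                x$E, x$nu, x$density))
  } else if (inherits(x, "ignored_material")) {
    cat("Ignored material (zero mechanical contribution)\n")
  }
  invisible(x)
}

#' Tissue material defaults
#'
#' Returns the default material model for a bone-tissue component: vessel
#' walls are the Mooney-Rivlin 5-parameter fit, marrow is linear elastic at
#' 10 kPa, blood is a near-zero-stiffness placeholder (1e-4 MPa) that
#' retains its mass, and the sinusoid endothelium is an "ignored" sentinel
#' (it contributes neither stiffness nor mass).
#'
#' @param component one of `"arteriole_wall"`, `"artery_wall"`, `"blood"`,
#'   `"sinus_wall"`, `"marrow"`.
#' @return a `material_model` object (or the `ignored_material` sentinel).
#' @export
materialFromTable <- function(component) {
  switch(component,
    arteriole_wall = ,
    artery_wall = mooney_rivlin5(),
    blood = linear_elastic(E = 1e-4, nu = 0.3, density = 1.06e-3),
    marrow = linear_elastic(E = 0.01, nu = 0.3, density = 1.00e-3),
    sinus_wall = structure(list(type = "ignored"),
                           class = c("ignored_material", "material_model")),
    stop("unknown tissue component: ", component)
  )
}

# ---- deformation kinematics -------------------------------------------------

#' Deformation state from a deformation gradient
#'
#' @param F 3x3 deformation gradient (dimensionless). Must have positive
#'   determinant.
#' @return list with `F`, `J`, Cauchy-Green invariants `I1`, `I2`, and the
#'   isochoric invariants `I1bar`, `I2bar`.
#' @export
deformation <- function(F) {
  F <- matrix(as.numeric(F), 3, 3)
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("inverted element: det(F) <= 0")
  C <- crossprod(F) # F^T F
  I1 <- sum(diag(C))
  I2 <- 0.5 * (I1^2 - sum(C * C))
  list(F = F, J = J, C = C, I1 = I1, I2 = I2,
       I1bar = J^(-2 / 3) * I1, I2bar = J^(-4 / 3) * I2)
}

mr_dW <- function(I1b, I2b, m) {
  list(W  = m$C10 * (I1b - 3) + m$C01 * (I2b - 3) +
            m$C20 * (I1b - 3)^2 + m$C11 * (I1b - 3) * (I2b - 3) +
            m$C02 * (I2b - 3)^2,
       W1 = m$C10 + 2 * m$C20 * (I1b - 3) + m$C11 * (I2b - 3),
       W2 = m$C01 + m$C11 * (I1b - 3) + 2 * m$C02 * (I2b - 3))
}

#' Mooney-Rivlin strain energy density
#'
#' @param def a [deformation()] or a 3x3 deformation gradient.
#' @param mat a [mooney_rivlin5()] material.
#' @return energy density W in MPa; zero at the identity.
#' @export
mrStrainEnergy <- function(def, mat) {
  if (is.matrix(def) || length(def) == 9) def <- deformation(def)
  d <- mr_dW(def$I1bar, def$I2bar, mat)
  d$W + (1 / mat$D1) * (def$J - 1)^2
}

#' Mooney-Rivlin Cauchy stress
#'
#' Cauchy stress obtained by pushing forward the strain-energy derivative:
#' the isochoric part is the deviator of
#' \eqn{2[(W_1 + \bar I_1 W_2)\bar b - W_2 \bar b^2]/J}
#' with \eqn{\bar b = J^{-2/3} F F^T}, plus the volumetric pressure
#' \eqn{p = 2(J-1)/D_1}.
#'
#' @inheritParams mrStrainEnergy
#' @return symmetric 3x3 Cauchy stress (MPa); zero at the identity.
#' @export
mrCauchyStress <- function(def, mat) {
  if (is.matrix(def) || length(def) == 9) def <- deformation(def)
  J <- def$J
  bbar <- J^(-2 / 3) * tcrossprod(def$F) # F F^T scaled
  d <- mr_dW(def$I1bar, def$I2bar, mat)
  A <- 2 * ((d$W1 + def$I1bar * d$W2) * bbar - d$W2 * (bbar %*% bbar)) / J
  iso <- A - diag(3) * sum(diag(A)) / 3
  p <- (2 / mat$D1) * (J - 1)
  sig <- iso + p * diag(3)
  (sig + t(sig)) / 2
}

#' First Piola-Kirchhoff stress for a Mooney-Rivlin material
#'
#' `P = J * sigma * F^{-T}`; used by the finite-difference energy-stress
#' consistency checks and the assembly kernels.
#'
#' @inheritParams mrStrainEnergy
#' @return 3x3 first Piola-Kirchhoff stress (MPa).
#' @export
mrPK1 <- function(def, mat) {
  if (is.matrix(def) || length(def) == 9) def <- deformation(def)
  def$J * mrCauchyStress(def, mat) %*% t(solve(def$F))
}

#' Linear-elastic stress from small strain
#'
#' Inverts the isotropic compliance relations
#' \eqn{\epsilon_i = (\sigma_i - \nu(\sigma_j+\sigma_k))/E} and adds the
#' shear terms \eqn{\sigma_{ij} = E/(1+\nu)\,\epsilon_{ij}} for \eqn{i\ne j}.
#'
#' @param strain symmetric 3x3 small-strain tensor.
#' @param mat a [linear_elastic()] material.
#' @return symmetric 3x3 Cauchy stress (same units as `E`).
#' @export
linearStress <- function(strain, mat) {
  strain <- matrix(as.numeric(strain), 3, 3)
  if (max(abs(strain - t(strain))) > 1e-12 * max(1, max(abs(strain))))
    stop("strain tensor must be symmetric")
  E <- mat$E; nu <- mat$nu
  if (abs(nu - 0.5) < 1e-12) stop("singular compliance: nu = 0.5")
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  lam * sum(diag(strain)) * diag(3) + 2 * mu * strain
}

#' Von Mises equivalent stress
#'
#' \eqn{\sigma_S = \sqrt{\tfrac32\,\mathrm{dev}(\sigma):\mathrm{dev}(\sigma)}};
#' rotation-invariant, zero for hydrostatic states.
#'
#' @param stress symmetric 3x3 stress tensor.
#' @return scalar equivalent stress (same units as input).
#' @export
vonMises <- function(stress) {
  stress <- matrix(as.numeric(stress), 3, 3)
  dev <- stress - diag(3) * sum(diag(stress)) / 3
  sqrt(1.5 * sum(dev * dev))
}

#' Small-strain tangent moduli of a material
#'
#' For Mooney-Rivlin: initial shear modulus `mu0 = 2(C10+C01)` and the
#' incompressible-limit Young's modulus `E0 = 6(C10+C01)`; for linear
#' elastic the given `E`, `nu`. Used for time-step estimation and checks.
#'
#' @param mat a `material_model`.
#' @return list with `mu`, `kappa`, `E`, `density`.
#' @export
smallStrainModuli <- function(mat) {
  if (inherits(mat, "mooney_rivlin5")) {
    mu <- 2 * (mat$C10 + mat$C01)
    list(mu = mu, kappa = 2 / mat$D1, E = 3 * mu, density = mat$density)
  } else if (inherits(mat, "linear_elastic")) {
    mu <- mat$E / (2 * (1 + mat$nu))
    kappa <- mat$E / (3 * (1 - 2 * mat$nu))
    list(mu = mu, kappa = kappa, E = mat$E, density = mat$density)
  } else {
    list(mu = 0, kappa = 0, E = 0, density = 0)
  }
}

#' Convert mmHg to MPa
#'
#' @param p pressure in mmHg.
#' @return pressure in MPa (`p * 1.333224e-4`).
#' @export
mmHgToMPa <- function(p) p * 1.333224e-4
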
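---
title: "Methods: finite-element mechanopropagation analysis of bone-marrow vessels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finite-element mechanopropagation analysis of bone-marrow vessels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`vesselmech` studies how exercise-induced mechanical stimuli propagate from
cortical bone along the bone-marrow vasculature. Three vessel archetypes are
modelled at the scale of a mouse tibia:

* **artery** — 200 µm long, lumen radius 15 µm (configurable), wall
  thickness 14.3 µm; smooth-muscle-rich wall, hyperelastic;
* **arteriole** — 200 µm long, lumen radius 10 µm, wall 5 µm; hyperelastic;
* **sinusoid** — 300 µm long, lumen radius 20 µm; its discontinuous
  endothelium carries no load, so the domain is a blood column embedded in
  linear-elastic marrow.

Three load cases drive the mechanics:

1. **intravascular pulse pressure** (50 mmHg for walking, 100 mmHg for
   running) applied as a follower pressure on the endovascular surface;
2. **cortical-bone bending**, entering through the kinematic chain
   strain → arc angle → midspan transverse displacement (below), applied as
   a prescribed displacement at the vessel midspan with both ends fixed;
3. **vibratory end stretch** — a 1 µm axial displacement ramped over 1 µs at
   one longitudinal end — integrated in time with explicit dynamics, alone
   or on top of a statically pre-pressurized configuration.

The output of interest is the surface von Mises stress
$\sigma_S = \sqrt{\tfrac32\,\mathrm{dev}\,\sigma : \mathrm{dev}\,\sigma}$
and the statistics built on it: its unwrapped (z, arc) grid at 10 µm × 10 µm
cells, the Gaussian-fitted histogram mode, the area fraction above 10 kPa,
the peak $\sigma_{S,\max}$, and the average propagation velocity $v_S$ of
the travelling stress front.

## Constitutive models and units

Vessel walls use a 5-parameter Mooney–Rivlin strain-energy density

$$W = \sum_{i+j=1}^{2} C_{ij}\,(\bar I_1 - 3)^i(\bar I_2 - 3)^j
      + \frac{1}{D_1}(J-1)^2,$$

with isochoric invariants $\bar I_k$ built from $J^{-2/3}$-scaled stretches
and the default wall coefficients (MPa)
$C_{10} = 0.115$, $C_{01} = -0.049$, $C_{20} = 1.403$, $C_{11} = -3.370$,
$C_{02} = 2.201$, an arterial-wall fit from the smooth-muscle literature.
The initial shear modulus is $\mu_0 = 2(C_{10}+C_{01}) = 0.132$ MPa and the
incompressible-limit Young's modulus $6(C_{10}+C_{01}) = 0.396$ MPa. Because
no volumetric coefficient is part of that parameter set, $D_1$ defaults to
$\kappa/\mu_0 = 1000$ (effective Poisson ratio ≈ 0.4995, i.e. a
near-incompressible wall); it is exposed for overriding. Marrow is linear
elastic at $E = 10$ kPa and blood is a near-zero-stiffness placeholder
($E = 10^{-4}$ MPa) that retains its mass — "mass only" in the sense that it
loads the dynamics without resisting shear.

The internal unit system is **µm – µs – MPa**. It is self-consistent for
dynamics: densities are expressed in $10^6\,$kg m$^{-3}$ (water $=10^{-3}$)
and velocities come out in µm/µs, numerically equal to m/s. Densities are
soft-tissue literature values: wall $1.10\times10^{-3}$, blood
$1.06\times10^{-3}$, marrow $1.00\times10^{-3}$. Marrow and blood use
Poisson ratio 0.3. Post-processing reports stresses in kPa.

## Synthetic geometry

Real vessel geometries come from image-based surface reconstructions that
are not redistributable, so the package generates synthetic counterparts:
straight (optionally tortuous) circular tubes with the class dimensions
above. The cross-section is a triangulated disk — a centre node, concentric
rings shared by blood and wall (or marrow) — extruded along z into prisms,
each split into three tetrahedra by a *smallest-global-index diagonal rule*
that is deterministic and conformal across all shared faces. A filled lumen
is required because the blood mass participates in the dynamics; the node
count is therefore $(n_{axial}+1)(n_{circ} \cdot n_{rings} + 1)$, the $+1$
being the axis node of each cross-section.

The default characteristic edge is 3 µm. The wall must be at least two
element layers thick, and an explicit resolution that cannot satisfy this is
rejected. The polygonal circumference makes mesh volumes underestimate
analytic cylinder volumes by $O(n_{circ}^{-2})$ — under 0.5% at the default
resolution, and the convergence rate is verified by test.

`perturbCenterline()` adds a smooth sinusoidal transverse displacement with
seeded random direction and phase, normalised so the maximum node
displacement equals the requested amplitude. This emulates the tortuosity of
real marrow vessels, which is what spreads the surface-stress distribution;
on a perfectly straight tube the inflation stress is nearly uniform and the
10 kPa tail is empty. Scenario runs that examine area fractions therefore
use a tortuous artery (amplitude 6 µm, wavelength 80 µm — comparable to the
visual irregularity of reconstructed vessels). What the generator does *not*
emulate: branching, elliptical lumina, wall-thickness variation, and
image-noise artefacts. Conclusions from passing tests are therefore about
the mechanics on smooth tubular topologies, not about geometric extremes.

The simplified counterparts of the CAD processing chain operate on
triangulated surfaces: `offsetSurfaceInward()` (constant-thickness shells by
vertex-normal offset with flipped-face and triangle–triangle
self-intersection checks), `smoothSurface()` (volume-preserving two-step
band-pass Laplacian smoothing, < 1% volume change per 10 iterations),
`subdivideMidpoint()`, and STL import with vertex deduplication (1e-6 µm)
plus bridging of boundary loops whose chord is ≤ 4.2 µm.

## Static solver

Total-Lagrangian Newton iteration on linear tetrahedra with load stepping
(10 equal increments by default, automatic bisection on divergence, one
recovery step after each success). Pressure is a follower load: facet
normals and areas are re-evaluated on the deformed configuration each
iteration.

Near-incompressible linear tetrahedra lock volumetrically. The package uses
the *average nodal pressure* projection: element Jacobians are volume-
averaged into nodal patches, $\bar J_a = v_a / V_a$, and the volumetric
stress uses the patch pressure $\tilde p_e$, the mean of
$U'(\bar J_a) = 2(\bar J_a - 1)/D_1$ over the element's nodes. The residual
is exact for this functional. The tangent is assembled as (i) a per-element
central finite-difference tangent of the isochoric force and (ii) the exact
projected volumetric stiffness $G^T \mathrm{diag}(U''/V_a)\, G$, where $G$
collects $\partial v_a/\partial x$; the small geometric term
$\tilde p\,\partial^2 v$ is omitted. Convergence is measured against the
full internal-force norm (including reactions), so displacement-driven cases
keep a meaningful reference; the default relative tolerance is $10^{-6}$.
The tangent is symmetric, so the linear solves use sparse Cholesky with an
LU fallback.

Boundary conditions: both longitudinal ends are fully fixed by default
(a flag relaxes this to axial-only "plane ends"). Static arteriole/artery
runs include the wall region only — blood is mass-only and the surrounding
marrow is two orders softer than the wall — while coupled runs keep blood in
both phases so the static and dynamic formulations match exactly. Bending
applies the transverse displacement to the one-element-wide node ring
nearest $z = L/2$.

Verification oracles, all in the test suite: a distorted-mesh patch test
(uniform stress to 1e-8), the Lamé thick-walled cylinder (hoop stresses
within 5%, measured by volume-weighted radial-layer means and an
$A + B/r^2$ recovery to the inner surface), small-pressure linearity
(doubling), and rotation objectivity.

## Explicit dynamics

Lumped-mass central differences. The stable step is
$\Delta t = s\,\min_e h_e/c_e$ with $h_e$ the minimum tetrahedron altitude
($3V/A_{\max}$), $c_e = \sqrt{(\kappa + \tfrac43\mu)/\rho}$ the dilatational
speed, and safety $s = 0.5$. The near-incompressible wall sets the step
(≈ 346 µm/µs dilatational speed), giving $O(10^4)$ steps for a 20 µs run.

The end pulse is a half-cosine ramp to the amplitude over the rise time,
then held — bounded acceleration avoids spurious ringing; a linear ramp
option is retained. No damping by default; a mass-proportional coefficient
is available. The step count follows from the CFL limit rather than any
fixed prescription.

An energy ledger (external work from reactions and pressure via
trapezoidal increments, kinetic, strain) is maintained; undamped runs must
balance within 1%, and the integrator aborts with a diagnostic when kinetic
energy exceeds 10× external work or a field goes non-finite. Verified
against the rod wave speed $\sqrt{E/\rho}$ (within 5%), causality at the far
end, axisymmetry of axisymmetric runs, and a dt-halving change of the peak
stress trace below 2%.

`couplePrestress()` first solves the static follower-pressure inflation on
the full mesh, then integrates the pulse from that stressed configuration
with the pressure held throughout. At zero pressure the code path is the
cold start itself, bitwise. During the coupled dynamic phase the static
fixtures are retained except that the pulsed end's axial component follows
the prescribed ramp.

## Bending kinematics

A bone segment of chord length $L$ bent into a circular arc while its axis
stretches by $\varepsilon$ satisfies arc/chord $= \theta/\sin\theta = 1 +
\varepsilon$, solved for the half-angle $\theta \in (0, \pi)$ by bracketed
bisection to $10^{-10}$ ($\theta \approx \sqrt{6\varepsilon}$ for small
strain; $\varepsilon$ is capped at 0.2 to keep the root bracketed, far above
the physiological 0.001–0.002). The midspan transverse displacement is the
arc sagitta evaluated with the deformed arc length,

$$d = \frac{L}{2}\,(1+\varepsilon)\,\tan\frac{\theta}{2},$$

giving $d = 3.88$ µm at $\varepsilon = 0.001$ and $5.49$ µm at
$\varepsilon = 0.002$ for $L = 200$ µm. The chord-based variant without the
$(1+\varepsilon)$ factor differs by 0.1–0.3% and is available via
`arc_length = FALSE`. A complementary-angle construction
$d = (L/2)\tan((\pi-\theta)/2)$ is *not* used: it measures the distance to
the arc's centre-side intersection and is three orders of magnitude too
large for these strains. The vessel is assumed to follow the bone's
curvature ($d_{vessel} = d_{bone}$); beam-theory stress recovery of the
bone itself is out of scope.

## Surface statistics

* **Grid sampling** unwraps a (topologically cylindrical) facet set into
  (z, arc) cells — default 10 µm — by area-averaging facet values at their
  centroids; cell areas are conserved exactly, and a surface whose radial
  spread exceeds half its mean radius is rejected with a pointer to
  facet-level statistics.
* **Histogram + Gaussian fit**: area-weighted, 1 kPa bins by default;
  distributions narrower than 12 bins are re-binned proportionally so the
  least-squares fit (Levenberg–Marquardt) is well posed. A fitted mode
  outside the data range or $R^2 < 0.8$ flags a poor fit, and a
  non-convergent fit falls back to the empirical mode with a warning.
* **Threshold fraction**: area-weighted by default; a cell-count variant is
  provided because either convention is defensible.
* **Front tracking**: per snapshot the front is the axial position of the
  global maximum of outer-surface $\sigma_S$; values within 2% of the
  maximum count as ties, resolved to the position farthest from the loaded
  end (on an ideal rod the stressed band is flat behind the front, so a
  strict argmax would wander in discretization noise). $v_S$ is the
  end-to-end average (last − first position)/(elapsed time), with
  per-interval velocities also reported.

## Problem sizes and reproducibility

The shipped tests and scenario runs use desk-scale resolutions chosen as
the package's defaults for a single CPU: characteristic edges of 5–8 µm for
the vessel meshes (the 3 µm default remains available), a 16 µm-long
cylinder section for the Lamé benchmark, and 18–20 µs dynamic windows with
snapshots every 1–2 µs. At these sizes the documented tolerances hold with
margin; refining toward 3 µm moves the Lamé and volume checks monotonically
toward their analytic limits (verified by the convergence tests). All
randomness — centerline irregularity, synthetic test distributions — is
seeded, and identical configurations reproduce identical results bitwise.

## Known limitations

* Blood is a mass-carrying placeholder solid, not a fluid: no pulse-wave
  fluid–structure interaction, no viscous damping of the wall by the lumen.
* The blood–wall interface shares nodes (bonded). With the blood's
  near-zero shear stiffness the tangential tractions it transmits are
  negligible, approximating frictionless contact, but true slip is not
  modelled.
* The sinusoid's marrow annulus is truncated at 100 µm (configurable)
  rather than extending to the full marrow cavity; the outer boundary is
  fixed. Stress decays with distance from the lumen, but very long-time
  reflections from the artificial boundary are present in principle.
* Isotropic wall only: no fiber-reinforced (Holzapfel-type) anisotropy, no
  viscoelasticity.
* Linear tetrahedra with nodal-pressure projection control but do not
  eliminate locking; absolute stiffness at coarse resolution is
  overestimated by a few percent (the Lamé benchmark quantifies this).
* Front velocities on strongly dispersive media (the sinusoid) depend
  mildly on the tie tolerance; the default 2% is stated and fixed.
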
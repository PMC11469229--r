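# vesselmech

Finite-element analysis of **mechanopropagation** — the transmission of
exercise-induced mechanical stimuli from cortical bone along the bone-marrow
vasculature — for researchers in bone mechanobiology and vascular
biomechanics who want a scriptable, fully synthetic counterpart of
image-based vessel simulations.

The package builds tetrahedral meshes of the three marrow vessel archetypes
(artery: 200 µm long, 14.3 µm wall; arteriole: 200 µm, 5 µm wall; sinusoid:
300 µm blood column in linear-elastic marrow, its endothelium mechanically
ignored), assigns tissue properties, and solves the three loadings that
matter physiologically:

* **intravascular pulse pressure** (50 mmHg walking / 100 mmHg running) as a
  follower load on the endovascular surface — static nonlinear FEA;
* **cortical-bone bending** at strain ε = 0.001–0.002, entering as a
  midspan transverse displacement `d = (L/2)(1+ε)tan(θ/2)` with
  `θ/sin θ = 1+ε` — static FEA;
* **vibratory end stretch** (1 µm axial displacement in the first 1 µs) —
  explicit central-difference dynamics, optionally coupled with a held pulse
  pressure from a pre-inflated static state.

Vessel walls follow a 5-parameter Mooney–Rivlin hyperelastic law

```
W = Σ_{i+j=1..2} C_ij (Ī₁−3)^i (Ī₂−3)^j + (1/D₁)(J−1)²,
C10 = 0.115, C01 = −0.049, C20 = 1.403, C11 = −3.370, C02 = 2.201 MPa
```

with a nodal-patch pressure projection against volumetric locking; marrow is
linear elastic at 10 kPa and blood carries mass but near-zero stiffness.
Surface von Mises stress σ_S is sampled on an unwrapped 10 µm × 10 µm grid
and summarised by Gaussian-fitted histograms, the area fraction above
10 kPa, the peak σ_Smax, and the front propagation velocity v_S (µm/µs).

## Worked example

Inflate a synthetic artery at the walking and running pulse pressures and
compare the surface-stress statistics:

```r
library(vesselmech)

mesh <- makeTubeMesh(vesselSpec("artery", characteristic_edge = 6))
mats <- defaultMaterials(mesh)

s50  <- summarize(solveStatic(mesh, mats, loadCase(pulse_pressure = 50)),  mesh)
s100 <- summarize(solveStatic(mesh, mats, loadCase(pulse_pressure = 100)), mesh)

cat(sprintf("mode  50 mmHg: %.2f kPa   mode 100 mmHg: %.2f kPa   ratio %.2f\n",
            s50$summary$gaussian_fit$mu, s100$summary$gaussian_fit$mu,
            s100$summary$gaussian_fit$mu / s50$summary$gaussian_fit$mu))
cat(sprintf("sigma_Smax: %.2f vs %.2f kPa\n", s50$sigma_smax, s100$sigma_smax))
```

```
mode  50 mmHg: 4.08 kPa   mode 100 mmHg: 8.49 kPa   ratio 2.08
sigma_Smax: 4.27 vs 8.77 kPa
```

The fitted histogram mode doubles with the pulse pressure — the inflation
response is linear at these strains. The bending kinematics print the
standard displacement table:

```r
bendSolution(c(0.001, 0.002), L = 200)
```

```
  epsilon      theta         r        d
1   0.001 0.07743257 1292.7376 3.877438
2   0.002 0.10946792  915.3366 5.489826
```

so a bone bending strain of 0.001 (0.002) deflects a 200 µm vessel by
3.88 µm (5.49 µm) at midspan. A vibratory run returns the front trace and
energy ledger:

```r
ser <- runExplicit(mesh, mats,
                   loadCase(end_pulse = list(amplitude = 1, rise = 1,
                                             direction = "z"),
                            fixed = list()),
                   duration = 20, output_times = c(1, 2, 5, 10, 20))
trackFront(ser, mesh)$v_s   # mean front velocity, um/us
energyDrift(ser)            # relative energy-balance drift (undamped)
```

Typical desk-scale output: peak surface stress ≈ 25 kPa at t = 1 µs decaying
over 20 µs, front velocity of order 10 µm/µs on the hyperelastic wall versus
~3 µm/µs on a sinusoid, and energy drift in the 1e-5 range.

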
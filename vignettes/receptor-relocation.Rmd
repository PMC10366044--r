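---
title: "Modelling VEGFR2 relocation on a spreading endothelial cell membrane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling VEGFR2 relocation on a spreading endothelial cell membrane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegfr2sim)
```

## The biological problem

When an endothelial cell settles onto a slide coated with gremlin, a ligand of
the growth-factor receptor VEGFR2, the receptors relocate within minutes from
a uniform distribution to a strong polarization at the basal membrane. Three
processes interact: the receptor–ligand reaction R + L ⇌ C at the
cell–substrate interface, diffusion of free receptors in the membrane, and the
advection of the membrane itself as the cell flattens from a sphere into a
spread shape. `vegfr2sim` simulates this coupled system at desk scale and also
provides the two short-range electrostatic traction models whose comparison
supports the conclusion that electrostatic attraction is *not* what drives
spreading — that requires the cytoskeleton.

## Model

### Kinematics surrogate

The mechanical problem is one-way coupled to the chemistry (protein transport
does not feed back on deformation), so any motion that reproduces the observed
contact-area history exercises the chemistry identically. Instead of a bulk
finite-element model, the package prescribes a family of volume-conserving
shapes: a flat contact disc of radius $a(t)$ plus a spherical cap, with $a(t)$
piecewise linear in time — 0 at $t=0$, 3.35 µm at the end of attachment
(300 s), 19.8 µm at the end of translocation (600 s), constant afterwards
(the measured contact diameters are 6.7 µm and 39.6 µm). The cap height
follows from conservation of the enclosed volume $\tfrac43\pi r_0^3$ with
$r_0 = 10$ µm.

Material points are placed on the current shape by a monotone area-fraction
map: the reference node with cumulative area fraction $f$ (counted from the
pole facing the slide) lands at the current-surface point with the same
cumulative fraction. Two consequences follow, both deliberate simplifications:

* the areal stretch $\lambda_a$ (the Nanson factor $J\,\lvert F^{-T} n_R
  \rvert$) is **spatially uniform**, equal to the global area ratio
  (≈ 2.07 at the final shape);
* the gap $g_N$ is exactly zero on the disc and grows smoothly along the cap.

The kinematics provider is pluggable: `step_base()`/`step_split()` accept any
pair of frames carrying per-node `g_N` and `lambda_a`, so a higher-fidelity
motion (e.g. from an external FEM) can be substituted without touching the
transport code. The slide is the plane $y = 0$; `hsm_check()` verifies the
frictionless-contact complementarity triple $g_N \ge 0$, $p_N \le 0$,
$p_N g_N = 0$ for any candidate traction field.

### Chemistry

Binding is much faster than transport, so the reaction is closed by
instantaneous equilibrium. In referential densities (molecules per unit
*undeformed* area — these integrate to molecule counts without a Jacobian) the
closure reads $c_C = c_R\,c_L/\alpha$ with
$\alpha = (c_R^{max} c_L^{max}/c_C^{max})\,\lambda_a/K_{eq}$, and
$K_{eq} = \exp(-\Delta G^0 / \mathcal{R}T)$. With the calibrated
$\Delta G^0 = -32949$ J/mol the published constant $K_{eq} = 354058.32$ is
recovered at $T = 310.15$ K (37 °C, not printed in the calibration but the
unique temperature reconciling the two numbers — verified to 0.05% in the
test suite).

Ligands sit on the slide and cannot flow; their availability is slaved to the
gap, $S_L = c_L^{av}\exp(-g_N/\ell_{chem})$ with $c_L^{av} = 90$ molecules/µm²
and $\ell_{chem} = 0.2$ µm. Because ligand and complex are immobile,
$c_L + c_C = S_L$ holds pointwise, and the problem reduces to one evolution
equation for the difference $c_D = c_R - c_L$ plus a per-node quadratic
constraint whose unique non-negative root gives $c_R$
(`solve_equilibrium_base()`).

FRAP shows ~23% of VEGFR2 to be immobile. The split variant carries two pools
with identical chemistry but different motility. Summing free and complexed
parts of each pool gives conserved nodal totals $c_m$ and $c_i$; the immobile
total is constant in time at every node (no flux, no receptor
internalization/exposure — receptor supplies are zero), and the ligand
bookkeeping becomes a single monotone scalar equation in $c_L$
(`solve_equilibrium_split()`). This reduction of the split system to
$(c_m, c_i, c_L)$ is the package's own derivation; it is validated against
bisection oracles and the degenerate-split limit in the test suite.

The saturation-aware mass-action rate (`mass_action_rate()`, occupancy ratios
$\vartheta/(1-\vartheta)$) is provided as a diagnostic only; the equilibrium
closure is the production path.

### Transport discretization

Axisymmetry reduces the sphere to a 1D meridian: linear finite elements in
$\theta$ with the surface measure $2\pi r_0^2 \sin\theta\,d\theta$. The
stiffness matrix uses the exact element integrals, so constants are in its
kernel to machine precision. Time integration is the trapezoidal rule for the
diffusive flux with the supply difference taken between step endpoints;
within each mechanical step the chemo problem is sub-incremented
(`substeps`, default 100, the validated ratio of mechanical to chemical time
scales; the acceptance studies use 10 and document it) with $S_L$ and
$\alpha$ interpolated linearly between frames. Each sub-step solves the
coupled linear-system/constraint pair by a staggered Newton iteration
(tridiagonal solve, nodal constraint re-solve, Jacobian
$M + \tfrac{\Delta t}{2} K\,\mathrm{diag}(\partial c_R/\partial c_D)$) to a
relative update below $10^{-10}$, at most 50 iterations. The inner loop is
compiled (Rcpp), which keeps a full three-stage run at 200 nodes around two
to three minutes.

Two numerical choices deserve a note:

* **Mass lumping.** The mass matrix defaults to the exact spherical-zone node
  weights rather than the consistent FE mass. The trapezoidal scheme then
  conserves *exactly* the quadrature that `integrate_totals()` uses, so the
  global receptor count (free + complexed, both pools) is constant to
  round-off at any resolution, and nodal positivity is preserved — matching
  the decision to impose the equilibrium constraint point-wise rather than in
  an $L_2$ sense. A consistent mass is available
  (`assemble_operators(..., mass = "consistent")`); it conserves the
  $M$-weighted total instead, which differs from the zone quadrature by
  $O(\Delta\theta^2)$.
* **Supply baseline.** At $t = 0$ the sphere touches the slide at a single
  point where the gap formula already gives $S_L = 90$; the stored state
  nevertheless starts from $S_L = 0$ (consistent with zero initial ligand and
  complex) and the supply ramps in over the first mechanical step. At the
  first contact instant the difference field at the pole becomes
  $c_D = 19.1 - 90 = -70.9$, the regime in which the quadratic constraint is
  exercised hardest; the solver uses the cancellation-safe branch of the
  quadratic formula there.

Initial conditions: 24000 receptors uniformly on the sphere
(19.0986 molecules/µm²; the commonly quoted 19.1 is this value rounded, and
the printed split densities 4.393/14.707 are 23%/77% of the *rounded* value),
zero ligand and complex.

## Verification strategy

Every closed-form solve is checked against an independent bisection oracle on
randomized inputs; the cap-height cubic likewise. The time integrator is
cross-checked against a brute-force explicit-Euler march (own inline closure,
1000× smaller steps) over a 30-node attachment window — agreement is ~0.01%,
asserted at 0.5%. Spatial accuracy is verified against the Laplace–Beltrami
spectrum of the sphere: a $\cos\theta$ perturbation decays at
$\exp(-2 D_R t / r_0^2)$ within 1% at 200 nodes, and the discrete eigenvalue
converges under refinement. Conservation (global receptor count, nodal ligand
bookkeeping, immobile totals) is asserted at every output time of every run
in the suite. Problem sizes in the tests (30–200 nodes, sub-increment factors
2–10, windows of 40–7200 s) were chosen once as the smallest sizes at which
the asserted tolerances are comfortably met by the converged behaviour.

## What the surrogate does and does not reproduce

The synthetic study conditions — schedule, contact radii, chemistry constants,
receptor count, the 23% immobile fraction — are the validated calibration of
the real experiment, and the package reproduces the calibrated quantities
(reference area 1256.64 µm², $K_{eq}$, contact areas 35.3/1232 µm²,
conservation of 24000 receptors) essentially exactly. Three observed outcomes,
however, depend on *spatially varying* areal stretch, which the uniform-
stretch map deliberately does not carry:

* **Attachment plateau.** The complex density inside the contact area
  saturates to 88.8 molecules/µm² by 300 s, 98.7% of the available-ligand
  ceiling of 90 — just outside a 1% band. The tangent-sphere rim leaves the
  slide at a shallow (~20°) angle, so a ~2 µm wide partially-supplied band
  ($g_N < 3\ell_{chem}$) competes with the rim for receptors. The converged
  value is insensitive to mesh (100–400 nodes), sub-incrementation (10–100)
  and step size (0.5–0.1 s).
* **Coffee ring.** During translocation a sharp rim and a weak local maximum
  do form at the advancing contact boundary, but the *global* maximum of the
  complex density remains in the attachment-saturated core. The border ring
  of the observed basal distributions is a current-configuration feature: the
  core's current density is diluted by the large local basal stretch of the
  real deformation, which a uniform $\lambda_a$ cannot express.
* **Residual free receptors.** With uniform stretch, the reference area
  mapped to the final contact disc is $\pi a^2 / \lambda_a \approx 595$ µm²,
  so the referential ligand capacity at the reduced availability of
  60 molecules/µm² (~36000 binding sites) exceeds the 24000 receptors, and
  the near-equilibrium end state leaves only ~1% of VEGFR2 unbound, versus
  ~30% observed. Matching the observation requires a local basal stretch of
  roughly 4, i.e. a capacity of ~17000 — information that only a full
  mechanical model supplies. The split model's immobile pool does survive
  apically as expected (referential residual ≈ 23–24% of the initial
  density); dividing by the global $\lambda_a \approx 2.07$ halves the
  current-configuration ratio to ≈ 11–12%.

These three discrepancies are asserted at their nominal tolerances in
`tests/testthat/test-acceptance.R` and are the suite's known red entries; a
kinematics provider with realistic non-uniform stretch is the extension that
would close them.

## Electrostatic tractions

`traction_gn()` implements the screened-Coulomb model
$-\mathcal{C}(Kg+1)[(Kg+1)^2+1]\,g^{-5} e^{-2Kg}\rho_{rl}$ (defined for
$g \ge h_0 = 9$ nm; $\mathcal{C} = 1.17\times10^{-7}$ fN µm⁻⁵, $K = 1$ µm⁻¹
— the inverse Debye length is quoted unitless in the source, and the µm⁻¹
reading is exposed as a parameter; the stated unit of $\mathcal{C}$ combined
with $g^{-5}$ and $\rho_{rl}$ is treated as dimensionally self-consistent in
the model's own unit system). `traction_exp()` implements
$-Q(g/\delta_p)e^{-g/\delta_p}$ with $Q = 5\times10^7$ fN/µm²,
$\delta_p = 0.13$ µm, peaking at $Q/e$ at $g=\delta_p$. Over the
physiological gap range the exponential model exceeds the screened-Coulomb
one by roughly four orders of magnitude (`traction_profile()`), which is the
quantitative content of the claim that physically plausible electrostatics
cannot supply spreading tractions; accordingly these forces are diagnostic
outputs and never feed back into the kinematics. The default
$\rho_{rl} = 10^5$ molecules/µm² is the literature constant; it is defensible
only as a count of *all* membrane receptors, so `effective_rho_rl()` offers
the pointwise $\min(c_R, c_L)$ alternative from a simulated field state.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `r0` | 10 | µm | suspended cell radius |
| `N_receptors` | 24000 | — | total VEGFR2, conserved |
| `dG0` | −32949 | J/mol | binding free energy |
| `T` | 310.15 | K | temperature |
| `cLmax` | 16000 | mol/µm² | ligand saturation |
| `cLav` | 90 | mol/µm² | available ligands at contact (60 in the low-ligand variant) |
| `ell_chem` | 0.2 | µm | gap scale of ligand availability |
| `D_R` | 0.198 | µm²/s | receptor diffusivity (FRAP) |
| `immobile_frac` | 0.23 | — | immobile VEGFR2 fraction (FRAP) |
| `dt_stage` | 0.5/0.1/0.05 | s | mechanical steps per stage |
| `substeps` | 100 | — | chemo sub-increments per mechanical step |
| `a_attach`, `a_final` | 3.35, 19.8 | µm | contact radii at stage ends |

## A short run

```{r example, eval = FALSE}
cfg <- default_config()
cfg$t_stop <- 300          # attachment stage only
cfg$stages$substeps <- 10L
traj <- run_simulation(cfg)
tail(traj$totals, 1)
#      t N_R_free      N_C N_L_free N_L_available contact_area
#    300  19759.1 4240.897 59.40268        4300.3     35.25652
```

By the end of attachment ~4240 complexes have formed inside a 35.3 µm²
contact area, receptors are conserved (19759.1 + 4240.9 = 24000), and nearly
all available ligand under the contact disc is bound (59 of 4300 available
remain free).

## Known limitations

Beyond the stretch-related items above: the surrogate assumes axisymmetry
(as do all reported experiments); adaptive time stepping and 2D unstructured
surface meshes are out of scope (the operator interface permits a
triangulated backend); receptor internalization/exposure, synthesis,
multi-ligand competition and integrin crosstalk are not modelled.
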
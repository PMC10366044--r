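# vegfr2sim

Simulation of VEGFR2 receptor relocation on the membrane of an endothelial
cell adhering to a gremlin-coated slide.

When an endothelial cell lands on a substrate coated with an immobilized
VEGFR2 ligand, the receptors polarize to the basal membrane within minutes.
The package models this as a surface reaction–diffusion problem on an
advecting membrane, written in referential (pulled-back) densities on the
undeformed sphere:

- reaction R + L ⇌ C closed by instantaneous equilibrium,
  `c_C = c_R c_L / α` with `α = c_L^max λ_a / K_eq` and
  `K_eq = exp(−ΔG⁰/RT)`;
- gap-slaved ligand availability `S_L = c_L^av exp(−g_N/ℓ_chem)` (ligands and
  complexes cannot flow, so `c_L + c_C = S_L` pointwise);
- Fickian diffusion of free receptors (`D_R` from FRAP), reducing the system
  to one parabolic equation for `c_D = c_R − c_L` plus a per-node quadratic
  constraint;
- an optional mobile/immobile split (23% of VEGFR2 is immobile by FRAP) in
  which only the free mobile pool diffuses and the immobile nodal total is
  conserved exactly;
- a prescribed, volume-conserving spherical-cap kinematics (contact disc +
  cap) driven by the measured contact-radius history — 0 → 3.35 µm during
  attachment (0–300 s), → 19.8 µm during translocation (300–600 s), frozen
  during the diffusion stage (600–7200 s) — standing in for the one-way
  coupled cell mechanics;
- the two short-range electrostatic binding-traction models (screened-Coulomb
  and exponential) whose four-orders-of-magnitude disparity underpins the
  conclusion that electrostatics cannot drive cell spreading.

Spatial discretization is 1D axisymmetric linear finite elements on the
meridian with the surface-of-revolution measure; time integration is a
trapezoidal scheme with chemo sub-incrementation and a staggered Newton
solve of the nodal equilibrium constraint (compiled core via Rcpp). See the
methods vignette (`vignettes/receptor-relocation.Rmd`) for the model,
numerics, and known limitations of the kinematics surrogate.

## Worked example

Attachment stage at 200 meridian nodes, sub-increment factor 10:

```r
library(vegfr2sim)
cfg <- default_config()
cfg$t_stop <- 300              # attachment stage only
cfg$stages$substeps <- 10L
traj <- run_simulation(cfg)
tail(traj$totals, 1)
#>      t N_R_free      N_C N_L_free N_L_available contact_area
#> 31 300  19759.1 4240.897 59.40268        4300.3     35.25652
```

By 300 s, 4240.9 complexes have formed inside the 35.3 µm² contact area;
receptors are conserved (19759.1 + 4240.9 = 24000 to round-off) and almost
all ligand available under the contact disc is bound. The maximum nodal
complex density inside the contact area,

```r
st <- traj$fields[[length(traj$fields)]]
frame <- map_reference_to_current(traj$mesh, cap_shape(3.35, 4/3*pi*1000), 300)
max(st$c_C[frame$contact])
#> [1] 88.81844
```

sits at 98.7% of the 90 molecules/µm² available-ligand ceiling. The traction
comparison behind the electrostatics argument:

```r
traction_profile(c(0.1, 0.13, 0.5))
#>      g   traction_gn traction_exp        ratio
#> 1 0.10 -2.328691e+03    -17821899 7.653182e+03
#> 2 0.13 -6.251366e+02    -18393972 2.942392e+04
#> 3 0.50 -6.714536e-01     -4108027 6.118110e+06
```

A thin CLI wrapper is installed at `inst/exec/vegfr2sim`
(`run`, `tractions`, `profile` subcommands); configurations are YAML files
(`inst/extdata/default-config.yaml` is the template read by
`read_config()`).

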
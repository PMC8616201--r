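# ipdt — treatment planning for interstitial photodynamic therapy of brain tumors

`ipdt` is an R package for planning interstitial photodynamic therapy
(iPDT) of glioblastoma: 635 nm light delivered through cylindrical
diffusing optical fibers inserted stereotactically into a segmented brain
volume. It answers the planner's question — *given these fiber
trajectories, what volume actually receives a therapeutic light dose, and
how much of the contoured tumor does it cover?*

The pipeline:

1. **Tissue optics** — a versioned table of absorption (µa), scattering
   (µs), anisotropy (g) and refractive index for the seven segmented brain
   tissue classes (CSF, grey/white matter, necrotic, non-enhancing and
   enhancing tumor, oedema) at 635 nm, plus diffusion-theory closed forms
   (µs′ = µs(1−g), µeff = √(3µa(µa+µs′))) used as engine validation
   oracles.
2. **Fiber source model** — diffusers as isotropic line sources; the axial
   launch-position density is a super-Gaussian
   p(z) ∝ exp(−((z−c)²/2w²)^k) fitted to measured emission profiles
   (flat-top default when none is supplied); 200 mW per cm of diffuser.
3. **Monte Carlo transport** — a compiled voxel-grid photon-packet engine
   (dimensionless stepping, exact boundary sub-stepping,
   Henyey–Greenstein scattering, Russian roulette, track-length fluence
   tally with a collision-tally cross-check), bit-reproducible under a
   fixed seed.
4. **Dosimetry** — per-fiber fluence-rate maps summed, × illumination time
   (default 3600 s), thresholded at 25 J/cm² into the *effective treated
   volume* (cm³) and the *coverage index* (% of the target covered), with
   a 250 J/cm² high-dose display region.
5. **Plan geometry & reporting** — stereotactic trajectories validated
   against the safety rules (diffuser lengths ∈ {2, 2.5, 3, 4, 5} cm,
   ≥ 9 mm between diffusing parts, non-crossing insertion paths, in-volume
   containment); simulation and report export are gated on a clean
   validation; reports serialize to JSON, plans and tissue tables to TSV,
   volumes to NIfTI.
6. **Synthetic phantoms** — concentric tumor-in-brain label volumes and
   noisy diffuser emission profiles so everything is testable without
   patient data.

## Worked example

```r
library(ipdt)

ph   <- generate_phantom(phantom_spec(dims = 100))   # segmented phantom
plan <- ipdt_plan(
  fiber_trajectory(entry = c(50, 50, 5), target = c(50, 50, 60),
                   diffuser_length = 30),
  treatment_time = 3600, n_packets = 131072L, seed = 1L)

validate_plan(plan, ph$grid)   # 0 rows -> no alerts, plan is admissible
sim <- simulate_plan(ph$grid, plan, target_mask = ph$target)
sim
#> <ipdt_simulation> 1 fiber(s), 131072 packets each
#>   treated volume: 2.350 cm^3 (> 25 J/cm^2 in 3600 s)
#>   coverage index: 15.1 %
#>   high-dose volume: 0.849 cm^3
```

Reading: one 3 cm diffuser ending at the tumor centre treats ≈ 2.3 cm³
above the 25 J/cm² therapeutic fluence after one hour at 200 mW/cm, but
covers only 15 % of this (rather large, 11.5 cm³) contoured target —
the planner would add fibers, respecting the 9 mm spacing rule, and
re-simulate:

```r
validate_plan(ipdt_plan(list(
  fiber_trajectory(c(42, 50, 5), c(42, 50, 60), 30),
  fiber_trajectory(c(50, 50, 5), c(50, 50, 60), 30))), ph$grid)
#>               kind fibers value                                  message
#> spacing-violation    1,2     8 diffusers of fibers 1 and 2 are 8.00 ...
```

A command-line front end with `phantom`, `validate` and `simulate`
subcommands lives at `system.file("cli", "ipdt.R", package = "ipdt")`;
`validate` exits non-zero iff the plan raises alerts, and `simulate`
writes fluence/mask volumes (NIfTI) and the JSON plan report.

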
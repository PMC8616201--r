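---
title: "Light-transport dosimetry for interstitial PDT planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light-transport dosimetry for interstitial PDT planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipdt)
```

## The problem

Interstitial photodynamic therapy (iPDT) of glioblastoma delivers 635 nm
light through cylindrical diffusing fibers inserted stereotactically into
the tumor. The photosensitizer (protoporphyrin IX, induced by 5-ALA)
accumulates preferentially in tumor cells, so therapeutic selectivity comes
from the drug; the planner's job is purely photometric: given a segmented
brain volume, a contoured target and a set of fiber trajectories, predict
the fluence (J/cm²) everywhere, report the *effective treated volume* — the
voxels receiving more than a therapeutic threshold fluence — and the
*coverage index*, the percentage of the target inside that volume.

`ipdt` implements this pipeline end to end: a tissue optical-property
database, a diffuser source model, a voxelized Monte Carlo transport
engine, dosimetry, stereotactic plan validation and reporting, plus
synthetic phantoms that make every stage testable without any patient data.

## Model and assumptions

**Tissue optics.** Each voxel carries one of seven tissue labels (CSF, grey
matter, white matter, necrotic, non-enhancing and enhancing tumor, oedema)
plus background. Per label the database stores the absorption coefficient
µa (/mm), scattering coefficient µs (/mm), Henyey–Greenstein anisotropy g
and refractive index n at 635 nm. All tissues share n = 1.40, which has a
useful consequence: no internal Fresnel reflection or refraction events
occur, and the engine needs no index-mismatch logic. The exterior boundary
is treated as matched — any packet leaving the grid, or entering a
background voxel, escapes. The table is shipped as versioned plain text
(`inst/extdata/tissue_optics_635nm.tsv`) and can be replaced wholesale; the
values are treated as exact constants. Two quirks of the shipped table are
intentional and taken as published: oedema carries white-matter optics, and
non-enhancing tumor combines white-matter absorption with µs = 69.7/mm.

**Source model.** Diffusers (2, 2.5, 3, 4 or 5 cm diffusing parts) are
modelled as isotropic *line sources* on the fiber axis: the physical
diffuser radius is neglected, launch directions are isotropic, and launch
positions along the axis follow a super-Gaussian probability density

$$p(z) \propto \exp\!\left[-\left(\frac{(z-c)^2}{2w^2}\right)^k\right],
\qquad z \in [0, L],$$

which reduces to a Gaussian at order $k = 1$ and flattens as $k$ grows.
The family is fitted to measured emission profiles by Levenberg–Marquardt
least squares with a deterministic restart ladder; when no measurement is
supplied a flat-top default ($k = 3$, $w = 0.42L$, $c = L/2$) is used,
matching the qualitative shape of bench-measured cylindrical diffusers.
Sampling uses a numeric inverse CDF on a 4096-point grid — dense enough
that the interpolation error is far below Monte Carlo noise at any
realistic packet count. The diffusing part is placed with its *distal end
at the target point*, extending back toward the entry point; the
convention is configurable (`distal_at_target`). Source power is linear:
200 mW/cm of diffuser by default, so a 3 cm diffuser injects 600 mW.

Note on the fitted order: the parameter container accepts any $k > 0$
rather than clamping at 1, so that fits to near-Gaussian profiles can land
on either side of $k = 1$ without boundary artefacts.

**Transport.** The engine is a compiled (C++) voxelized Monte Carlo of the
mcxyz lineage. Packets of initial weight 1 take dimensionless steps
$s = -\ln \xi$, consumed across voxels as physical length $s/\mu_t$ with
exact ray–voxel boundary sub-stepping; at each interaction a fraction
$\mu_a/\mu_t$ of the weight is deposited and the packet scatters through a
Henyey–Greenstein angle; packets below weight $10^{-4}$ play Russian
roulette (survival probability 0.1, unbiased re-weighting). Voxels with
$\mu_t = 0$ are crossed in free flight. Fluence rate is estimated with the
*track-length* tally,

$$\hat\varphi_v = \frac{P}{V_v\,N}\sum_{\text{chords in } v} w\,\ell,$$

because the collision (absorption) estimator degenerates where µa is
nearly zero — CSF has µa = 0.004/mm and µs = 0.009/mm — while the
track-length estimator stays well conditioned everywhere. The collision
estimator is computed alongside and used as an internal cross-check; on
homogeneous phantoms the two agree within Monte Carlo error. All
randomness is drawn from R's generator, so a single `set.seed` (the `seed`
argument) makes a run bit-reproducible; multi-fiber plans seed fiber $i$
with `seed + i - 1`, which also makes an $N$-fiber simulation exactly the
superposition of its $N$ single-fiber runs. The reference GPU heritage of
this class of codes is replaced here by a single-threaded compiled engine;
the contract preserved is bit-reproducibility under a fixed seed, not any
particular execution strategy.

**Dosimetry.** Per-fiber fluence-rate maps (mW/cm²) are summed, multiplied
by the illumination time (3600 s default — one hour is a practical
anaesthesia budget) and converted to fluence via
1 mW/cm² × 1000 s = 1 J/cm². The effective treated volume applies a
*strict* threshold — fluence *higher than* 25 J/cm² — and reports
count × voxel volume in cm³; the same strict convention is used for the
250 J/cm² high-dose display region. Both thresholds are parameters, and a
`strict = FALSE` variant exists for sensitivity checks. An optional
photodynamic weighting can multiply fluence by a relative PpIX
concentration factor (tumor classes 1, healthy classes 1/100, reflecting
the up-to-100:1 tumor-to-parenchyma concentration ratio) before
thresholding; it is OFF by default because the treated volume is defined
on fluence alone, and both modes are exposed deliberately.

**Plan geometry.** Trajectories live in stereotactic millimetre
coordinates (X medial-lateral, Y anterior-posterior, Z cranial-caudal) in
the frame of the volume's affine. Validation enforces: diffuser lengths
from the allowed set and shorter than their track; diffusing parts inside
the volume; pairwise diffuser separation of at least 9 mm (exactly 9 mm
passes — closer spacing risks thermal hot spots above the 43 °C
parenchymal tolerance; the limit is configurable down to 7 mm but defaults
to the hard 9 mm rule); and non-crossing insertion paths. "Crossing" is
not given a formal definition in the clinical workflow this mirrors, so it
is implemented as the full entry→target segments approaching within a
clearance (1 mm default) — full tracks rather than diffusers only, since
physical guides cannot co-occupy space anywhere along their length.
Validation returns alerts (never exceptions), and both simulation and
report export refuse to proceed while alerts stand, reproducing the
gate-ordered planning workflow.

## Synthetic phantoms: what they emulate, and what they do not

`generate_phantom()` rasterizes a concentric glioblastoma caricature —
necrotic core, enhancing rim, non-enhancing region, oedema shell, strictly
nested — inside a spherical head of white matter with a cortical
grey-matter shell and optional ventricle-like CSF spheres, at 1 mm
isotropic resolution by default (~120³, with smaller grids used in tests
for speed). The target mask is the union of the three tumor compartments,
optionally extended to the oedema shell (whether to treat infiltrated
oedema is an open clinical question; the default target excludes it).
Compartment label volumes converge to the analytic sphere volumes as the
voxel size shrinks — verified at 2, 1 and 0.5 mm.

These phantoms exercise every code path (heterogeneous optics, CSF near
transparency, target overlap), but they are deliberately simple: real
segmentations have irregular, disconnected compartments, partial-volume
boundaries and anisotropic voxels. Passing tests on phantoms therefore
validates the *machinery* — transport physics, dosimetry algebra, geometry
rules — not the clinical accuracy of any particular patient plan.

## Numerical choices

* Voxel traversal nudges positions across faces by 10⁻⁹ mm; chord sums
  match in-grid ray lengths to ~10⁻⁷ relative, far below voxel scale.
* The roulette threshold (10⁻⁴) and survival probability (0.1) follow
  long-standing practice in tissue-optics Monte Carlo; disabling roulette
  makes the weight ledger close exactly (`conservation_summary()`), and
  every simulation logs that ledger per fiber so tally bugs surface in
  routine runs.
* The super-Gaussian normalization uses adaptive quadrature (relative
  tolerance 10⁻¹²); the PDF integrates to 1 within 10⁻⁹.
* Fit non-convergence triggers up to 8 deterministic restarts from
  perturbed moment-based starting values before a diagnostic error; no RNG
  is consumed, so fitting never perturbs downstream seeds.
* The validation oracle for diffuse light is the infinite-medium diffusion
  point-source solution $\varphi(r) = P e^{-\mu_{\rm eff} r}/(4\pi D r)$
  with $D = 1/3(\mu_a + \mu_s')$; in white matter the engine tracks it
  within ~7% over 2–8 mm, inside the ~15% accuracy one expects of the
  diffusion approximation itself at these distances.

## Problem sizes used in the shipped tests

Unit tests run thousands-to-tens-of-thousands of packets on 21³–61³
grids; the end-to-end acceptance checks use the full default 131,072
packets on a 100³ grid for the single-fiber treated-volume computation and
4 × 25,000 packets for the diffusion-oracle comparison. These sizes were
chosen so the whole suite completes in a few minutes while keeping Monte
Carlo error well below every tolerance tested.

## A worked example

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_spec(dims = 100))
plan <- ipdt_plan(
  fiber_trajectory(entry = c(50, 50, 5), target = c(50, 50, 60),
                   diffuser_length = 30),
  treatment_time = 3600, n_packets = 131072L, seed = 1L)
validate_plan(plan, ph$grid)     # zero rows: plan is clean
sim <- simulate_plan(ph$grid, plan, target_mask = ph$target)
glance(sim)                      # treated volume, coverage index, ...
tidy(sim)                        # per-fiber weight-conservation ledger
plot_fluence_slice(sim)          # axial slice with 25/250 J/cm^2 contours
```

## Known limitations

* No polarization, no time-resolved transport, no thermal model: the 9 mm
  spacing rule is the only thermal surrogate.
* The exterior boundary is perfectly matched; light re-entering the head
  after an excursion through background is not modelled (packets
  terminate). With brain-scale grids and 635 nm attenuation this is
  negligible except within a voxel or two of the surface.
* PpIX photochemistry (oxygen kinetics, photobleaching, fractionation
  physiology) is out of scope; the concentration-ratio weighting is a
  static multiplier only.
* The line-source model ignores the physical diffuser radius (~1 mm);
  fluence within the first voxel around the fiber is therefore nominal,
  which is harmless for treated-volume work at 25 J/cm² but matters if one
  cares about the immediate peri-fiber dose.
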
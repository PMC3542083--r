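---
title: "Flow-driven accretive growth and 3D morphometrics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow-driven accretive growth and 3D morphometrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`coralmorph` couples a polyp-based accretive growth model of branching
scleractinian corals to steady laminar flow and nutrient transport, and
quantifies the resulting forms with a 3D morphometric suite.  This vignette
explains the models, the numerical choices behind them, the tunable
parameters, and what the desk-scale simulations do and do not show.

## The growth model

The colony is a triangulated surface whose vertices stand for polyps.  Each
growth step runs four phases:

1. **Flow.**  The steady incompressible Navier-Stokes and continuity
   equations are solved in a rectangular channel around the voxelized
   colony.  Water enters at `x = 0` with a uniform velocity `u0` (default
   0.05 m/s), leaves at the far face where pressure and viscous stress
   vanish, and the lateral and top faces are open boundaries; the
   substratum (`z = 0`) and the colony surface are no-slip walls.  The
   external volume force is zero.  At natural sea-water viscosity a 2 cm
   branch at 5 cm/s has `Re ~ 1000` and a whole colony `Re ~ 5000`, which
   puts the wake in an unsteady regime; following the laminarization
   strategy of the study this package reproduces, the dynamic viscosity is
   raised to `5e-2` Pa s so that `Re_branch ~ 20` and `Re_colony ~ 100` and
   a steady solution exists.  `solve_flow()` enforces this regime
   (`Re_colony <= 200`) as a precondition.
2. **Transport.**  Steady advection-diffusion of a nutrient proxy (e.g.
   dissolved inorganic carbon) on the flow field: concentration is held at
   the idealized value 1 mol/m^3 on every far-field face and at zero on the
   colony surface and the substratum, which absorb it.  The per-polyp
   *absorbed flux* is the concentration sampled a small distance `l`
   (default one voxel) along the vertex normal, normalized by the maximum
   sample `c_max`; the normalization makes the flux independent of the
   choice of `D` and `l` and gives it a maximum of exactly 1.
3. **Translocation.**  Absorbed flux spreads between neighbouring polyps by
   surface diffusion, `dC/dt = D_s lap_s C`, integrated for a time `tau_s`
   with the surface diffusivity held at `D_s = 3e-4` m^2/s (an intermediate
   branching regime; branch spacing is known to be sensitive to this
   value, so it is constant across all runs).
4. **Accretion.**  The translocated concentration sets the thickness of the
   new skeletal layer through a saturating sigmoid,
   `g(C) = L_max * C^n / (K^n + C^n)`, with `L_max = 1` mm, `K = 1` mol/m^3
   and kinetic order `n = 1.2`.  Because flux is normalized to a maximum of
   `K`, the best-fed polyp extends about half a millimetre per step; 150
   steps take the 6 cm seed to roughly 10 cm, the scale of real colonies
   growing 1-2 cm per year.  Each vertex moves along its area-angle-weighted
   outward normal; rim vertices on the substratum are anchored, and the
   substratum plane is impenetrable.  The surface is then remeshed
   (edge split/collapse) back towards the target edge length.

Branching is *emergent*: nothing in the model prescribes where branches
form.  Protruding regions sample higher concentrations, grow faster, and
protrude further — the diffusion-limited instability — while surface
diffusion sets the smallest spacing that can amplify.  There is no
stochastic term anywhere; runs are reproducible bit-for-bit from their
configuration, and symmetry is broken only by mesh discreteness.

### The sigmoid form

The growth function is stated in the source model as a sigmoid obeying
saturation kinetics with half-maximum at `K` and asymptote `L_max`; the
Hill form above is the standard function with exactly those properties and
is the default.  A normalized logistic alternative (same endpoints) can be
selected with `growth_params(form = "logistic")` for sensitivity checks.

### The duration of surface diffusion

`tau_s` is not stated by the source model.  The default couples it to the
mesh: the lateral translocation length `sqrt(D_s * tau_s)` equals three
remesh target edges, so refining the mesh refines the smallest branch
spacing in step.  It is exposed in `growth_params()` because branch spacing
responds directly to it.

### The initial colony

The seed is a triangulated sphere of 6 cm diameter sitting on the
substratum.  How deeply the sphere intersects the plane is not specified by
the source model; the default truncates it one sixth of the diameter below
the centre (config-exposed via `clip_fraction`), and rim vertices never
grow.  The cap is triangulated on latitude rings and polished (spring
relaxation, valence-regularizing flips, an outlier-focused pass) until
every edge is within about 20% of the target length, which keeps the
accretion isotropic.

## Numerical methods

* **Flow** is discretized on a marker-and-cell staggered grid with
  first-order upwind convection and central diffusion and solved with
  SIMPLE pressure-correction iteration.  Open/outlet faces are pressure
  boundaries (ghost correction pressure zero) whose normal velocities are
  set by the continuity correction, which realizes "open to a large volume,
  no viscous stress" stably.  Solid (colony) cells impose no-slip with
  half-cell wall distances on fully blocked tangential links.  Convergence
  is declared when normalized momentum and continuity residuals drop below
  the configured tolerance (default `1e-3`, the tolerance of the original
  study's iterative solver).  Within a growth run each solve is
  warm-started from the previous step, which cuts iteration counts by
  roughly 3x because the geometry changes little per layer.
* **Transport** uses monotone first-order upwinding (the discrete maximum
  principle `0 <= c <= cb` holds unconditionally, avoiding the oscillations
  a higher-order scheme would need stabilization for) with SOR iteration to
  a relative residual of `1e-6`, normalized by the boundary-source scale so
  warm starts terminate sensibly.  Colony cells absorb at the shared cell
  face (half-link Dirichlet), which halves the effective-radius bias of
  voxelized absorbers.
* **Surface diffusion** uses the cotangent-weighted Laplacian with lumped
  vertex areas, integrated by Crank-Nicolson substeps finished with two
  backward-Euler substeps (the latter damp the stiff-mode ringing CN
  leaves on long horizons).  Total area-weighted nutrient is conserved to
  near machine precision on closed surfaces.
* **Remeshing** splits edges beyond 1.5x and collapses below 0.5x the
  target (standard isotropic-remeshing bounds; the source model describes
  triangle insertion only qualitatively), with link-condition checks so the
  mesh stays 2-manifold; split vertices average the endpoint state.
* **Self-intersection** (the geometric analogue of branch fusion, which
  the model does not simulate) is detected each step by triangle-triangle
  intersection tests over a uniform-grid broad phase; a run halts with a
  structured report instead of fusing branches.

### Solver validation

`analytic_flow_cases()` packages three closed-form references: plane
Poiseuille flow between no-slip plates (profile within 0.1% at 48 cells
across the gap), the 1-D advection-diffusion slab at `Pe = 5`
(`c(x) = (e^{Ux/D}-1)/(e^{UL/D}-1)`, within 3%), and a spherical absorber
inside a concentric far-field shell.  For the absorber the exact solution
of the configured problem is the annulus form
`(1 - R/r) / (1 - R/Rout)`, which the solver matches to better than 1%
using the volume-equivalent radius of the discrete absorber; the
infinite-domain limit `1 - R/r` is approached within ~6% at `Rout = 16 R`
(the residual is the finite-shell factor `~R/Rout`, not solver error).

## Morphometrics

The voxel pipeline mirrors CT post-processing: volumes come from CT-like
input (`read_nrrd()`, `read_tiff_stack()`, anisotropic pitch supported) or
from voxelizing a simulated mesh.  Skeletonization is distance-ordered
homotopic thinning: border voxels are deleted in increasing
distance-transform order, deletions are restricted to topologically simple
points (26/6 digital topology), and curve endpoints are preserved, so the
skeleton is one voxel thick, centred, and has the branching topology and
loop count of the solid.  Two clean-ups follow: terminal tails whose
inscribed radius climbs at unit slope (cap-corner erosion artifacts) are
trimmed back to where the radius levels off, and spurs shorter than
`prune_factor` (default 2) times the junction's inscribed radius are
removed.  Distance-transform ties are broken by a coordinate hash rather
than scan order so the medial path has no systematic directional drift.

* **Terminal branch thickness** `dc` is twice the Euclidean
  distance-transform value at each skeleton endpoint (the largest inscribed
  sphere); its mean is the characteristic length in `Pe_branch = u dc / D`
  and `Re_branch = rho u dc / mu`.  Endpoints on the volume border are
  flagged and excluded.
* **Symmetry angles**: for every skeleton point `k` with offset
  `d = v_k - v0` from the root, `h_angle` is the angle between `d` and its
  projection on the horizontal plane through the root, and `v_angle` the
  angle to the projection on the vertical plane orthogonal to the flow.
  The convention reproduces both diagnostic limits: isotropic 45-degree
  branching gives `h ~ v ~ 45` degrees, and streamwise-tilted points give
  `h + v ~ 90` degrees.  The dense point set (all skeleton voxels, not just
  junctions) is used, which is what makes isotropy read back as 45 degrees
  on fixtures and gives the angle histograms their sample size.
* **Symmetry magnitude** `sm` is the scalar projection of `d` onto the
  horizontal direction towards an upstream reference point; mirror-opposed
  points cancel in the signed sum, so near-zero signed mean indicates
  streamwise symmetry.  Both the signed mean (the symmetry criterion) and
  the mean magnitude (the scale reported in colony summaries) are returned.
* The **root** is the skeleton node nearest the colony-substratum
  attachment centroid; when thinning does not reach the substratum a short
  anchor edge is grafted down to the attachment plane, so angles are always
  measured from the true base of the colony.

Distribution summaries use the adjusted Fisher-Pearson skewness and
bias-corrected excess kurtosis with t-based confidence intervals.

## Synthetic fixtures

`make_branching_volume()` builds capsule-union colonies at known ground
truth: branches radiate from a basal node on a small substratum pedestal at
evenly spaced azimuths (with a seeded random global phase), pulled toward a
bias azimuth by a factor `beta` in `[0, 1]`.  Even spacing makes the
isotropic case exactly mirror-symmetric, so the generator's ground truth
predicts endpoint counts, `dc`, mean `h_angle` (45 degrees for 45-degree
elevation) and near-zero signed `sm` without any reference data.  Capsules
rather than cylinders keep unions smooth so skeleton junctions are well
defined.  The fixtures emulate connected branching solids at CT-like voxel
pitch; they do not attempt statistically realistic coral morphology.

## Desk-scale runs: what they show and what they cannot

The default study conditions follow the original protocol: channel
0.6 x 0.6 x 0.4 m (a smaller 0.3 x 0.3 x 0.2 m channel is the desk-scale
default in `load_run_config()`, keeping >2 colony diameters of clearance),
6 cm seed, `u0 = 0.05` m/s, and a Peclet sweep that lowers `D` by factors
of 10 from 1.0 to 1e-5 m^2/s with the velocity fixed.  The suite runs the
sweep at 40 growth steps on a 30 x 30 x 20 grid (about half a minute per
run), and the acceptance script uses the same sizes.

Two regimes behave as in the full-scale study: the Peclet number ordering
of the sweep, and the transport asymmetry — at high `Pe` the upstream side
of the colony absorbs measurably more nutrient (mean flux ratio ~2.7 at
`D = 1e-4`) and the colony's centre of mass shifts monotonically upstream
across the sweep.

What desk-scale grids cannot reproduce is *branching itself* within 40
steps.  The diffusion-limited instability feeds on concentration
differences across bumps comparable to the sampling distance `l` (one
voxel).  With 5-10 mm voxels the per-step amplification of a bump is only a
few percent, so mesh-discreteness seeds (~0.03 mm) stay below a millimetre
after 40 steps and the colony remains an unbranched dome; the original
150-step finite-element runs resolve the sub-millimetre diffusive boundary
layer that drives the instability.  Consequently the skeleton of a
desk-scale colony has no terminal branches, its symmetry magnitude is
dominated by medial-axis placement noise, and surface/volume differences
across the sweep are below one percent — so the branch-scale symmetry and
compactness orderings of the full-scale study are not reproducible at this
problem size, and the corresponding acceptance checks fail honestly rather
than being re-targeted at different metrics.  The morphometric suite itself
is validated independently on procedural fixtures where ground truth is
known exactly.

## Known limitations

* First-order upwinding in flow and transport is diffusive; profiles
  sharper than a few cells are smeared.  The validation cases quantify the
  error at the configured resolutions.
* Sampling absorbed flux one voxel above a voxelized surface carries a
  staircase artifact of order ten percent of the local flux (the distance
  from the sample point to the discrete surface varies by half a voxel);
  it averages out in colony-level summaries and disappears when `l` is two
  or more voxels, which is what the solver-validation tests use when they
  probe transport physics rather than the sampling itself.
* Turbulence is never modelled (the laminarized viscosity is part of the
  study conditions); anastomosis is detected and reported, not resolved.
* Corallite-scale surface roughness is not represented; the surface is
  smooth at the mesh scale.
* The full-scale morphospace (branch thickness `dc ~ 2 mm`, symmetry
  magnitudes of tens of millimetres) requires resolving the diffusive
  boundary layer and ~150 growth steps, beyond a single-CPU desk budget.
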
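# coralmorph

Simulation of flow-driven growth in branching corals, plus the 3D
morphometrics to quantify the resulting forms.

Branching scleractinian corals such as *Pocillopora verrucosa* are strongly
shaped by water motion: under unidirectional current, colonies grow
asymmetrically with branches favouring the upstream side, and they become
more compact as advection increasingly dominates nutrient supply.
`coralmorph` implements the two halves needed to study this numerically:

1. **A polyp-based accretive growth model.**  The colony is a triangulated
   surface whose vertices are simulated polyps.  Each growth step solves
   steady laminar flow (incompressible Navier-Stokes, SIMPLE iteration on a
   staggered grid) in a channel around the colony, then steady
   advection-diffusion of nutrient (`u . grad c = D lap c`) with `c = 1`
   mol/m³ on the far field and `c = 0` on the absorbing colony and
   substratum.  The per-polyp absorbed flux — the concentration a small
   distance `l` along the vertex normal, normalized to a maximum of 1 — is
   translocated laterally by surface diffusion
   (`dC/dt = D_s ∇²_s C`, `D_s = 3·10⁻⁴` m²/s) and converted into the
   thickness of a new skeletal layer by the saturating growth law

   `l_i = g(C_i) = L_max · C_iⁿ / (Kⁿ + C_iⁿ)`,

   with `L_max = 1` mm, `K = 1` mol/m³, `n = 1.2`.  Every vertex advances
   along its outward normal and the surface is remeshed.  Branching is an
   emergent instability, not a rule.  The impact of flow is summarized by
   the branch Péclet number `Pe = u·dc/D` and Reynolds number
   `Re = ρ·u·dc/μ`, where `dc` is the mean terminal-branch diameter.

2. **A 3D morphometric suite** for simulated colonies or CT-like volumes:
   topology-preserving skeletonization (distance-ordered homotopic
   thinning), terminal-branch thickness `dc` from the distance transform,
   symmetry angles `h_angle`/`v_angle` relative to the substratum plane and
   the plane orthogonal to flow, the streamwise symmetry magnitude
   `sm_mag`, surface area, volume and surface/volume ratio, and
   skewness/kurtosis summaries of the angle distributions.

Procedural branching fixtures (capsule unions with exact ground truth) make
every operator testable without scan data, and three closed-form reference
problems (plane Poiseuille flow, the 1-D advection-diffusion slab, the
spherical absorber) validate the solvers.

## Worked example

Grow a colony for a few steps under flow and report its morphometrics:

```r
library(coralmorph)

dom <- simulation_domain(extent = c(0.3, 0.3, 0.2), n = c(30, 30, 20))
run <- grow_colony(domain = dom,
                   fluid = fluid_params(),                  # u0 = 0.05 m/s, mu = 5e-2 Pa s
                   transport = transport_params(D = 1e-3),
                   growth = growth_params(steps = 10L, target_edge = 4e-3))
run
#> <growth_run> 10 steps, final 582 vertices
#>   extent 0.064 m, S/V 86 m^-1

rep <- morph_report(run, u_mean = 0.05, D = 1e-3, mu = 5e-2, rho = 1000)
rep[, c("dc", "pe_branch", "re_branch", "sv_ratio", "h_angle_mean")]
#>           dc pe_branch re_branch sv_ratio h_angle_mean
#> 1 0.04391285  2.195643  43.91285 85.53938     78.87946
```

After ten layers the colony has grown from 6 cm to 6.4 cm in extent while
its surface/volume ratio eased to 86 m⁻¹; no branches have formed yet at
this desk-scale resolution, so `dc` falls back to the colony's largest
inscribed diameter, and `Pe_branch`/`Re_branch` are recomputed from the
run's own `u`, `D`, `μ`, `ρ` and `dc`.

Morphometrics on a synthetic "CT scan" with known ground truth:

```r
fx <- make_branching_volume(fixture_spec(n_branches = 8, elevation_deg = 45))
sk <- skeletonize(fx$volume)
length(terminal_thickness(sk, fx$volume)$dc)     # 8     (= branch count)
symmetry_angles(sk)$mean_h                       # 44.54 degrees
terminal_thickness(sk, fx$volume)$mean_dc * 1e3  # 6.34 mm  (true: 6 mm)
```

A command-line front end is installed with the package
(`system.file("cli", "coralmorph", package = "coralmorph")`) with verbs
`grow`, `flow`, `transport`, `morph`, `synth` and `sweep` over YAML run
configurations; outputs (meshes as PLY with per-vertex flux, fields as
NRRD/VTK, skeletons as GraphML, reports as CSV, logs as line-delimited
JSON) land in a per-run directory.

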
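---
title: "Geometry-prescribed CFD of a dynamic heart phantom: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-prescribed CFD of a dynamic heart phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardiocfd)
```

This vignette is the package's own account of the science it implements:
the models, the numerical choices made where the design was genuinely
open, what the synthetic phantom does and does not emulate, and the known
limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The pipeline in one paragraph

A ventricle-like cavity undergoes a programmed cyclic compression. A 4D
image sequence of the moving cavity is the *only* motion input to the flow
model: volumetric registration recovers a cyclic displacement field, the
field is prescribed to the boundary of a fluid-domain mesh, interior mesh
motion is a smoothing extension, and the incompressible Navier–Stokes
equations are solved on the moving mesh in arbitrary Lagrangian–Eulerian
(ALE) form. The simulated flow is then compared to planar 2D vector-flow
velocity records on a common spatio-temporal grid through stationary
regions of interest (ROIs), time bins and linear regression. Because no
imaging or measurement data are distributed, a synthetic dynamic phantom
generates all inputs with known ground truth.

## The phantom and its motion

The cavity is an axis-aligned truncated ellipsoid (base plane at $z = 0$,
apex at $z = z_c + R_z$) with two cylindrical tubes attached above the
base. The programmed motion is a pure long-axis compression
$$c(t) = C_d \sin^2\!\left(\frac{\pi t}{T}\right),$$
with defaults $C_d = 10$ mm and programmed period $T = 0.8$ s. The cycle
period *realized* by the physical phantom was measured as 0.76 s rather
than 0.8 s, for reasons unknown; the generator therefore carries both
periods and the realized motion uses the same squared-sine shape completed
in $T_{meas} = 0.76$ s. The discrepancy mechanism itself is deliberately
not modelled.

Material points move axially by $-c(t)\,s(z)$ where $s$ is a C¹ smoothstep
from 0 at the base plane to 1 at the apex, identically zero on the base
plate and the tube walls. This profile was chosen because it is smooth
(hence recoverable by intensity-based registration), respects the
non-moving tubes, and makes the apex stroke exactly $C_d$. The rendered
sequence has 20 phases per cycle (sample period $0.76/20 = 0.038$ s),
lumen/wall/background intensities 300/80/0 with a 0.5-voxel Gaussian
partial-volume blur, and optional additive Gaussian noise behind a single
seed.

**What the phantom does not emulate:** CT physics (beam hardening, gating
artifacts), ultrasound speckle, torsion (the physical programme is pure
compression), valves, and the pump–afterload interaction. Passing tests
therefore demonstrate correctness of the pipeline mechanics under ideal
contrast and known motion, not robustness to clinical image quality.

## Registration

Motion recovery follows the simplest scheme that works: 19 *independent*
pairwise registrations of phase 1 against every other phase, by
symmetric-forces diffeomorphic demons (update field composed through the
scaling-and-squaring exponential map, Gaussian fluid/diffusion
regularisation). The similarity metric is the mean squared intensity
difference, appropriate for a same-modality sequence and invariant to a
global additive intensity offset. Since no algorithm parameters are
canonical, the defaults — 3 pyramid levels, 50/30/15 iterations,
$\sigma_{fluid} = 2$, $\sigma_{diff} = 1$ voxels — are exposed in the
configuration. Joint spatio-temporal (groupwise) registration is a known
improvement and is intentionally out of scope.

Zero displacement holds at the reference phase by construction and is
appended at $t = T$ because the motion is cyclic, giving 21 instances.
Temporal smoothing is a circulant fourth-difference penalised smoother
solved per voxel with the FFT; a rank-one correction pins the zero
instances exactly, so cyclicity survives smoothing to machine precision.
Field evaluation between instances uses periodic cubic splines, which by
construction have equal first derivatives at the two cycle ends — this is
how the "equal rates of volume change at start and end of cycle"
requirement is realised, since the mechanism behind the original penalised
smoothing is not public.

## Moving mesh

The displacement field is sampled at every boundary node at fixed 0.019 s
steps (41 stored positions per 0.76 s cycle). Interior motion solves a
linear elastic extension (Navier–Cauchy form, Poisson ratio 0.3) with
Jacobian-based stiffening $(\bar V / V_e)^\chi$ protecting small elements;
a harmonic switch exists in the configuration. A genuinely hyper-elastic
extension would need constitutive parameters that are not available, so
equivalence is claimed only at the level of valid, smooth interior motion
— element validity is checked at every stored step and an inversion is a
hard error naming the step and element. Affine boundary motion is
reproduced exactly (to solver tolerance), which is the property the
Galilean/transport test of the solver relies on.

Mesh velocity is the exact time derivative of the periodic spline through
the stored trajectories; nodes with constant trajectories get exactly zero
velocity, so no-slip on static patches is exact. One cycle of motion is
stored and reused for every flow cycle.

## Flow solver

Taylor–Hood mixed elements (continuous P2 velocity / P1 pressure) on
triangles are inf-sup stable without pressure stabilisation. Time
integration is implicit Euler along the mesh-node trajectories: on the
geometry at $t^{n+1}$,
$$\rho\left(\frac{u^{n+1} - u^n}{\Delta t}
  + ((u^\ast - w)\cdot\nabla) u^{n+1}\right)
  - \mu \Delta u^{n+1} + \nabla p^{n+1} = 0, \qquad
  \nabla\cdot u^{n+1} = 0,$$
with $w$ the mesh velocity and $u^\ast$ the Picard iterate (adaptive
under-relaxation, warm-started from the previous step). Because the
discrete time derivative follows the nodes and the convective velocity is
$u - w$, a uniform flow on a uniformly translating mesh is transported
exactly (the geometric-conservation property tested in the suite). Each
linearised saddle system is solved by a sparse direct factorisation, so
the discrete divergence residual is at round-off at every step and the
global flux balance (open-boundary flux equals $-\mathrm{d}V/\mathrm{d}t$)
holds to machine precision.

At the phantom's operating point (peak plug speed ≈ 0.73 m/s in an 8 mm
inlet, Re ≈ 1.5·10³) convection dominates coarse desk-scale meshes, so
the convective term carries a streamline-upwind (SU) stabilisation with
the classic cell-Péclet switch. The SU term acts only along
$(a\cdot\nabla)u$ and therefore vanishes identically for developed
Poiseuille profiles and for uniform fields — the exactness benchmarks are
unaffected. It is not a consistent SUPG formulation; at the mesh sizes
used here that trade-off favours robustness.

Boundary conditions: spatially uniform plug at the inlet (placed at the
far end of the inlet tube so the profile can develop before entering the
cavity), zero-traction outlet which fixes the 0 Pa gauge, and no-slip
equal to the mesh velocity on walls and base. Outlet backflow is left
unpenalised by default (a directional penalty would be a modelling
addition, and the desk-scale runs do not need it). Initial conditions come
from a stationary ramp: a sequence of stationary solves with the inlet
speed stepped from 0 to its $t = 0$ value, each warm-started from the
previous.

**Benchmarks.** The solver's analytic anchor is plane (2D channel)
Poiseuille flow, whose parabolic profile is *exactly* representable in P2,
so the computed centreline speed is $1.5\,\bar U$ to round-off; the
circular-pipe factor $2\bar U$ belongs to the 3D/axisymmetric case, which
this package does not discretise. Cycle convergence is quantified as
$Vel_{diff} = |U_i| - |U_{i+1}|$ at probe points at the last step of each
cycle; mesh independence uses the volume-and-cycle-averaged velocity
magnitude with a 0.5 % agreement band against the finest mesh.

## Inlet construction

For fully developed Poiseuille flow $u(r) = 2V(1 - r^2/R^2)$, the line
average along a chord at perpendicular offset $d$ is
$\tfrac{4V}{3}(1 - d^2/R^2)$ and the chord length is $2\sqrt{R^2 - d^2}$,
so the ratio of an off-centre chord mean to the centred (diameter) mean is
the *squared* chord-length fraction. That reading is the only one
consistent with the stated pair of numbers (a chord at 89.4 % of the
diameter reading 80 % of the mean: $0.894^2 = 0.8$), and is the
interpretation implemented. The inlet waveform is
$U(t) = Q(t)/A + U_{off}$, with the additive offset (0.386 m/s in the
reference configuration) applied after the ratio correction. The inlet
diameter and flow shape are configuration, not physics: the synthetic
default is a smooth single-lobed waveform with a 2.21 L/min peak, 15 %
baseline, peaking at 55 % of the cycle (mid-diastole), sampled at 40
points per cycle so the peak lies exactly on a sample.

## Comparison protocol

CFD and measurement records share one container: pixel grid (0.5 × 0.5 mm
by default), 0.01 s sample period, in-plane components $u, w$, a geometry
channel $g$, and the out-of-plane component $v$ stored but excluded from
all comparison statistics. Phase alignment reduces each $g$ stack to a
frame-wise displacement metric and maximises the circular normalised
cross-correlation; rigid co-registration is landmark-based Kabsch. The
comparison metric is $|U| = \sqrt{u^2 + w^2}$ in 16 stationary circular
ROIs (radius 2.5 mm — the ROI geometry is not canonical, so it is a
recorded configuration choice) over 11 equal-width, left-closed time bins
partitioning the 0.76 s cycle, equal-weighted in the regression (bin
sample counts differ by at most one, so weighting is immaterial at this
scale). Regression puts CFD on the vertical axis, so systematic CFD
underestimation appears as a negative intercept.

In the synthetic pipeline the emulated measurement is a sliced flow field
plus seeded Gaussian velocity noise. With the measurement referenced to
the CFD's own field the expected regression is slope 1 / intercept 0 (the
self-consistency check); with the measurement referenced to a
ground-truth-motion solve, enabling registration can only degrade the
agreement — the ablation the pipeline exposes via
`compare$reference = "truth"`.

## Problem sizes and numerical parameters

The shipped configuration is deliberately desk-scale: 2D long-axis
cross-section, image spacing 1.5 mm, mesh size 4.5 mm (≈ 500 elements,
≈ 5·10³ degrees of freedom), motion step 0.038 s, solver step 0.038 s,
four cycles, Picard tolerance 10⁻⁵ with at most 10 iterations per step.
The stationary benchmarks use meshes of ≈ 300–900 elements. These sizes
were chosen so the full pipeline and the property suite complete in
minutes on one CPU while every tested property (mass balance, cycle
convergence, warp recovery, regression recovery) is resolution-independent
in formulation. Paper-style settings (0.019 s motion step, dt half of it,
six cycles) are plain configuration changes.

Other numerical choices: multilinear interpolation clamps out-of-grid
points to the edge (with a warning); the demons update magnitude is capped
by the standard $\sigma_x$ normalisation; triangle quality is
$2 r_{in}/r_{circ}$; ties in time-bin assignment follow left-closed /
right-open edges; the cycle seam uses phase $0 \equiv T$ everywhere.

## Known limitations

- The flow discretisation is 2D; out-of-plane transport in the real
  cavity is absent, which is precisely why the comparison protocol tracks
  the out-of-plane share separately.
- SU stabilisation is inconsistent (adds streamline diffusion) on coarse
  meshes at high cell Péclet numbers.
- Pairwise-independent registration under-recovers motion in homogeneous
  image regions; only boundary-adjacent accuracy matters for the mesh,
  and the warp-recovery test quantifies exactly that.
- The headline agreement statistics of the physical experiment depend on
  recordings that are not distributed; the package reproduces the
  protocol and its analytic anchors, not those numbers.
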
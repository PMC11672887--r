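---
title: "Modelling soft-tissue outcome of orbital decompression surgery"
author: "orbdecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling soft-tissue outcome of orbital decompression surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Thyroid eye disease swells orbital fat and extraocular muscles inside
the rigid bony orbit, raising intraorbital pressure and pushing the
globe forward. Decompression surgery creates space: either by
*resecting* wall fragments, so pressurised tissue can flow into the
opened windows, or by *lateral valgization* (LAVA), which cuts the
lateral wall free and swings it outward about a hinge at its anterior
edge. The valgized plate both enlarges the bony orbit and carries the
temporalis muscle outward with it; after a plain lateral resection the
temporalis instead herniates into the defect and largely re-closes it.

`orbdecomp` implements a complete, self-contained simulation pipeline
for this comparison. Because patient CT data of this kind are not
publicly available, the package ships a parametric synthetic orbit with
exact geometric ground truth; every downstream stage (meshing, boundary
conditions, solver, volumetrics, inverse estimation) is testable against
closed-form oracles on that phantom.

## The mechanical model

Soft tissue is treated as an isotropic, homogeneous, linearly elastic
(Hookean) material per tissue class. The displacement field `u` solves
the Lamé–Navier equation

$$\Delta \mathbf{u} + \frac{1}{1-2\nu}\,\nabla(\nabla\cdot\mathbf{u})
  = -\frac{2(1+\nu)}{E}\,\mathbf{f},$$

with per-tissue Young's modulus $E$ and Poisson ratio $\nu$. The weak
form is discretised with linear (P1) tetrahedra; the stiffness is
assembled per element from the Lamé parameters
$\lambda = E\nu/((1+\nu)(1-2\nu))$, $\mu = E/(2(1+\nu))$ and reduced by
eliminating Dirichlet degrees of freedom; the reduced
symmetric-positive-definite system is solved by sparse Cholesky
factorisation (deterministic fill-reducing ordering, relative residual
checked against $10^{-9}$).

Large surgical displacements are handled in a *piecewise-linear
incremental* regime: prescribed displacements and loads are applied in
`n_steps` equal increments (default 10), the stiffness is re-assembled
on the updated geometry after every step, and pressures act as follower
loads on the current facet normals. Each increment is memoryless (the
updated configuration is the new reference), which is the simplest
consistent reading of a piecewise-linear constitutive approximation; no
true hyperelastic law is used, and the package makes no claim beyond
that regime. An element that would invert during an update aborts the
run with the step and element identified.

### Parameters and defaults

| Parameter | Default | Notes |
| --- | --- | --- |
| `E` (fat, muscle, bulbus) | 3, 12, 90 kPa | literature-scale soft-tissue modulus ordering: fat softest, globe far stiffer |
| `nu` | 0.45 (all tissues) | nearly incompressible; capped at 0.49 to avoid P1 volumetric locking |
| intraorbital pressure | 1.2 kPa (≈ 9 mmHg) | elevated retrobulbar pressure scale |
| valgization | shift 2.5 mm, angle 30° | the clinical LAVA manoeuvre simulated here |
| `n_steps` | 10 | incremental regime |
| contact tolerance | 1 mm | nodes this close to a fragment follow it |

Only the ratio of pressure to stiffness (and stiffness ratios between
tissues) affects traction-driven displacement — see *Identifiability*
below — so the absolute scales are conventions, chosen once at
clinically plausible magnitudes.

## The synthetic orbit

The phantom emulates the *output* of a segmented orbital CT, not the CT
itself. In a right-handed frame with x lateral, y anterior, z superior:

* the bony orbit is a truncated cone (apex at the origin, axis +y,
  default depth 42 mm, rim radius 19 mm, apex radius 3 mm) with a
  2 mm bone shell, a posterior bone cap, and a thin anterior bone
  annulus standing in for the orbital septum so that the intraorbital
  space is topologically sealed;
* the bulbus is a 10.5 mm sphere near the aperture; four rectus-like
  muscle cylinders (radius 2 mm) run parallel to the axis, rotated 10°
  off the coordinate planes so that voxelisation errors behave
  generically under grid refinement;
* fat fills the remaining cavity; a temporalis body lies outside the
  lateral wall over the posterior 60% of the depth;
* the wall is divided into lateral/roof/medial/floor sectors by angular
  extents (default 121°/90°/59°/90°). The default lateral sector area
  over the tissue-contact depth is 9.60 cm², matching the reported
  clinical scale of valgized lateral fragments (~9.6 cm²).

Ground truth (exact tissue volumes, sector areas, and the cavity signed
distance) comes from the analytic geometry, so voxelisation and meshing
accuracy are measurable, not assumed. What the phantom deliberately does
*not* emulate: real orbital shape variation, inhomogeneous tissue,
partial-volume segmentation noise, and image artefacts. Tests passing on
the phantom therefore validate the *pipeline machinery*, not clinical
predictive accuracy on real anatomy.

## From labelmap to mesh

Deformable voxels (fat, muscle, bulbus) are grouped into cubic cells
(`target_edge`, default one voxel) and each cell is cut into six
tetrahedra (Kuhn subdivision — conforming across cells and fully
deterministic). Boundary nodes are then snapped onto the zero level of
the signed Euclidean distance transform of the tissue mask by damped
Newton steps, with three safeguards: a quarter-to-half-voxel deadband
(nodes already on the surface, e.g. on grid-aligned planes, do not
move), a trust region of 0.45 cell edges, and an inradius floor with
rollback (snapping must not create slivers that would invert under
later deformation).

Because a snapped lattice boundary still carries small tangential
folds, *wall-fragment areas* are measured as facet areas signed-projected
onto the local smoothed-SDF gradient: folds contribute with cancelling
signs and the sum converges to the area of the patch footprint on the
smooth surface. Sub-voxel iso-surfaces (`extract_surfaces()`) are
extracted by marching tetrahedra on the SDF and relaxed by clamped
Laplacian smoothing with SDF re-projection.

Boundary facets are tagged by marching a short ray outward and
classifying the first non-deformable label: bone maps to a wall sector
(by angle about the orbital axis), to `APEX_FIXED` near the posterior
tip (default 2 mm band), or to `ANTERIOR_FREE` for the anterior
membrane; background maps to `ANTERIOR_FREE`. Every boundary facet
receives exactly one tag.

## Surgical boundary conditions

**Resection.** Fragment facets become Neumann surfaces carrying the
intraorbital pressure along the outward normal; all other wall facets
and the apex are fixed; the anterior surface is traction-free. Window
facets that are backed by the temporalis body (detected by a ray query
through the bone in the labelmap) remain fixed — the muscle herniates
into the defect and blocks outflow there. This boundary-condition-level
treatment replaces contact mechanics deliberately.

**Valgization** runs in two steps.

1. *Kinematic relocation.* Soft-tissue nodes within the contact
   tolerance of the fragment receive the rigid valgization displacement
   (rotation about the anterior-edge hinge, sign chosen so the plate
   swings outward, plus the lateral shift) as Dirichlet values. Two
   regularisations keep the prescribed field kinematically admissible:
   the drag magnitude is tapered by distance to the fragment rim
   (Lipschitz cap, `drag_taper`, default slope 1/1.5), since tissue at
   the osteotomy edge is tethered to the intact wall; and a consistency
   filter releases contact nodes whose prescribed motion would invert a
   fully-prescribed element (such elements have no elastic freedom
   left). With `drag_taper = Inf` the literal rigid-drag contract is
   recovered.
2. *Pressure-driven outflow.* On the updated geometry, rim nodes whose
   plate displacement exceeded the contact tolerance are released (the
   plate has swung away from their seat, leaving the "new free area"
   around its edges), the rim band of fragment facets is pressurised,
   and plate-backed tissue stays pinned — a unilateral-contact
   approximation by Dirichlet pinning.

The hinge is placed on the fragment's anterior edge (principal direction
of the anterior boundary-edge vertices). This choice — deep lateral
expansion about an anterior hinge — is configurable, not claimed to be
the only possible reading of the manoeuvre. Intraorbital pressure is
applied as a surface traction on opened windows; a uniform body-force
loading mode is available as an alternative (`body_force` in the plan)
but off by default.

## Outcome metrics

*Released volume* is the volume of deformed tissue outside the original
bony cavity. The primary estimator rasterises the deformed mesh on a
fine voxel grid (default pitch 0.5 mm) and counts centres with positive
cavity signed distance; the undeformed baseline (the discretised rest
mesh protrudes marginally past the analytic cavity) is subtracted, so a
zero field reports exactly zero. Two independent estimators cross-check
it: brute-force point-in-tet membership counting, and a first-order
surface-flux integral of `u · n` over the boundary. A fast
fixed-quadrature per-element estimator (`mode = "sample"`) serves inside
the inverse-problem loop where only self-consistency matters.
*Proptosis change* is the posterior retreat of the anterior-most bulbus
node. Reports carry affected area (cm²), released volume (cm³), their
ratio, and per-tissue breakdowns; `compare_scenarios()` adds pairwise
ratio-of-ratios. Whether "orbital volume change" should mean released
tissue volume or cavity-expansion volume is ambiguous in general; the
package computes the former as its headline number and exposes the flux
mode as the cavity-boundary alternative.

## Identifiability and inverse estimation

For traction-driven linear elastostatics, scaling all moduli and the
pressure by a common factor leaves the displacement unchanged: only
`p/E_fat`, stiffness *ratios*, and `ν` are identifiable from outcome
data. `fit_parameters()` therefore works in those coordinates and
refuses a joint fit of absolute `E_fat` and pressure outright rather
than silently returning one point of the degenerate ridge. The search is
a Nelder–Mead simplex in transformed coordinates (log for ratios, scaled
logit for `ν`, so bounds hold by construction) with random restarts
(default 3, seed 17); a failed forward solve during the search scores a
large penalty so the simplex retreats. The bulbus-to-fat stiffness ratio
is held fixed (default 30): the globe is far stiffer than fat and the
outcome observations are insensitive to it.

Acceptance of the estimator is by *parameter recovery on synthetic
observations* (released volume plus sparse boundary displacement
samples, optionally with multiplicative noise), not by matching any
reported clinical values — none are available.

## Numerical choices and degenerate inputs

* P1 tetrahedra with `ν` capped at 0.49; near-incompressible defaults
  (0.45) stay below the locking-dominated regime at the mesh sizes used.
* All randomness (observation sampling, noise, optimizer restarts) is
  seeded; phantom generation, meshing, boundary compilation and solves
  are seed-free deterministic, so identical configurations produce
  bit-identical artifacts.
* Degenerate inputs are rejected with named diagnostics: phantom specs
  whose bulbus does not fit the cone, labelmaps with unknown codes,
  empty or genuinely disconnected fragment selections (tiny satellite
  patches from tag discretisation are dropped with a message),
  over-constrained Dirichlet/Neumann conflicts, and singular systems
  (the unconstrained rigid-body mode is named).
* Verification problem sizes: the thick-sphere benchmark runs three
  octant meshes up to ~29k degrees of freedom, where the radial
  displacement matches the closed form to well under 2% relative L2;
  the scenario comparison runs at 2 mm cells (~8k dof); recovery
  experiments use a 2 mm-voxel phantom at 4 mm cells so that a full
  simplex search stays interactive.

## Known limitations

* Linear kinematics per increment; no true finite-strain constitutive
  law, no viscoelasticity, no self-contact. Large valgization angles are
  meaningful only through the incremental regime.
* Bone is rigid and only present through boundary conditions; the
  temporalis is a blocking obstacle, not an elastic body.
* The orbital septum stand-in is a rigid membrane in the labelmap and a
  free surface in the mechanical model; real septal compliance lies
  between those extremes.
* Phantom realism is intentionally schematic (see above); absolute
  released-volume magnitudes depend on the chosen `p/E` scale and should
  be read comparatively (scenario vs scenario), which is how the package
  reports them.
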
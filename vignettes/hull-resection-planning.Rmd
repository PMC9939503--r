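---
title: "Hull-based resection planning: model, geometry and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hull-based resection planning: model, geometry and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resectplanr)
```

## The planning problem

En-bloc bone tumor surgery removes the tumor in one piece together with a
cuff of healthy tissue. Conventional preoperative plans are built from a
small number of planar saw cuts, which in thick bone inevitably take a
large collateral volume of healthy bone with the tumor. Robotic or
guide-assisted cutting makes *conformal* cuts feasible, and the question
becomes geometric: given segmented bone and tumor surface meshes, what is
the least-wasteful cut surface that still removes the whole tumor and can
be withdrawn en bloc?

`resectplanr` answers this with a family of convex-hull resection
geometries. The scene is discretized on a uniform cubic voxel grid
(default pitch 2 mm, coordinates at cube centers) spanning the joint
bounds of both meshes; each center is classified against each mesh by
ray-crossing parity, centers outside both are discarded, and bone centers
inside the tumor mesh form the *intracortical tumor* (they are removed
from the healthy-bone set). The scene is then translated so the tumor
mesh's vertex centroid sits at the origin.

## The three resection geometries

All three geometries derive from the convex hull of the tumor surface and
a *focal point* FP. A parameter vector places the scene in a local frame:
extrinsic rotations about the base z-, y- and x-axes (degrees, applied in
that order), then a translation $(t_x, t_y, t_z)$ so FP is the local
origin. Bounds: rotations $\pm 180^\circ$; $t_x, t_y$ within the rotated
tumor's x/y extents (the cone apex stays under the tumor footprint);
$t_z \in [-200000, \min T'_z]$ — the enormous lower bound is a numerical
stand-in for "focal point at infinity", which degenerates the cone into a
quasi-cylindrical resection.

* **Conical hull** — the cut surface is the cone from FP through the
  tumor hull, with every profile line extended beyond the farthest bone or
  tumor point inside the profile so the piece can be withdrawn along the
  cone without further cuts. The removed region is the healthy bone inside
  this (extended) cone.
* **Flat-based hull** — the cone tip is replaced by a planar facing cut
  at the lowest tumor point: bone with local $z < \min T'_z$ is spared
  (the inequality is strict; a center exactly on the cut plane is removed
  — ties favor resection throughout).
* **Contoured hull** — the planar facing cut is replaced by a curvilinear
  one: after an extra rotation $\varphi_z \in [-90^\circ, 90^\circ]$ about
  the local z-axis, only bone whose $(x, z)$ projection falls inside the
  2D convex hull of the tumor's local $xz$ silhouette is removed. Because
  that prism lies within $z \ge \min T'_z$ and the extra rotation is
  common to the whole scene, the three removed sets nest exactly:
  contoured $\subseteq$ flat $\subseteq$ conical for identical parameters.

The objective is **bone waste**,

$$ B_{\mathrm{waste}\%} \;=\; \frac{B_{\mathrm{removed}}}
   {B_{\mathrm{removed}} + T_{\mathrm{intracortical}}} \times 100, $$

collaterally removed healthy bone as a percentage of the total resected
intracortical volume. Only intracortical tumor enters the denominator;
extraosseous tumor (outside the cortex) is excluded, but both counts are
reported so either convention can be formed. A complete resection is a
*constraint*, not part of the objective: every intracortical voxel lies in
the removed set by construction (a hull contains its generators), and the
test suite asserts it for random parameter draws rather than trusting the
construction.

### Why the counted volume is the extended cone

The cut surface that is physically executed is the *extended* profile —
the cone walls continue through the entire bone so the piece can leave the
anatomy. The bone enclosed by those walls is resected whether or not it
lies inside the bounded hull of (tumor ∪ FP). We therefore count removed
voxels by membership in the tangent cone from FP spanned by the tumor
hull. This also makes the optimization meaningful: under the bounded-hull
reading, pushing FP up to the tumor base would always yield zero waste and
the flat and contoured variants could never improve on the conical one,
while with cone counting the focal-point position trades tip waste against
flare waste exactly as the three geometries' relative performance shows.
Membership in the cone depends only on direction from FP, so the exported
extension clearance (default 5 mm beyond the farthest in-cone point;
configurable, since the exact clearance convention is not fixed by the
method) never changes a count.

## Numerical choices

* **Grid anchoring.** The grid is anchored so the minimum corner of the
  joint bounding box is a cube corner. Voxel-count volumes then carry a
  deterministic lattice fluctuation of a few percent; at 2 mm pitch and
  solid diameters ≥ 20 mm generic placements are within ~3% of analytic
  volumes. An integer-radius sphere centered exactly on the lattice is a
  measure-zero worst case: dozens of centers fall exactly on the ideal
  surface, which any inscribed triangulation misses, so validation solids
  are placed generically off-lattice.
* **Boundary rule.** A center within $10^{-9}$ mm of a surface crossing
  counts as inside, and hull/facet membership uses the same tolerance with
  ties counting as removed — all ties favor resection completeness.
  Centers exactly on a casting-ray-parallel facet are resolved by
  re-casting with a small deterministic in-plane perturbation.
* **Conditioning at extreme $t_z$.** The cone facets are built from the
  tumor hull's horizon as seen from FP, never by running a hull algorithm
  on point sets mixing coordinates of order $10^0$ and $10^5$.
* **Hull caching.** The tumor hull (facets and edge topology) is computed
  once per scene; rigid motions transform facet normals and offsets
  directly. One objective evaluation reduces to small matrix products plus
  a progressively-filtered half-space test over the bone voxels
  (~5–10 ms on the phantoms used here).

## The optimizer

Bone waste is piecewise constant in the parameters (voxel counts), so a
gradient-free population method fits. The bounded particle swarm uses
50 particles, personal and global learning coefficients of 1.49, a
per-particle inertia weight initialized uniformly in $[0.1, 1.1]$, an
iteration cap of $200 \times n_{\mathrm{params}}$, early termination
after 20 iterations without improvement of the global best, and
10 independent restarts, each from its own sub-seed derived from the
master seed. Two conventions that this kind of swarm setup leaves open
were fixed as follows:

* **Adaptive inertia.** After an iteration that improves the global best,
  every particle's inertia is multiplied by 1.25 (capped at 1.1); after
  two consecutive stalled iterations it is multiplied by 0.75 (floored at
  0.1). This reproduces the qualitative explore/contract behavior of
  adaptive-inertia swarms while staying fully specified and configurable.
* **Rotation-dependent translation bounds.** The table bounds for
  $t_x, t_y, t_z$ are expressed in the local frame, which moves with the
  rotation parameters — they do not define a static box. The swarm
  therefore searches a fixed box built from the tumor's circumscribing
  radius, and every evaluation clamps the translation to the exact rotated
  extents. The boundary handler clamps positions and zeroes the violating
  velocity component, which keeps the quasi-cylindrical $t_z$ extreme
  reachable.

Evaluations are memoized on parameter vectors quantized at $10^{-6}$
(the objective is constant on far coarser cells). Failed evaluations
(degenerate hulls) score $+\infty$ and the search continues. Runs are
bit-reproducible from the master seed; restart order does not affect the
reported optimum.

Warm-starting the flat/contoured searches from the conical optimum is
available but off by default: seeding a narrower geometry's search with a
wider one's optimum risks trapping the swarm in the conical basin.

## The phantom generator

Patient segmentations are replaced by parametric phantoms with known
analytic geometry. The bone is a long-bone-like generalized cylinder
along z — a tapered shaft (default radius 20 mm, length 120 mm, 15%
taper) whose radius is modulated near one end by a smooth condylar bulge
with a mild two-lobed angular profile. A single radial profile
$r(\theta, z)$ was preferred over a boolean union of shaft and condyle
primitives: it is watertight by construction, and the planner consumes
only meshes and voxels, so shaft-plus-condyle topology is all that
matters. Tumors are star-shaped radial solids on icosphere scaffolds:
spheres, ellipsoids, or spheres perturbed by seed-controlled low-order
spherical harmonics ("lobed", amplitude capped below 0.3 so the solid
stays star-shaped about its center — which is what guarantees that
uniform margin expansion contains the original tumor). Eccentric
placements push the tumor through the cortex to create extraosseous
extension.

Defaults model a metaphyseal tumor: a 12 mm-radius sphere centered 15 mm
up the shaft axis. The stratified suite (`make_suite()`) cycles tumor
sizes of 0.4/0.55/0.7 shaft radii, the three shapes, and alternates
centered with cortex-breaching placements.

What the phantoms deliberately do not emulate: cortical/trabecular
distinction, anatomically realistic condyles, segmentation and smoothing
artifacts, and imaging noise. Passing tests on phantoms therefore
validate the geometry and optimization machinery — voxel classification,
hull construction, nesting, completeness, reproducibility — not the
clinical realism of any particular waste value.

## Validation strategy and problem sizes

Every geometric predicate is checked against an independent oracle built
from different mathematics: ray-parity point classification against a
generalized-winding-number oracle; 3D hull membership against an LP
convex-combination feasibility oracle; the focal-point cone against a
conic-combination LP; full removal masks against a per-voxel LP test with
no hull code involved; optimized conical results against a coarse
deterministic parameter grid; and the distant-focal-point limit against
the analytic circumscribing-cylinder volume.

The shipped tests run at desk scale, chosen so the whole suite exercises
every property in minutes: phantoms of 2,500–17,000 healthy-bone voxels,
50 random parameter draws across 5 phantoms for the nesting and
completeness properties, and a 10-phantom suite optimized at 20 particles
and 3 restarts for the qualitative ordering (median waste: contoured ≤
flat ≤ conical, with every hull geometry beating the best grid-searched
single plane on phantoms whose tumor is fully intracortical). The
reference script in `scripts/acceptance.R` runs the default phantom
end-to-end at the same desk scale.

## Known limitations

* Waste is the sole objective; structural integrity of the remaining
  bone, soft-tissue corridors and critical structures are not modeled.
* The margin model is uniform scaling of the tumor mesh about its
  centroid; non-uniform, distance-true margins are out of scope.
* The planar baseline is a grid search over single planes, a stand-in
  comparator — it is not a model of an experienced surgeon's plan.
* Voxel counts inherit lattice fluctuation at coarse pitch; waste values
  on small tumors carry a corresponding quantization granularity.
* The 2D hull of the contoured facing cut uses the tumor silhouette in
  one rotated plane; tumors with strongly non-convex silhouettes keep a
  convex cut in that plane.
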
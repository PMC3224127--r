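---
title: "Simultaneous multi-object segmentation with deformable simplex meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simultaneous multi-object segmentation with deformable simplex meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-throughput structural imaging of small specimens often packs many
similar objects into a single field of view — for example fixed mouse
embryos embedded in gel and stacked inside one imaging tube. Downstream
analysis needs one binary mask per specimen, but the image properties
defeat the standard tools: the gel is inhomogeneous and its intensity
distribution overlaps the specimens', so thresholding fails; and
neighbouring specimens touch, so region growing and single-surface active
contours leak from one object into the next.

`multiseg` segments N similar, touching objects simultaneously. Each
object is represented by a deformable *simplex mesh* — a closed surface in
which every vertex has exactly three neighbours, the topological dual of a
triangulation. The three neighbours of a vertex define its tangent plane,
normal, and *simplex angle* (the signed lift of the vertex out of its
neighbours' plane), from which mean curvature follows directly; these
quantities drive the deformation.

## Equation of motion and force terms

Every vertex `p` behaves as a unit mass under damped Newtonian dynamics,
updated synchronously per iteration:

```
p[t+1] = p[t] + (1 - gamma) (p[t] - p[t-1]) + w_int F_int + F_ext
F_ext  = w_grad F_gradient + w_edge F_edge
         + w_balloon F_balloon + w_collision F_collision
```

All external forces act strictly along the vertex normal; tangential
external displacement is never applied, which both smooths the deformation
and avoids a classical source of self-intersection. `gamma` (default 0.65)
is the damping factor; it is not stated by the original formulation of
this pipeline and is exposed as a parameter.

* **Internal force.** The tangential part moves the vertex toward the
  position encoded by its stored *reference* barycentric coordinates in the
  neighbour triangle. The normal part drives the simplex angle toward a
  smoothed reference: the vertex's stored reference angle plus the mean
  deviation-from-reference over a graph neighbourhood of
  `smoothness_scale` rings. Averaging the *deviation* rather than the raw
  angle means a mesh at its reference configuration feels no force, while
  curvature noise at scales below `smoothness_scale` is ironed out.
* **Gradient force.** A search over a ball of `gradient_search_radius`
  voxels around the vertex for the voxel of highest gradient magnitude;
  the displacement toward that voxel is projected on the normal and capped
  at `force_cap` voxels per step, so a single strong image feature cannot
  run away with a mesh while weaker features are still acting. Ties are
  broken by distance to the vertex, then by lowest voxel index, so results
  are deterministic. The gradient magnitude is computed once per run by
  central differences after a small Gaussian smoothing
  (`gradient_sigma`, in voxels) that suppresses single-voxel texture
  gradients relative to the coherent object boundary. Inside the engine,
  voxels outside the tube mask or within two voxels of its edge are
  censored from the search (the container wall is the strongest edge in
  the image, and keeping the boundary search away from it is the tube
  mask's purpose), and the search floor defaults to the 0.7 quantile of
  the gradient magnitudes over the object-classified voxels (wall band
  excluded): object texture produces weak but spatially stable gradient
  maxima that would otherwise pin vertices against the balloon, and at
  this level most of the interior response is suppressed while boundary
  ridges remain almost entirely above the floor.
* **Edge force.** The brightest voxel along the normal line within the
  same radius; off by default (`w_edge = 0`) in both stages of the
  standard schedule.
* **Balloon force.** `B(I(p)) n`, where `B` is the indicator of the pass
  band `[T_low, T_high]` evaluated on the *classified* volume at the
  vertex (nearest-neighbour sample — labels are categorical, so
  interpolation would fabricate intermediate values). With the classifier
  encoding below, the printed thresholds `T_low = -0.99`, `T_high = 1.0`
  admit exactly the object-classified voxels: small initial spheres
  inflate while they remain in object territory and stop at the classified
  boundary.
* **Collision force.** Gated by the mesh's collision energy image (below):
  zero where the energy is 0; where a vertex stands in claimed territory,
  a gradient search over `collision_search_radius = 5` voxels pulls it to
  the nearby true boundary. The energy image additionally acts as a binary
  mask on the search itself — voxels claimed by other meshes are excluded
  as candidates — so the recovered boundary always lies on the vertex's
  own side. Search radii above 5 voxels were reported not to improve
  efficiency, and 5 is the default.

## Bayesian voxel classification

A supervised two-class quadratic (Gaussian) classifier labels every voxel
object (+1) or gel (-1) from the 2-D feature vector (intensity, local
standard deviation). The local SD is computed over a centered cubic window
(default 5 voxels; the window size is a package choice, exposed as
`classifier_window`). The user supplies 25 training coordinates per class;
per-class feature centroids and covariance matrices are fitted, priors are
proportional to training counts, and each voxel takes the
maximum-a-posteriori label, ties resolving to gel so that a borderline
vertex does not balloon. The +1/-1 encoding is a package decision that
makes the printed balloon thresholds meaningful.

The classifier deliberately over-labels: windows straddling an object
boundary have elevated SD and are labeled object, so the classified
region is a slight dilation of the truth. This is harmless — the balloon
only needs to stop *near* the boundary, and the gradient force then locks
onto the true edge.

## Collision detection by mask XOR

Every `collision_check_interval` (default 5) iterations each mesh is
rasterized to a binary mask `M_i` (voxel-center-in-polyhedron by parity of
ray crossings). The collision energy image of mesh i is the voxelwise
exclusive-or of all *other* masks. A vertex of mesh i in a voxel with
energy 1 is in collision. The XOR is implemented exactly as specified,
including its counter-intuitive cancellation where two other masks overlap
each other; a `union` mode is available behind a flag for robustness
experiments. During any stage, a mesh found in collision has its balloon
weight latched to zero for the remainder of the stage ("stop the inflation
for models in collision"); whether a halted mesh may resume if its
neighbour retreats is not specified, and the latch is implemented as
permanent per stage. The container wall is treated as one more static
neighbour for this rule: a mesh whose displacement gets clamped by the
tube mask latches its balloon the same way, so it cannot crawl along the
wall. The cadence of 5 iterations lets meshes deform between checks but
not far enough to inter-penetrate deeply before detection.

## Tube mask

The sample container is segmented from the intensity histogram (256 bins
by default): the lower threshold is the mean intensity of the voxels in
the bin holding the first local minimum after the first (lowest-intensity)
highest peak; the upper threshold is the data maximum. Tie rules — equal
peaks resolve to the lower-intensity bin; the local minimum is the first
bin bounded above by both neighbours; an empty minimum bin falls back to
its center — are package decisions, as is the cleanup step (largest
26-connected component, internal holes filled) that keeps stray bright
voxels out of the mask. At every iteration, any vertex whose proposed
position leaves the mask has its displacement cancelled and keeps its
previous coordinate, so no mesh ever leaks outside the container.

## Multi-resolution schedule and convergence

Deformation is staged coarse-to-fine. Stage 1 uses 80-vertex spheres
(icosahedron dual, one subdivision; radius 5 voxels by default — the
original resolution and radius are not stated) with the stage-1 weights:
internal 0.9, gradient 0.3, edge 0, balloon 0.08, collision 0.4,
smoothness scale 12. The strong internal force and large smoothness scale
keep the rapidly inflating coarse mesh smooth and self-intersection free.
Between stages each mesh is refined — the dual triangulation is midpoint-
subdivided once and re-dualized, which quadruples the vertex count
(linear resolution doubles), with new vertices projected onto the previous
surface via Phong tessellation (flat projection lifted by the vertex
normals, blend 3/4) so refinement interpolates the curved surface rather
than the facets. High-resolution stages use internal 0.7, gradient 0.4,
balloon 0.02, collision 0.4, smoothness scale 3, a gradient search radius
narrowed to 2 voxels (the refined meshes already sit near the boundary,
and the tighter window resists spurious texture maxima), and run between
3 and 5 times (`min_high_res_stages`..`max_high_res_stages`); refinement
stops once the mean edge length falls below 1.25 voxels — beyond that,
subdivision cannot add boundary detail on the given grid — or at 2000
vertices. The collision weight sits at the upper end of its working
mid range (0.3–0.4): high enough that touching objects stay essentially
separate, low enough that each is still fully segmented.

A vertex is *inactive* when its displacement stays below
`displacement_threshold` (0.0001 mm) in each of the last
`activity_window` iterations (window default 10; the original text leaves
`n` unspecified). A mesh converges when the inactive fraction strictly
exceeds `activity_threshold` (0.5) — "exactly half" does not converge.
Converged meshes are frozen while the rest continue. On textured images
the gradient-search equilibrium jitters above the displacement threshold,
so stages typically run to their iteration caps (200 coarse, 100 per
high-resolution stage); the caps are package defaults, as the original
only illustrates 50-iteration snapshots.

All per-iteration updates are synchronous (forces are evaluated on the
positions at the iteration's start), so results are independent of mesh
ordering and the whole pipeline is deterministic: re-running with the same
inputs is bit-identical.

## The phantom

No imaging data are distributed, so the package generates its own test
volume emulating the study conditions: a bright gel cylinder (the tube) on
a dark exterior, containing axis-aligned ellipsoidal objects. The standard
layout (`default_tube(n)`) stacks up to 4 ellipsoids per layer
(semi-axes 10 x 10 x 13 voxels at 1 mm isotropic spacing on a 64^3 grid
for one layer), adjacent ellipsoids within a layer exactly tangent to each
other, and the layer block shifted off-axis so one object per layer is
tangent to the tube wall while the others keep a gel margin — touching
objects and wall contact are the two failure modes the collision force and
tube mask exist to handle, so both are always present.

Intensities: gel 100 +/- 5, object 130 +/- 10, exterior 10 +/- 4, all
multiplied by a smooth bias field (sum of three separable cosine modes at
0.5/1/1.5 cycles per extent, scaled to vary several percent pointwise and
clipped at +/-20%) plus additive noise (SD 3). The object's richer texture
is what carries class information into the local-SD feature while the raw
intensity histograms overlap under the bias — by construction the phantom
defeats global thresholding (best achievable Dice < 0.8 against the union
truth) yet supports near-complete classifier coverage. Training
coordinates are drawn from voxels at least 3 voxels inside their material
(relaxed if too few remain), emulating the manual selection of training
points by a user who clicks well inside each region.

What the phantom does **not** emulate: fine appendages (paws, tails) —
the documented failure mode of the method, out of scope here (an optional
protrusion mode would only serve qualitative demonstration); MR physics
(partial volume, Rician noise, susceptibility); and non-ellipsoidal
anatomy. Passing the phantom suite therefore demonstrates the mechanics
of the algorithm — inflation, boundary lock-on, collision handling, tube
constraint, multi-resolution refinement — not segmentation quality on
real anatomy.

Seed-sensitivity experiments perturb each seed by up to 10 voxels in a
random direction, truncated so the seed stays at least 3 voxels inside its
object: alternative seed sets are interior points, matching the
observation that seeds near object edges fail (a documented limitation,
not a robustness target).

## Numerical choices

* Meshes live in world (mm) coordinates; voxel space is 0-based with a
  voxel-center convention, and conversions are explicit.
* Rasterization casts z-rays through voxel centers with a sub-voxel ray
  offset (~1e-7 voxel) so rays never hit triangle edges exactly; columns
  with an odd crossing count (open or degenerate surfaces) drop the last
  crossing. Voxel centers exactly on the surface are outside.
* Normal orientation is fixed outward at construction (checked against
  the dual-triangulation winding) and propagated through refinement and
  file round trips; face cycles are stored outward-wound (positive
  enclosed volume).
* Degenerate (collinear) neighbour triples yield zero internal force with
  a warning rather than an abort.
* The simplex angle is computed from the circumscribed circle/sphere
  relations; a coplanar vertex has angle exactly 0.
* Ridge regularization (1e-6 of the mean feature variance) keeps
  near-singular class covariances invertible, with a diagnostic.
* Self-intersection is neither detected nor repaired during deformation
  (matching the method's stated design); `refine()` offers an optional
  O(T^2) triangle-intersection scan for diagnostics at coarse resolution.

## Problem sizes

The test-suite and acceptance problem sizes are 64^3 voxels, 4 objects,
80-vertex initial meshes refined to at most ~1280 vertices, one coarse
stage of up to 200 iterations plus up to 5 high-resolution stages of up
to 100 iterations. These desk-scale sizes exercise every code path of the
method; the data structures are not size-limited, and larger volumes
simply cost proportionally more time.

## Known limitations

* Fine appendages below the mesh resolution are not recovered; local
  (curvature-adaptive) refinement is out of scope.
* Seeding is manual by design; automatic initialization is out of scope.
* The XOR energy cancels where two *other* masks mutually overlap; with
  well-separated seeds and the balloon latch this situation is transient,
  and a `union` collision mode is available where robustness to it
  matters.
* Convergence by activity ratio rarely triggers on strongly textured
  images (equilibrium jitter exceeds the 1e-4 mm threshold), so runs are
  typically bounded by the stage iteration caps.
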
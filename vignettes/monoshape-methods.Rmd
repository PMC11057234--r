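---
title: "Methods: symmetry-constrained monocular shape reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symmetry-constrained monocular shape reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monoshape)
```

## The inverse problem

Recovering a 3D shape from one 2D image is ill-posed: the depth dimension
is lost, and any image is consistent with infinitely many scenes. For
objects with a plane of mirror symmetry, the ambiguity collapses almost
completely. In an orthographic image of a symmetric object all *symmetry
line segments* — the segments joining the projections of 3D mirror
pairs — are parallel, and the image determines the 3D shape up to a
single free parameter, naturally taken to be the slant σ of the symmetry
plane (the angle between the plane's normal and the line of sight). This
package implements that one-parameter family, the priors that pick one
member of it, and a linear model that combines the priors' slant
estimates into a single prediction.

The coordinate convention throughout: the camera sits at the origin
looking along +z, x is horizontal, y is vertical; depth means z.

## From image to family

**Input representation.** The model does not solve image correspondence:
a `pair_image` already lists, for each 3D mirror pair, the 2D projections
of its two endpoints, together with the camera (orthographic, or
perspective with viewing distance d and picture plane z = d). All
vertices are projected as if the object were transparent — no occlusion.
The endpoint order within a pair is made consistent across pairs
(first endpoint on the fixed negative side of the symmetry plane); with
inconsistent ordering the segment directions would cancel in the
correction step below.

**Noise model.** Human orientation discrimination is good to about one
degree, so `perturb_orientations()` rotates each segment about its own
midpoint by an independent N(0, 1°) draw. Midpoints and lengths are
untouched; rotation about the midpoint (rather than an endpoint) keeps
the perturbation symmetric and the image centroid fixed.

**Correction.** A noisy or perspective image is not a valid orthographic
image of any symmetric shape, so the family is not yet defined. The
correction finds the unit direction u minimizing
Σᵢ‖(bᵢ − aᵢ) − Lᵢu‖²; the minimizer is the normalized segment-vector sum
u ∝ Σ(bᵢ − aᵢ). Each segment is rotated about its midpoint onto u. Only
orientations change — lengths and midpoints are preserved, which is the
minimal intervention that achieves parallelism and keeps the depth
formulas below well defined. The correction is idempotent and leaves an
already-parallel image untouched.

**Reconstruction.** Let τ be the orientation of u (the tilt). The slant-σ
member places the symmetry plane with unit normal
n = (cos τ sin σ, sin τ sin σ, cos σ) through the origin (gauge c = 0:
depth from a single orthographic image is only ever defined up to a
constant shift, and every consumer — compactness, depth range, the
two-plane loss — is shift-invariant, so the gauge is harmless). Forcing
each pair midpoint onto the plane and the pair's 3D segment along n
gives, for a pair with image midpoint (xₘ, yₘ) and length L,

* midpoint depth zₘ = −tan σ · (xₘ cos τ + yₘ sin τ),
* endpoint depths zₘ ∓ (L/2) cot σ, the second endpoint deeper.

Re-projection reproduces the corrected image exactly, and at the true
slant of a noiseless image the reconstruction is congruent to the true
shape up to the depth shift. Two members of the family are related by an
affine map whose singular-vector structure is a stretch along two fixed
orthogonal directions — one of them the symmetry-plane normal, while the
in-image direction perpendicular to the symmetry lines is invariant (the
test suite verifies this structure numerically). The depth-reversed twin
of each member is excluded by the pair-ordering convention, matching an
adjustment task in which only slants in (0, π/2) were reachable.

**Grid.** All selectors search σ over 0.2 rad … π/2 − 0.2 rad in steps of
0.01 rad — the adjustable range and per-key-press step of the experiment
the model emulates. These are `family_grid()` defaults and configurable.

## The four slant estimators

**Compactness (θ_v2s3).** C₁ = V²/S³ is dimensionless, maximized over
all shapes by the sphere (1/36π), and penalizes the elongation in depth
that high-slant family members exhibit. Both compactness constraints are
evaluated on the **convex hull** of the reconstructed points: the volume
of thin parts (a wing, a chair leg) is numerically unreliable, the hull's
is not. There is no qhull binding in the dependency stack, so the package
carries a small incremental hull (visible-face deletion + horizon
stitching, cached face normals); it is validated against closed forms and
containment properties in the tests.

**Modified compactness (θ_s3v).** C₂ = V/S³ scales as k⁻³, so its values
are only comparable within one family, where the image fixes the scale —
the package never compares C₂ across objects. Its maximizer closely
tracks the slant minimizing the reconstruction's depth range (the tests
assert correlation > 0.9 across trials). Note the full depth range itself
is *not* monotone in σ: the within-pair offsets shrink as cot σ but the
midpoint-depth spread grows as tan σ, so the range is U-shaped; only the
within-pair offsets fall monotonically.

**Two-plane consistency (θ_sym2).** Many objects have parts symmetric
about a second plane (a box part has three planes). Each plane yields its
own correspondences, hence its own corrected image and family. For the
vertices shared by both correspondence sets, depths from family 1 at θ₁
and family 2 at θ₂ should agree up to the depth-shift gauge; the loss

L(θ₁, θ₂) = Σᵢ ((z_{θ₁,i} − z̄_{θ₁}) − (z_{θ₂,i} − z̄_{θ₂}))²

vanishes at the true slant pair for noiseless input. The selector does an
exhaustive 2D grid search (≈137² cheap vectorized evaluations) and
returns θ₁ at the global minimum.

One degeneracy is worth knowing about. If the object is posed so that the
primary and secondary normals project to the *same* image orientation —
which happens exactly when the pose has no spin about the primary normal
and the secondary normal lies in the object's xz-plane, the natural
construction for two-box stimuli — then a box-shaped shared part admits a
one-parameter near-continuum of two-plane-symmetric interpretations, and
the loss surface has an extremely shallow valley along θ₁ + θ₂ = 90°.
The zero is still unique at the truth, but the *grid* argmin can land far
away along the valley. A physical 3D orientation has three degrees of
freedom, not two; `view_spec()` therefore carries a spin component
(`sample_view()` draws it uniformly, mirroring orientations "varied
randomly"), and any generic spin restores the sharp unique minimum.

**Vanishing point (θ_persp).** Under perspective projection the symmetry
segments converge; extending any two of them gives an intersection v on
the picture plane, and the ray from the projection center through v is
normal to the symmetry plane, so each segment pair contributes slant
atan(‖v‖/d). The estimate is the median over all pairs. Parallel segment
pairs (intersection farther than 10⁶ image diameters — continuity with
the exact-parallel case) contribute 90°, which is also the exact answer
for any orthographic image: the vanishing point sits at infinity and the
estimator is deliberately uninformative there. The
`rotated_rectangles_image()` constructor reproduces the textbook check:
frontoparallel rectangles rotated 75° about their bottom edge give slant
15°.

**Uniqueness flags.** Grid selectors assert a unique optimum: optima
within 1e−12 at non-adjacent grid cells raise a warning rather than being
silently broken — adjacent-cell ties are ordinary discretization.

## Cue combination

θ̂ = λ θ_persp + (1 − λ) θ_LM with
θ_LM = β₀ + β₁θ_v2s3 + β₂θ_s3v + β₃θ_sym2. (The source formulation of
θ_LM prints a doubled intercept; a duplicated linear intercept is not
identifiable, so a single β₀ is used.)

λ encodes the reliability of perspective information as a function of the
angular size γ of the image (radius of the smallest enclosing circle of
the endpoints, seen from d): α = tan(γ/2), φ = 2 atan(α tan t),
λ = (1 − cos φ)/2. φ is the convergence angle the image of a reference
surface rotated t from frontoparallel would show; t = 75° is the default
(the value that best matched observers) and is held fixed during fitting.
λ(0) = 0, λ is strictly increasing in γ, and λ(20°) ≈ 0.30 versus
λ(7°) ≈ 0.05 — perspective information matters three-fold more at the
larger of the two image sizes the emulated experiment used.

**Fitting.** β is chosen to minimize Σ(θ̂ − σ_r)² against response slants
σ_r — the residual of the *full* prediction, not of θ_LM alone, since the
model's output is θ̂. With λ and θ_persp fixed per trial this stays
linear: regress σ_r − λθ_persp on (1 − λ)[1, θ_v2s3, θ_s3v, θ_sym2].
Rank deficiency is reported with the names of the collinear estimators.
Groups (object type, subject) are fit separately. When a condition has no
secondary plane on some trials (random polyhedra), θ_sym2 is NA and the
β₃ column is dropped; the pipeline's simulated observer folds its β₃ into
β₁ in that case.

`simulate_observer()` generates σ_r = clamp(θ̂(β*) + N(0, sd)) records
for parameter-recovery testing — the stand-in for human response files,
which are not distributed with the package.

## The synthetic stimulus world

`generate_random_polyhedron()` emulates the random-polyhedron stimulus
class: two box-like parts appended along a shared vertical face region,
bottom faces coplanar on y = 0, exactly mirror-symmetric about the YZ
plane (every vertex (x, y, z) has its twin (−x, y, z) by construction —
the symmetry is not approximate). Each part extrudes a convex
cross-section quadrilateral in the symmetry plane; three corner widths
are drawn and the fourth is solved from the side-face planarity
condition, resampling the widths (the cross-section is kept) when the
solved width is non-positive, exceeds 3× the largest drawn width, or the
side face self-intersects. Emitted objects have no face angle within
0.5° of 90°, at most 5% of angles within 5° of 90° (population fraction
beyond 5° ≈ 98%), and aspect ratio ≤ 9 measured in the construction
frame (x = symmetry normal, y = vertical). The rectangular class uses
the identical pipeline with exact rectangles and constant widths, so
every face angle is exactly 90°; edge lengths and widths are drawn from
the same distributions in both classes (defaults: U(1, 4) for
cross-section edges and widths — the source never states the
distribution, and these give the stated aspect-ratio range headroom —
and a U(0.3, 1.0) relative size for the second box, "varied over a wide
range").

Choices the source leaves open, fixed here once: the bottom-corner lean
angles of random cross-sections are drawn directly in angle space
(U(6°, 18°)) rather than as depth-proportional jitter, because
depth-proportional jitter makes the rejection rate depend on the drawn
edge length and visibly biases the emitted edge-length distribution away
from the rectangular class's; the "too large" threshold for the
planarity-forced width is 3× the largest sampled width; the two boxes
are merged into one mesh (each part remains a closed component, so
volumes add).

What a green test does and does not establish: the generator reproduces
the *constraints* of the stimulus classes (symmetry exactness, angle and
aspect-ratio rules, shared distributions), not any particular object set;
natural-object results (meshes with one global symmetry plane and locally
two-plane-symmetric parts) are reachable through `read_mesh()` +
`ransac_symmetry_planes()` but no natural-object corpus ships with the
package, and human response data are simulated, never reproduced.
Distribution-sharing is verified at hundreds of objects, not the
thousands a large-sample location test would use, to keep the suite fast.

## Numerical choices

* RANSAC: N = 2000 default iterations (tests use less on 16-vertex
  meshes), matching tolerance 0.01 × object diameter, secondary-plane
  fallback tolerance 0.15 × diameter; candidates deduplicated at 2° of
  normal and one tolerance of offset, refined by one least-squares refit
  (principal direction of the sign-aligned pair-difference vectors).
* Correspondence matching is globally greedy on the full
  reflection-distance matrix, so pairs are disjoint and tol = ∞ pairs
  every vertex.
* Normal signs are canonicalized to non-negative z (then x, then y), so
  slants live in [0°, 90°].
* The convex hull uses a visibility epsilon of 1e−10 × cloud diameter;
  coplanar and collinear inputs are rejected with explicit errors.
* All internal angles are radians; user-facing interfaces are degrees.
* Determinism: every stochastic function takes a `seed` and restores the
  caller's RNG state; condition sets derive per-trial seeds as
  seed + trial index so single trials are reproducible in isolation.

## Limitations

* Symmetry correspondence in a single 2D image is not solved — pair
  images come from known 3D correspondences (the transparent-object
  convention); occlusion and the reconstruction of invisible back parts
  are out of scope.
* The vanishing-point estimator assumes calibrated viewing distance d.
* C₂ is dimensionful; its values are never compared across objects.
* RANSAC samples mesh vertices, not densified surface points, which is
  adequate for polyhedra and vertex-rich meshes but can under-weight
  sparsely triangulated symmetric regions of CAD-style meshes.
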
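# monoshape

Monocular 3D shape reconstruction from single images of mirror-symmetric
objects.

A single 2D image is consistent with infinitely many 3D scenes, yet human
observers see the shapes of familiar objects almost veridically from one
eye. `monoshape` implements a computational account of how that is
possible for mirror-symmetric objects: the image constrains the 3D shape
up to **one free parameter**, and a small set of priors — 3D compactness,
a second symmetry plane, and perspective convergence — picks the member
of that family a human observer would pick.

## The model

For a mirror-symmetric object, the image segments joining projected
symmetric point pairs ("symmetry lines") are parallel in any orthographic
image. A noisy or perspective image is first *corrected*: all segments
are rotated about their midpoints onto the common least-squares direction
u ∝ Σ(bᵢ − aᵢ), preserving lengths and midpoints. The corrected image
defines a **one-parameter family** of 3D symmetric interpretations
indexed by the slant σ of the symmetry plane (grid 0.2 … π/2 − 0.2 rad,
step 0.01 rad): with tilt τ read off u and plane gauge n·p = 0, each pair
with image midpoint (xₘ, yₘ) and length L gets midpoint depth
zₘ = −tan σ (xₘ cos τ + yₘ sin τ) and endpoint depths zₘ ∓ (L/2) cot σ.

Four estimators each select one slant:

| estimator | rule |
|---|---|
| θ_v2s3 | maximize compactness C₁ = V²/S³ of the convex hull over the slant grid |
| θ_s3v  | maximize modified compactness C₂ = V/S³ (tracks minimal depth range) |
| θ_sym2 | minimize the two-plane loss L(θ₁, θ₂) = Σᵢ ((z_{θ₁,i} − z̄_{θ₁}) − (z_{θ₂,i} − z̄_{θ₂}))², the depth discrepancy of vertices shared by the primary and secondary symmetry-plane families |
| θ_persp | median over segment pairs of atan(‖v‖/d), v the vanishing point of two extended symmetry lines (exactly 90° for parallel lines) |

Primary and secondary symmetry planes and their vertex correspondences
are found by RANSAC over bisector planes of random vertex pairs; the
secondary plane must lie ≥ 45° from the primary and maximizes
*overlapping correspondences* (chained triplets).

The estimates combine linearly, with the perspective weight λ driven by
the image's angular size γ:

θ̂ = λ θ_persp + (1 − λ)(β₀ + β₁ θ_v2s3 + β₂ θ_s3v + β₃ θ_sym2),
λ = (1 − cos φ)/2, φ = 2 atan(tan(γ/2) · tan t), t = 75°.

β₀…β₃ are fit per group by least squares against response slants.
Reconstruction error is reported as **shape dissimilarity**
log₂(tan σ_ref / tan σ_rec); a value x means the reconstructed aspect
ratio is 2ˣ times the reference (0.15 → 11%, 0.3 → 23%).

The package also ships the synthetic stimulus generator used to exercise
the model: random mirror-symmetric polyhedra (two appended box-like parts
with coplanar bottoms, planar faces, no 90° face angle, aspect ratio ≤ 9)
and rectangular mirror-symmetric polyhedra (two appended rectangular
prisms), plus slant/tilt trial sampling, the 1° segment-orientation noise
model, mesh I/O (OBJ/OFF/ASCII PLY), and an end-to-end pipeline.

## Worked example

```r
library(monoshape)

mesh   <- generate_rectangular_polyhedron(seed = 42)
planes <- select_primary_secondary(
  mesh, ransac_symmetry_planes(mesh, n_iters = 800, seed = 1))

view <- sample_view(seed = 42, slant_deg = 60)      # true slant 60 deg
cam  <- camera("perspective", distance = 50.8)       # 20-inch viewing
scaled <- mesh
scaled$vertices <- scaled$vertices * 50.8 * tan(10 * pi / 180) /
  sqrt(max(rowSums(sweep(mesh$vertices, 2, colMeans(mesh$vertices))^2)))
pose <- view_pose(view, distance = 50.8, center = colMeans(scaled$vertices))

img <- perturb_orientations(                         # 1-degree image noise
  project_pairs(scaled, planes$primary, pose, cam), sd_deg = 1, seed = 42)
img2 <- perturb_orientations(
  project_pairs(scaled, planes$secondary, pose, cam), sd_deg = 1, seed = 43)
posed  <- apply_pose(scaled, pose)
shared <- shared_index_map(posed,
                           pose_correspondences(planes$primary, pose),
                           pose_correspondences(planes$secondary, pose))
est <- trial_slant_estimates(img,
                             fam2 = family_grid(correct_to_orthographic(img2)),
                             shared = shared)

beta <- model_coefficients(0, 0.4, 0.1, 0.5)
predict_slant(est, beta)
```

Output on this machine:

```
slant_estimate [v2s3]:  72.193 deg
slant_estimate [s3v]:   57.296 deg
slant_estimate [sym2]:  53.858 deg
slant_estimate [persp]: 61.435 deg
gamma = 18.79 deg, lambda = 0.276
theta_hat = 61.51 deg   (true slant 60)
dissimilarity(model vs truth) = -0.089  -> aspect-ratio factor 0.940
```

Reading this: the compactness priors alone mis-estimate the slant (72.2°
and 57.3°), the two-plane constraint lands at 53.9°, and the vanishing
point — reliable here because the perspective image spans γ ≈ 19° — gives
61.4°. The λ-weighted combination predicts 61.5° against a true slant of
60°: a dissimilarity of −0.089, i.e. an aspect ratio within 6% of
veridical.

The full simulated experiment (generate → detect → project → perturb →
correct → estimate → simulate observer → fit → summarize) is one call:

```r
run <- run_pipeline(default_pipeline_config(), outdir = "out")
run$summary
```

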
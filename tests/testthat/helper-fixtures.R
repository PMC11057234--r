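# Shared fixtures and small oracles used across test files. All fixtures
# are built in code; nothing is read from disk.

yz_plane <- function() symmetry_plane(c(1, 0, 0), 0)

# Correspondences of a generated stimulus under its construction-time
# symmetry plane (exact by construction).
true_correspondences <- function(mesh, tol = 1e-9) {
  correspondences_under_plane(mesh, yz_plane(), tol)
}

# Full noiseless orthographic path: mesh -> posed image -> corrected image.
ortho_corrected <- function(mesh, slant_deg, tilt_deg, spin_deg = 0,
                            cs = true_correspondences(mesh)) {
  v <- view_spec(slant_deg, tilt_deg, spin_deg)
  pose <- view_pose(v, distance = 0, center = colMeans(mesh$vertices))
  img <- project_pairs(mesh, cs, pose, camera("orthographic"))
  list(image = img, corrected = correct_to_orthographic(img),
       pose = pose, cs = cs)
}

# Posed endpoint matrix in the same (a-rows, b-rows) order that
# project_pairs and reconstruct_at_slant use; the depth oracle for
# round-trip congruence checks.
posed_truth_points <- function(mesh, cs, pose) {
  posed <- apply_pose(mesh, pose)
  pl <- pose_correspondences(cs, pose)$plane
  side <- (posed$vertices %*% pl$normal)[, 1] - pl$offset
  ai <- ifelse(side[cs$pairs[, 1]] <= side[cs$pairs[, 2]],
               cs$pairs[, 1], cs$pairs[, 2])
  bi <- ifelse(side[cs$pairs[, 1]] <= side[cs$pairs[, 2]],
               cs$pairs[, 2], cs$pairs[, 1])
  posed$vertices[c(ai, bi), , drop = FALSE]
}

# RMS depth error after removing the free depth shift.
rms_after_depth_shift <- function(points, truth) {
  dz <- points[, 3] - truth[, 3]
  sqrt(mean((dz - mean(dz))^2))
}

sort_rows <- function(x) x[do.call(order, as.data.frame(x)), ]

# Roughly uniform directions on the half-sphere (Fibonacci spiral); the
# brute-force plane grid for symmetry-detection properties.
fibonacci_directions <- function(n = 200) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - i / n)          # upper half-sphere
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Scale a mesh so its circumradius subtends gamma_deg at distance d.
scale_to_gamma <- function(mesh, gamma_deg, distance) {
  ctr <- colMeans(mesh$vertices)
  r <- sqrt(max(rowSums(sweep(mesh$vertices, 2, ctr)^2)))
  mesh$vertices <- mesh$vertices * distance *
    tan(gamma_deg / 2 * pi / 180) / r
  mesh
}

# Perspective image of a generated stimulus at a given slant/tilt and
# angular size.
persp_image <- function(mesh, slant_deg, tilt_deg, gamma_deg = 20,
                        distance = 50.8,
                        cs = true_correspondences(mesh)) {
  m <- scale_to_gamma(mesh, gamma_deg, distance)
  v <- view_spec(slant_deg, tilt_deg)
  pose <- view_pose(v, distance = distance, center = colMeans(m$vertices))
  project_pairs(m, cs, pose, camera("perspective", distance))
}
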
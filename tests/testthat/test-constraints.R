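test_that("compactness values match closed forms and scaling laws", {
  cube <- unit_cube()
  expect_equal(compactness_c1(cube), 1 / 216)
  expect_equal(compactness_c2(cube), 1 / 216)

  sphere_hull <- convex_hull(icosphere(3)$vertices)
  expect_lt(abs(compactness_c1(sphere_hull) - 1 / (36 * pi)) /
              (1 / (36 * pi)), 0.01)

  k <- 3.7
  big <- unit_cube(); big$vertices <- big$vertices * k
  expect_equal(compactness_c1(big), compactness_c1(cube),
               tolerance = 1e-12)
  expect_equal(compactness_c2(big), compactness_c2(cube) / k^3,
               tolerance = 1e-12)
})

test_that("compactness slant selectors equal the brute-force grid oracle", {
  m <- generate_random_polyhedron(seed = 26)
  fam <- family_grid(ortho_corrected(m, 45, 30)$corrected)
  for (which in c("c1", "c2")) {
    est <- select_slant_compactness(fam, which)
    fn <- if (which == "c1") compactness_c1 else compactness_c2
    oracle <- vapply(fam$slants_deg, function(s)
      fn(convex_hull(reconstruct_at_slant(fam$image, s)$points)),
      numeric(1))
    expect_equal(est$value_deg, fam$slants_deg[which.max(oracle)])
    expect_equal(est$diagnostics$objective, oracle, tolerance = 1e-12)
    # unique maximizer on generated stimuli
    expect_equal(sum(oracle >= max(oracle) - 1e-15), 1)
  }
})

test_that("two-plane loss is a centered depth discrepancy", {
  m <- generate_rectangular_polyhedron(seed = 11)
  cands <- ransac_symmetry_planes(m, n_iters = 800, seed = 5)
  sel <- select_primary_secondary(m, cands)
  # generic spin: a zero spin sends both plane normals to the same image
  # tilt, which degenerates the loss surface into a shallow valley
  out1 <- ortho_corrected(m, 45, 30, spin_deg = 37, cs = sel$primary)
  img2 <- project_pairs(m, sel$secondary, out1$pose, camera("orthographic"))
  fam1 <- family_grid(out1$corrected)
  fam2 <- family_grid(correct_to_orthographic(img2))
  posed <- apply_pose(m, out1$pose)
  shared <- shared_index_map(posed,
                             pose_correspondences(sel$primary, out1$pose),
                             pose_correspondences(sel$secondary, out1$pose))
  expect_gte(nrow(shared), 3)

  true1 <- out1$image$meta$slant_deg
  true2 <- img2$meta$slant_deg
  # loss vanishes at the true slant pair for a noiseless two-plane object
  expect_lt(two_plane_loss(fam1, fam2, shared, true1, true2), 1e-12)
  # depth-shift gauge: translating one image along its symmetry direction
  # shifts that family's depths by a constant and leaves L unchanged
  l0 <- two_plane_loss(fam1, fam2, shared, 40, 50)
  expect_gt(l0, 0)
  shifted <- fam1
  shifted$image$a <- shifted$image$a + rbind(shifted$image$u)[rep(1, nrow(shifted$image$a)), ] * 3.1
  shifted$image$b <- shifted$image$b + rbind(shifted$image$u)[rep(1, nrow(shifted$image$b)), ] * 3.1
  expect_equal(two_plane_loss(shifted, fam2, shared, 40, 50), l0,
               tolerance = 1e-9)

  est <- select_slant_two_planes(fam1, fam2, shared)
  step_deg <- 0.01 * 180 / pi
  expect_lt(abs(est$value_deg - true1), step_deg + 1e-9)

  # swapping the families returns the same minimum cell, roles exchanged
  est_sw <- select_slant_two_planes(fam2, fam1, shared[, 2:1])
  expect_equal(est_sw$value_deg, est$diagnostics$theta2_star_deg)
  expect_equal(est_sw$diagnostics$theta2_star_deg, est$value_deg)

  # grid selector equals an independent brute-force argmin
  oracle <- Inf; arg <- c(NA, NA)
  for (t1 in fam1$slants_deg[seq(1, length(fam1$slants_deg), by = 8)])
    for (t2 in fam2$slants_deg[seq(1, length(fam2$slants_deg), by = 8)]) {
      l <- two_plane_loss(fam1, fam2, shared, t1, t2)
      if (l < oracle) { oracle <- l; arg <- c(t1, t2) }
    }
  sub <- est$diagnostics$loss[seq(1, length(fam1$slants_deg), by = 8),
                              seq(1, length(fam2$slants_deg), by = 8)]
  expect_equal(min(sub), oracle, tolerance = 1e-12)

  expect_error(two_plane_loss(fam1, fam2, shared[0, , drop = FALSE],
                              40, 50), "empty shared")
})

test_that("vanishing-point slants are exact on constructed inputs", {
  # parallel segments (orthographic image): exactly 90
  m <- generate_random_polyhedron(seed = 3)
  img_o <- ortho_corrected(m, 30, 40)$image
  img_o$camera <- camera("perspective", 50.8)  # finite distance metadata
  expect_identical(vanishing_point_slant(img_o)$value_deg, 90)

  # rotated-rectangles construction: 75-degree rotation gives slant 15
  expect_equal(vanishing_point_slant(rotated_rectangles_image(75))$value_deg,
               15, tolerance = 1e-9)
  # and the relation is general: rotation r -> slant 90 - r
  expect_equal(vanishing_point_slant(rotated_rectangles_image(40))$value_deg,
               50, tolerance = 1e-9)

  expect_error(vanishing_point_slant(
    structure(list(a = cbind(0, 0), b = cbind(1, 1),
                   camera = camera("perspective", 10), meta = list()),
              class = "pair_image")), "two symmetry segments")
})

test_that("vanishing-point estimator recovers slant from perspective images
           and degrades gracefully under orientation noise", {
  m <- generate_random_polyhedron(seed = 15)
  for (s in c(15, 30, 45, 60, 75)) {
    img <- persp_image(m, s, 35, gamma_deg = 20)
    expect_lt(abs(vanishing_point_slant(img)$value_deg - s), 0.5)
  }
  errs <- vapply(1:5, function(k) {
    img <- persp_image(m, 30, 35, gamma_deg = 20)
    noisy <- perturb_orientations(img, 1, seed = k)
    abs(vanishing_point_slant(noisy)$value_deg - 30)
  }, numeric(1))
  expect_lt(stats::median(errs), 5)
})

test_that("depth structure is shift-invariant, pair offsets fall with slant", {
  m <- generate_random_polyhedron(seed = 6)
  co <- ortho_corrected(m, 45, 30)$corrected
  # within-pair depth offsets are L cot(sigma): strictly decreasing
  mpts <- nrow(co$a)
  offs <- vapply(seq(15, 80, by = 5), function(s) {
    z <- reconstruct_at_slant(co, s)$points[, 3]
    mean(z[mpts + seq_len(mpts)] - z[seq_len(mpts)])
  }, numeric(1))
  expect_true(all(diff(offs) < 0))

  rec <- reconstruct_at_slant(co, 45)
  shifted <- rec
  shifted$points[, 3] <- shifted$points[, 3] + 11.3
  expect_equal(depth_range(shifted), depth_range(rec))
  flat <- rec; flat$points[, 3] <- 2
  expect_equal(depth_range(flat), 0)
})

test_that("the modified-compactness choice tracks minimal depth range", {
  # the slant maximizing C2 follows the slant minimizing depth range
  # closely across trials (12 trials, scaled down from 100 for runtime)
  res <- vapply(1:12, function(s) {
    m <- generate_random_polyhedron(seed = 300 + s)
    v <- sample_view(seed = 300 + s)
    fam <- family_grid(
      ortho_corrected(m, v$slant_deg, v$tilt_deg, v$spin_deg)$corrected)
    e2 <- select_slant_compactness(fam, "c2")$value_deg
    dr <- vapply(fam$slants_deg, function(sl)
      depth_range(reconstruct_at_slant(fam$image, sl)), numeric(1))
    c(c2 = e2, dr_min = fam$slants_deg[which.min(dr)])
  }, numeric(2))
  expect_gt(stats::cor(res["c2", ], res["dr_min", ]), 0.9)
})
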
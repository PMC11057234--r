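test_that("bisector planes have the defining reflection property", {
  pl <- bisector_plane(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(pl$normal, c(1, 0, 0))
  expect_equal(pl$offset, 0)

  pl2 <- bisector_plane(c(2, 3, 3), c(0, 3, 3))
  expect_equal(pl2$normal, c(1, 0, 0))
  expect_equal(pl2$offset, 1)

  set.seed(4)
  p <- rnorm(3); q <- rnorm(3)
  pl3 <- bisector_plane(p, q)
  expect_equal(as.numeric(reflect_points(rbind(p), pl3)), q,
               tolerance = 1e-12)
  expect_error(bisector_plane(p, p), "coincident")
})

test_that("correspondences under a plane behave on the cube", {
  cube <- unit_cube()
  mid <- symmetry_plane(c(1, 0, 0), 0.5)
  cs <- correspondences_under_plane(cube, mid, 1e-6)
  expect_equal(nrow(cs$pairs), 4)
  expect_true(all(cs$pairs[, 1] < cs$pairs[, 2]))
  expect_equal(anyDuplicated(as.vector(cs$pairs)), 0L)

  # generic plane pairs nothing at tight tolerance (brute-force checked)
  generic <- symmetry_plane(c(0.3, 0.5, 0.81), 0.37)
  refl <- reflect_points(cube$vertices, generic)
  min_d <- min(vapply(1:8, function(i)
    min(sqrt(rowSums(sweep(cube$vertices[-i, ], 2, refl[i, ])^2))),
    numeric(1)))
  expect_gt(min_d, 1e-6)
  expect_equal(nrow(correspondences_under_plane(cube, generic, 1e-6)$pairs),
               0)

  # huge tolerance pairs everything
  cs_inf <- correspondences_under_plane(cube, generic, 1e9)
  expect_equal(nrow(cs_inf$pairs), 4)
})

test_that("reflection maps the matched pair set onto itself", {
  m <- generate_random_polyhedron(seed = 21)
  cs <- true_correspondences(m)
  refl <- reflect_points(m$vertices, cs$plane)
  for (k in seq_len(nrow(cs$pairs))) {
    expect_equal(refl[cs$pairs[k, 1], ], m$vertices[cs$pairs[k, 2], ],
                 tolerance = 1e-12)
  }
})

test_that("RANSAC recovers the construction plane and is deterministic", {
  m <- generate_random_polyhedron(seed = 12)
  cands <- ransac_symmetry_planes(m, n_iters = 800, seed = 1)
  top <- cands[[1]]
  expect_lt(max(abs(abs(top$plane$normal) - c(1, 0, 0))), 1e-6)
  expect_equal(nrow(top$pairs), nrow(m$vertices) / 2)

  again <- ransac_symmetry_planes(m, n_iters = 800, seed = 1)
  expect_identical(lapply(cands, `[[`, "pairs"),
                   lapply(again, `[[`, "pairs"))
})

test_that("the cube's three mid-planes all emerge with full counts", {
  cube <- unit_cube()
  cands <- ransac_symmetry_planes(cube, n_iters = 300, seed = 2,
                                  tol = 1e-6)
  axes <- t(vapply(cands, function(c_) c_$plane$normal, numeric(3)))
  counts <- vapply(cands, function(c_) nrow(c_$pairs), integer(1))
  for (ax in 1:3) {
    hit <- which(abs(abs(axes[, ax]) - 1) < 1e-6)
    expect_true(length(hit) >= 1)
    expect_true(any(counts[hit] == 4))
  }
})

test_that("true plane beats every plane >= 10 degrees away", {
  m <- generate_random_polyhedron(seed = 30)
  tol <- 0.01 * monoshape:::mesh_diameter(m)
  ctr <- colMeans(m$vertices)
  true_count <- nrow(true_correspondences(m, tol)$pairs)
  expect_equal(true_count, nrow(m$vertices) / 2)
  dirs <- fibonacci_directions(150)
  for (k in seq_len(nrow(dirs))) {
    n <- dirs[k, ]
    if (acos(pmin(1, abs(n[1]))) * 180 / pi < 10) next
    pl <- symmetry_plane(n, sum(n * ctr))
    expect_lt(nrow(correspondences_under_plane(m, pl, tol)$pairs),
              true_count)
  }
})

test_that("detection is invariant to vertex order", {
  m <- generate_random_polyhedron(seed = 9)
  perm <- sample(nrow(m$vertices))
  inv <- order(perm)
  m2 <- mesh3(m$vertices[perm, ], lapply(m$faces, function(f) inv[f]))
  c1 <- ransac_symmetry_planes(m, n_iters = 500, seed = 3)[[1]]
  c2 <- ransac_symmetry_planes(m2, n_iters = 500, seed = 3)[[1]]
  expect_equal(abs(sum(c1$plane$normal * c2$plane$normal)), 1,
               tolerance = 1e-6)
  expect_equal(nrow(c1$pairs), nrow(c2$pairs))
})

test_that("overlap counting matches brute-force triplet enumeration", {
  cube <- unit_cube()
  a <- correspondences_under_plane(cube, symmetry_plane(c(1, 0, 0), 0.5),
                                   1e-6)
  b <- correspondences_under_plane(cube, symmetry_plane(c(0, 1, 0), 0.5),
                                   1e-6)
  # oracle: enumerate all (u, v, w) triplets directly
  oracle <- 0L
  for (i in seq_len(nrow(a$pairs))) for (j in seq_len(nrow(b$pairs))) {
    pa <- a$pairs[i, ]; pb <- b$pairs[j, ]
    for (v in intersect(pa, pb)) {
      u <- setdiff(pa, v); w <- setdiff(pb, v)
      if (length(u) == 1 && length(w) == 1 && u != w)
        oracle <- oracle + 1L
    }
  }
  expect_equal(overlap_count(a, b), oracle)
  expect_equal(overlap_count(a, b), 8L)
  expect_equal(overlap_count(a, a), 0L)   # u != w convention

  disjoint <- a
  disjoint$pairs <- matrix(c(9L, 10L), 1)  # indices outside b's coverage
  expect_equal(overlap_count(disjoint, b), 0L)
})

test_that("primary/secondary selection matches the two-box structure", {
  m <- generate_rectangular_polyhedron(seed = 6)
  cands <- ransac_symmetry_planes(m, n_iters = 800, seed = 4)
  sel <- select_primary_secondary(m, cands)
  # primary is the whole-object YZ plane with every vertex paired
  expect_lt(max(abs(abs(sel$primary$plane$normal) - c(1, 0, 0))), 1e-6)
  expect_equal(nrow(sel$primary$pairs), nrow(m$vertices) / 2)
  # orthogonal secondary
  ang <- acos(abs(sum(sel$primary$plane$normal *
                        sel$secondary$plane$normal))) * 180 / pi
  expect_gt(ang, 88)

  cube <- unit_cube()
  csel <- select_primary_secondary(
    cube, ransac_symmetry_planes(cube, n_iters = 300, seed = 5, tol = 1e-6))
  ang_c <- acos(abs(sum(csel$primary$plane$normal *
                          csel$secondary$plane$normal))) * 180 / pi
  expect_equal(ang_c, 90, tolerance = 1e-6)
})

test_that("random polyhedra still yield a usable secondary plane", {
  m <- generate_random_polyhedron(seed = 14)
  cands <- ransac_symmetry_planes(m, n_iters = 800, seed = 6)
  sel <- select_primary_secondary(m, cands)
  ang <- acos(abs(sum(sel$primary$plane$normal *
                        sel$secondary$plane$normal))) * 180 / pi
  expect_gte(ang, 45 - 1e-9)
  expect_gte(nrow(sel$secondary$pairs), 1)
})
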
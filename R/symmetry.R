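# RANSAC estimation of the primary and secondary mirror-symmetry planes of
# a mesh. Candidate planes are bisectors of random vertex pairs; each is
# scored by the number of disjoint vertex pairs mapped onto each other by
# the reflection within tolerance. The secondary plane must make an angle
# of at least 45 degrees with the primary and is scored by overlapping
# correspondences (chained triplets sharing a middle vertex).

#' Mirror-symmetry plane
#'
#' The plane n . p = c with unit normal n. The normal's sign is
#' canonicalized to non-negative z component (non-negative x when the z
#' component is ~0, then non-negative y).
#'
#' @param normal length-3 numeric, need not be unit length
#' @param offset scalar c
#' @return a list of class `symmetry_plane` with unit `normal` and `offset`
#' @export
symmetry_plane <- function(normal, offset) {
  n <- as.numeric(normal)
  len <- sqrt(sum(n^2))
  if (len == 0) stop("zero normal")
  n <- n / len
  offset <- offset / len
  flip <- if (abs(n[3]) > 1e-9) n[3] < 0
          else if (abs(n[1]) > 1e-9) n[1] < 0
          else n[2] < 0
  if (flip) { n <- -n; offset <- -offset }
  structure(list(normal = n, offset = offset), class = "symmetry_plane")
}

#' Slant and tilt of a symmetry plane relative to the camera
#'
#' Slant is the angle between the plane normal and the camera axis (+z);
#' tilt is the image-plane orientation of the projected normal.
#'
#' @param plane a `symmetry_plane`
#' @return list with `slant_deg` in [0, 90] and `tilt_deg` in [0, 360)
#' @export
plane_slant_tilt <- function(plane) {
  n <- plane$normal
  slant <- acos(pmin(1, abs(n[3]))) * 180 / pi
  tilt <- (atan2(n[2], n[1]) * 180 / pi) %% 360
  list(slant_deg = slant, tilt_deg = tilt)
}

#' Reflect points about a symmetry plane
#' @param points n x 3 matrix
#' @param plane a `symmetry_plane`
#' @return n x 3 matrix of reflections
#' @export
reflect_points <- function(points, plane) {
  pts <- as.matrix(points)
  d <- pts %*% plane$normal - plane$offset
  pts - 2 * d %*% rbind(plane$normal)
}

#' Perpendicular bisector plane of two points
#'
#' The unique candidate mirror plane exchanging p and q: normal along
#' p - q, passing through their midpoint.
#'
#' @param p,q length-3 numeric, distinct
#' @return a `symmetry_plane`
#' @export
bisector_plane <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  d <- p - q
  if (sqrt(sum(d^2)) == 0) stop("coincident points have no bisector plane")
  mid <- (p + q) / 2
  n <- d / sqrt(sum(d^2))
  symmetry_plane(n, sum(n * mid))
}

#' Vertex correspondences of a mesh under a candidate mirror plane
#'
#' Greedy matching: each vertex's reflection is matched to its nearest
#' still-unmatched vertex if the residual is within `tol`. Pairs are
#' disjoint and stored with i < j. A vertex lying on the plane (matching
#' itself) is not paired.
#'
#' @param mesh a `mesh3` (or n x 3 vertex matrix)
#' @param plane a `symmetry_plane`
#' @param tol absolute matching tolerance (same length unit as the mesh)
#' @return a list of class `correspondence_set`: `plane`, `pairs` (m x 2
#'   integer matrix), `tol`, `residuals` (per-pair match distance)
#' @export
correspondences_under_plane <- function(mesh, plane, tol) {
  stopifnot(tol > 0)
  pts <- if (inherits(mesh, "mesh3")) mesh$vertices else as.matrix(mesh)
  n <- nrow(pts)
  refl <- reflect_points(pts, plane)
  # globally greedy matching on the full reflection-distance matrix so a
  # vertex whose nearest match is taken can still pair with its next
  # nearest (with tol = Inf every vertex pairs, floor(n/2) pairs)
  d2 <- outer(rowSums(refl^2), rowSums(pts^2), `+`) -
    2 * refl %*% t(pts)
  diag(d2) <- Inf
  tol2 <- tol^2
  pairs <- matrix(integer(0), 0, 2)
  res <- numeric(0)
  repeat {
    k <- which.min(d2)
    if (length(k) == 0 || !is.finite(d2[k]) || d2[k] > tol2) break
    ij <- arrayInd(k, dim(d2))
    i <- ij[1]; j <- ij[2]
    pairs <- rbind(pairs, c(min(i, j), max(i, j)))
    res <- c(res, sqrt(max(d2[k], 0)))
    d2[c(i, j), ] <- Inf
    d2[, c(i, j)] <- Inf
  }
  if (nrow(pairs) > 0) {
    o <- order(pairs[, 1])
    pairs <- pairs[o, , drop = FALSE]
    res <- res[o]
  }
  structure(list(plane = plane, pairs = pairs, tol = tol,
                 residuals = res),
            class = "correspondence_set")
}

#' @export
print.correspondence_set <- function(x, ...) {
  st <- plane_slant_tilt(x$plane)
  cat(sprintf(
    "correspondence_set: %d pairs, tol %.3g, slant %.1f deg, tilt %.1f deg\n",
    nrow(x$pairs), x$tol, st$slant_deg, st$tilt_deg))
  invisible(x)
}

plane_angle_deg <- function(a, b) {
  # angle between plane normals as undirected axes
  ca <- abs(sum(a$normal * b$normal))
  acos(pmin(1, ca)) * 180 / pi
}

# Least-squares refit of a mirror plane to its inlier pairs: the normal is
# the principal direction of the pair difference vectors, the offset the
# mean projection of pair midpoints.
refit_plane <- function(pts, pairs) {
  d <- pts[pairs[, 2], , drop = FALSE] - pts[pairs[, 1], , drop = FALSE]
  d <- d / sqrt(rowSums(d^2))
  # sign-align difference vectors before averaging the axis
  ref <- d[1, ]
  flip <- (d %*% ref)[, 1] < 0
  d[flip, ] <- -d[flip, , drop = FALSE]
  sv <- svd(d)
  n <- sv$v[, 1]
  mid <- (pts[pairs[, 1], , drop = FALSE] +
            pts[pairs[, 2], , drop = FALSE]) / 2
  symmetry_plane(n, mean(mid %*% n))
}

#' RANSAC candidate mirror planes of a mesh
#'
#' Repeatedly samples two distinct vertices, forms their bisector plane and
#' collects its correspondences. Candidates are refined by one
#' least-squares refit to their inliers, deduplicated (normals within 2
#' degrees and offsets within `tol`), and ranked by pair count with ties
#' broken by smaller mean residual.
#'
#' @param mesh a `mesh3`
#' @param n_iters number of RANSAC iterations (default 2000)
#' @param tol matching tolerance; default 0.01 x object diameter
#' @param seed integer seed
#' @return list of `correspondence_set`, best first
#' @export
ransac_symmetry_planes <- function(mesh, n_iters = 2000L, tol = NULL,
                                   seed = 1L) {
  pts <- if (inherits(mesh, "mesh3")) mesh$vertices else as.matrix(mesh)
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 vertices for symmetry detection")
  if (is.null(tol)) tol <- 0.01 * mesh_diameter(mesh3(pts, list(c(1, 2, 3))))
  with_seed(seed, {
    cands <- list()
    for (it in seq_len(n_iters)) {
      ij <- sample.int(n, 2)
      if (all(pts[ij[1], ] == pts[ij[2], ])) next
      plane <- bisector_plane(pts[ij[1], ], pts[ij[2], ])
      cs <- correspondences_under_plane(pts, plane, tol)
      if (nrow(cs$pairs) < 1) next
      refined <- refit_plane(pts, cs$pairs)
      cs <- correspondences_under_plane(pts, refined, tol)
      if (nrow(cs$pairs) < 1) next
      dup <- FALSE
      for (k in seq_along(cands)) {
        if (plane_angle_deg(cands[[k]]$plane, cs$plane) < 2 &&
            abs(cands[[k]]$plane$offset - cs$plane$offset) < tol) {
          if (nrow(cs$pairs) > nrow(cands[[k]]$pairs) ||
              (nrow(cs$pairs) == nrow(cands[[k]]$pairs) &&
                 mean(cs$residuals) < mean(cands[[k]]$residuals)))
            cands[[k]] <- cs
          dup <- TRUE
          break
        }
      }
      if (!dup) cands[[length(cands) + 1L]] <- cs
    }
    if (length(cands) == 0) stop("no symmetry plane candidates found")
    counts <- vapply(cands, function(c_) nrow(c_$pairs), integer(1))
    resid <- vapply(cands, function(c_) mean(c_$residuals), numeric(1))
    cands[order(-counts, resid)]
  })
}

#' Overlapping correspondences between two planes' correspondence sets
#'
#' Counts vertex triplets (u, v, w), u != w, with (u, v) a pair of `a` and
#' (v, w) a pair of `b`: object parts symmetric about both planes.
#'
#' @param a,b `correspondence_set`s on the same mesh
#' @return integer triplet count
#' @export
overlap_count <- function(a, b) {
  if (nrow(a$pairs) == 0 || nrow(b$pairs) == 0) return(0L)
  partner <- function(pairs, v) {
    hits <- c(pairs[pairs[, 1] == v, 2], pairs[pairs[, 2] == v, 1])
    hits
  }
  total <- 0L
  verts_a <- unique(as.vector(a$pairs))
  for (v in verts_a) {
    us <- partner(a$pairs, v)
    ws <- partner(b$pairs, v)
    if (length(ws) == 0) next
    for (u in us) total <- total + sum(ws != u)
  }
  as.integer(total)
}

# Vertices carried by both planes' pair sets (the triplet middles); these
# are the shared indices the two-plane depth-consistency loss is computed
# on.
shared_vertices <- function(a, b) {
  sort(intersect(unique(as.vector(a$pairs)), unique(as.vector(b$pairs))))
}

#' Transform a correspondence set's plane by a rigid pose
#'
#' Vertex index pairs are pose-invariant; only the plane moves. Useful for
#' working with a posed copy of the mesh the correspondences were detected
#' on.
#'
#' @param cs a `correspondence_set`
#' @param pose a `rigid_pose`
#' @return a `correspondence_set` with the plane in posed coordinates
#' @export
pose_correspondences <- function(cs, pose) {
  n <- as.numeric(pose$rotation %*% cs$plane$normal)
  c_ <- cs$plane$offset + sum(n * pose$translation)
  cs$plane <- symmetry_plane(n, c_)
  cs
}

#' Select the primary and secondary symmetry planes
#'
#' Primary: the candidate with the most correspondences. Secondary: among
#' candidates whose normal makes an angle of at least `min_angle_deg` with
#' the primary normal, the one with the most overlapping correspondences.
#' If no such candidate has any overlap at the detection tolerance (random
#' polyhedra have a single true plane), the correspondence sets are
#' recomputed at `large_tol` (default 0.15 x object diameter) and the best
#' estimate under that large tolerance is returned.
#'
#' @param mesh the `mesh3` the candidates were computed on
#' @param candidates ranked list from [ransac_symmetry_planes()]
#' @param min_angle_deg minimum primary/secondary normal angle (45)
#' @param large_tol fallback tolerance; default 0.15 x object diameter
#' @return list with `primary` and `secondary` (`correspondence_set`s) and
#'   `secondary_large_tol` flag
#' @export
select_primary_secondary <- function(mesh, candidates, min_angle_deg = 45,
                                     large_tol = NULL) {
  if (length(candidates) < 1) stop("no candidates")
  pts <- if (inherits(mesh, "mesh3")) mesh$vertices else as.matrix(mesh)
  primary <- candidates[[1]]
  ok_angle <- vapply(candidates, function(c_)
    plane_angle_deg(c_$plane, primary$plane) >= min_angle_deg, logical(1))
  eligible <- candidates[ok_angle]
  pick_best <- function(sets) {
    ov <- vapply(sets, function(c_) overlap_count(primary, c_), integer(1))
    if (max(ov) < 1) return(NULL)
    sets[[which.max(ov)]]
  }
  secondary <- if (length(eligible)) pick_best(eligible) else NULL
  used_large <- FALSE
  if (is.null(secondary)) {
    if (is.null(large_tol))
      large_tol <- 0.15 * mesh_diameter(mesh3(pts, list(c(1, 2, 3))))
    enlarged <- lapply(candidates[ok_angle], function(c_)
      correspondences_under_plane(pts, c_$plane, large_tol))
    secondary <- if (length(enlarged)) pick_best(enlarged) else NULL
    used_large <- TRUE
    if (is.null(secondary))
      stop("no secondary plane satisfies the 45-degree rule, ",
           "even at large tolerance")
  }
  list(primary = primary, secondary = secondary,
       secondary_large_tol = used_large)
}
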
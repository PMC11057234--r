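# The four slant estimators that pick a member of the one-parameter
# family: maximum compactness V^2/S^3 (theta_v2s3), maximum modified
# compactness V/S^3 (theta_s3v), the two-plane depth-consistency loss
# (theta_sym2), and the vanishing-point estimator from perspective images
# (theta_persp). Compactness is always evaluated on the convex hull of the
# reconstructed points: raw part volume of thin structures is unreliable.

#' Compactness V^2 / S^3 of a closed shape
#'
#' Dimensionless and maximized by the sphere (value 1 / (36 pi)); a unit
#' cube scores 1/216. Invariant under uniform scaling.
#'
#' @param mesh a watertight `mesh3` (callers pass the convex hull)
#' @return V(O)^2 / S(O)^3
#' @export
compactness_c1 <- function(mesh) {
  s <- mesh_surface_area(mesh)
  if (s == 0) stop("zero surface area")
  mesh_volume(mesh)^2 / s^3
}

#' Modified compactness V / S^3
#'
#' Not dimensionless (scales as k^-3 under uniform scaling by k), so
#' values are only comparable within one family, where the image fixes the
#' scale. Its maximizer is strongly tied to minimizing the shape's depth
#' range.
#'
#' @inheritParams compactness_c1
#' @return V(O) / S(O)^3
#' @export
compactness_c2 <- function(mesh) {
  s <- mesh_surface_area(mesh)
  if (s == 0) stop("zero surface area")
  mesh_volume(mesh) / s^3
}

#' A slant point estimate with diagnostics
#' @param value_deg estimate in degrees
#' @param estimator one of "v2s3", "s3v", "sym2", "persp"
#' @param diagnostics free-form list
#' @return a list of class `slant_estimate`
#' @export
slant_estimate <- function(value_deg, estimator, diagnostics = list()) {
  structure(list(value_deg = value_deg, estimator = estimator,
                 diagnostics = diagnostics),
            class = "slant_estimate")
}

#' @export
print.slant_estimate <- function(x, ...) {
  cat(sprintf("slant_estimate [%s]: %.3f deg\n", x$estimator, x$value_deg))
  invisible(x)
}

#' Select a family member by maximum (modified) compactness
#'
#' Evaluates the chosen compactness on the convex hull of the
#' reconstruction at every grid slant and returns the argmax. The maximum
#' is asserted to be unique: several non-adjacent grid cells within 1e-12
#' of the maximum are flagged via a warning and recorded in the
#' diagnostics.
#'
#' @param family a `family_grid`
#' @param which "c1" (V^2/S^3) or "c2" (V/S^3)
#' @return a `slant_estimate` with estimator "v2s3" or "s3v"; diagnostics
#'   hold the full objective curve
#' @export
select_slant_compactness <- function(family, which = c("c1", "c2")) {
  which <- match.arg(which)
  stopifnot(inherits(family, "family_grid"))
  fn <- if (which == "c1") compactness_c1 else compactness_c2
  vals <- vapply(family$slants_deg, function(s) {
    recon <- reconstruct_at_slant(family$image, s)
    fn(convex_hull(recon$points))
  }, numeric(1))
  flag_non_unique(vals, paste("compactness", which))
  k <- which.max(vals)
  slant_estimate(family$slants_deg[k],
                 estimator = if (which == "c1") "v2s3" else "s3v",
                 diagnostics = list(objective = vals,
                                    slants_deg = family$slants_deg))
}

flag_non_unique <- function(vals, what, minimize = FALSE) {
  v <- if (minimize) -vals else vals
  best <- max(v)
  near <- which(v >= best - 1e-12)
  if (length(near) > 1 && any(diff(sort(near)) > 1))
    warning("non-unique optimum of ", what,
            " at non-adjacent grid cells; first taken")
  invisible(near)
}

# Per-pair depth coefficients of a corrected image: for the family of
# `image`, the depth of endpoint rows (a then b) at slant sigma is
# z = -q tan(sigma) + s (L/2) cot(sigma) with s = -1 for a, +1 for b.
depth_coefficients <- function(image) {
  u <- image$u
  mid <- (image$a + image$b) / 2
  q <- as.numeric(mid %*% u)
  halfL <- segment_lengths(image) / 2
  list(q = c(q, q), s_halfL = c(-halfL, halfL))
}

depths_at_slant <- function(coef, slant_deg) {
  sig <- slant_deg * pi / 180
  -coef$q * tan(sig) + coef$s_halfL / tan(sig)
}

#' Two-plane depth-consistency loss
#'
#' For vertices shared by the correspondence sets of two symmetry planes,
#' compares the mean-centered depth profiles of the two families at slants
#' (theta1, theta2): L = sum_i ((z1_i - mean z1) - (z2_i - mean z2))^2.
#' For a noiseless orthographic image of an object with two true symmetry
#' planes the loss vanishes at the true slant pair, since the two families
#' coincide there up to a constant depth shift.
#'
#' @param fam1,fam2 `family_grid`s built from the corrected pair images of
#'   the primary and secondary planes
#' @param shared two-column integer matrix: row k gives the row index of
#'   shared vertex k in `fam1$image` (column 1) and `fam2$image` (column
#'   2), counted over the stacked (a then b) endpoint rows
#' @param theta1_deg,theta2_deg slants of the two families
#' @return the loss (non-negative)
#' @export
two_plane_loss <- function(fam1, fam2, shared, theta1_deg, theta2_deg) {
  if (NROW(shared) == 0) stop("empty shared vertex set")
  c1 <- depth_coefficients(fam1$image)
  c2 <- depth_coefficients(fam2$image)
  z1 <- depths_at_slant(c1, theta1_deg)[shared[, 1]]
  z2 <- depths_at_slant(c2, theta2_deg)[shared[, 2]]
  sum(((z1 - mean(z1)) - (z2 - mean(z2)))^2)
}

#' Select the primary-plane slant by the two-plane constraint
#'
#' Exhaustive search of the loss over the grid of (theta1, theta2) pairs;
#' returns theta1 at the global minimum. Uniqueness of the minimum is
#' asserted as in [select_slant_compactness()].
#'
#' @inheritParams two_plane_loss
#' @return a `slant_estimate` with estimator "sym2"; diagnostics hold the
#'   full loss surface and the minimizing theta2
#' @export
select_slant_two_planes <- function(fam1, fam2, shared) {
  if (NROW(shared) == 0) stop("empty shared vertex set")
  c1 <- depth_coefficients(fam1$image)
  c2 <- depth_coefficients(fam2$image)
  s1 <- fam1$slants_deg
  s2 <- fam2$slants_deg
  i1 <- shared[, 1]; i2 <- shared[, 2]
  z2mat <- vapply(s2, function(t2) {
    z <- depths_at_slant(c2, t2)[i2]
    z - mean(z)
  }, numeric(length(i2)))
  loss <- matrix(NA_real_, length(s1), length(s2))
  for (k in seq_along(s1)) {
    z1 <- depths_at_slant(c1, s1[k])[i1]
    z1 <- z1 - mean(z1)
    loss[k, ] <- colSums((z2mat - z1)^2)
  }
  flag_non_unique(as.vector(loss), "two-plane loss", minimize = TRUE)
  k <- arrayInd(which.min(loss), dim(loss))
  slant_estimate(s1[k[1]], estimator = "sym2",
                 diagnostics = list(loss = loss,
                                    theta1_deg = s1, theta2_deg = s2,
                                    theta2_star_deg = s2[k[2]]))
}

#' Map shared vertices to endpoint rows of two pair images
#'
#' The two-plane loss needs, for each vertex carried by both planes'
#' correspondence sets, its endpoint row in each family's image. Given the
#' two correspondence sets (on the same mesh) this helper returns that
#' index map, using the same endpoint ordering rule as [project_pairs()].
#'
#' @param mesh the posed `mesh3` both images were projected from
#' @param cs1,cs2 `correspondence_set`s of the two planes, with planes in
#'   the same (posed) frame as `mesh`
#' @return two-column integer matrix usable as `shared` in
#'   [two_plane_loss()]
#' @export
shared_index_map <- function(mesh, cs1, cs2) {
  pts <- if (inherits(mesh, "mesh3")) mesh$vertices else as.matrix(mesh)
  row_of <- function(cs) {
    side <- (pts %*% cs$plane$normal)[, 1] - cs$plane$offset
    m <- nrow(cs$pairs)
    ai <- ifelse(side[cs$pairs[, 1]] <= side[cs$pairs[, 2]],
                 cs$pairs[, 1], cs$pairs[, 2])
    bi <- ifelse(side[cs$pairs[, 1]] <= side[cs$pairs[, 2]],
                 cs$pairs[, 2], cs$pairs[, 1])
    rows <- integer(nrow(pts))
    rows[ai] <- seq_len(m)
    rows[bi] <- m + seq_len(m)
    rows
  }
  r1 <- row_of(cs1); r2 <- row_of(cs2)
  sv <- shared_vertices(cs1, cs2)
  cbind(r1[sv], r2[sv])
}

#' Vanishing-point slant estimate from a perspective image
#'
#' In a perspective image the symmetry segments of a mirror-symmetric
#' object converge to a vanishing point v; the ray from the center of
#' projection through v (a point on the picture plane z = d) is normal to
#' the symmetry plane, so the per-pair slant is atan(|v| / d). Every pair
#' of extended segments contributes one estimate; pairs that are parallel
#' beyond `parallel_factor` times the image diameter contribute 90 degrees
#' (the orthographic limit, where the vanishing point sits at infinity).
#' The estimate is the median over pairs.
#'
#' @param image a `pair_image` (any projection; an orthographic image of a
#'   symmetric shape yields exactly 90)
#' @param parallel_factor intersections farther than this multiple of the
#'   image diameter are treated as parallel
#' @return a `slant_estimate` with estimator "persp"; diagnostics hold the
#'   per-pair slants
#' @export
vanishing_point_slant <- function(image, parallel_factor = 1e6) {
  m <- nrow(image$a)
  if (m < 2) stop("need at least two symmetry segments")
  d <- image$camera$distance
  dirs <- image$b - image$a
  pts <- rbind(image$a, image$b)
  diam <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
  if (diam == 0) diam <- 1
  per_pair <- c()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      di <- dirs[i, ]; dj <- dirs[j, ]
      den <- di[1] * dj[2] - di[2] * dj[1]
      rhs <- image$a[j, ] - image$a[i, ]
      if (abs(den) < 1e-300) {
        per_pair <- c(per_pair, 90)
        next
      }
      t_i <- (rhs[1] * dj[2] - rhs[2] * dj[1]) / den
      v <- image$a[i, ] + t_i * di
      if (sqrt(sum(v^2)) > parallel_factor * diam) {
        per_pair <- c(per_pair, 90)
      } else {
        per_pair <- c(per_pair, atan(sqrt(sum(v^2)) / d) * 180 / pi)
      }
    }
  }
  slant_estimate(stats::median(per_pair), estimator = "persp",
                 diagnostics = list(per_pair_deg = per_pair,
                                    spread_deg = stats::IQR(per_pair)))
}

#' All four slant estimates for one trial
#'
#' Convenience wrapper running the compactness selectors and (when a
#' secondary plane is available) the two-plane selector on the corrected
#' image(s), plus the vanishing-point estimator on the uncorrected image.
#'
#' @param image the (noisy) `pair_image` of the primary plane
#' @param corrected its corrected version (computed if missing)
#' @param fam2 optional `family_grid` of the secondary plane's corrected
#'   image
#' @param shared optional shared-vertex index map for the two-plane loss
#' @param grid_args list of arguments passed to [family_grid()]
#' @return list with elements `v2s3`, `s3v`, `sym2` (NA-valued estimate if
#'   no secondary plane), `persp` (each a `slant_estimate`) and
#'   `gamma_deg`
#' @export
trial_slant_estimates <- function(image, corrected = NULL, fam2 = NULL,
                                  shared = NULL, grid_args = list()) {
  if (is.null(corrected)) corrected <- correct_to_orthographic(image)
  fam1 <- do.call(family_grid, c(list(corrected), grid_args))
  est_c1 <- select_slant_compactness(fam1, "c1")
  est_c2 <- select_slant_compactness(fam1, "c2")
  est_sym2 <- if (!is.null(fam2) && !is.null(shared))
    select_slant_two_planes(fam1, fam2, shared)
  else slant_estimate(NA_real_, "sym2")
  est_persp <- vanishing_point_slant(image)
  list(v2s3 = est_c1, s3v = est_c2, sym2 = est_sym2, persp = est_persp,
       gamma_deg = angular_size(image))
}
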
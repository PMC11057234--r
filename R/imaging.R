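# Projection of posed symmetric objects into pair images, the 1-degree
# segment-orientation noise model, angular size, and the least-squares
# correction that turns any pair image into a valid orthographic image of
# a mirror-symmetric shape (all symmetry segments parallel).

#' Camera model
#'
#' The center of projection sits at the origin looking along +z. Under
#' perspective projection a point (x, y, z) maps to (d x / z, d y / z) on
#' the picture plane z = d; under orthographic projection it maps to
#' (x, y). Distances are in the scene's length unit (the experimental
#' geometry used cm, with d = 50.8 cm = 20 inches).
#'
#' @param projection "orthographic" or "perspective"
#' @param distance viewing distance d > 0 (used by perspective projection
#'   and by angular-size computations)
#' @return a list of class `camera`
#' @export
camera <- function(projection = c("orthographic", "perspective"),
                   distance = 50.8) {
  projection <- match.arg(projection)
  if (distance <= 0) stop("viewing distance must be positive")
  structure(list(projection = projection, distance = distance),
            class = "camera")
}

#' Pair image of a posed symmetric object
#'
#' Projects the endpoints of every mirror pair of the correspondence set.
#' All vertices are projected (transparent-object convention, no
#' occlusion). Endpoint order is made consistent across pairs: the first
#' endpoint of every pair lies on the negative side of the posed symmetry
#' plane, so every segment's a-to-b direction crosses the plane the same
#' way. Under orthographic projection of a truly symmetric object all
#' segments are parallel; perspective projection breaks that parallelism.
#'
#' @param mesh a `mesh3` in object coordinates
#' @param correspondences a `correspondence_set` on `mesh` (its plane is
#'   interpreted in object coordinates and is posed along with the mesh)
#' @param pose a `rigid_pose` taking object to camera coordinates
#' @param cam a `camera`
#' @return a list of class `pair_image`: `a`, `b` (m x 2 endpoint
#'   matrices), `camera`, and `meta` (posed true slant/tilt of the
#'   symmetry plane)
#' @export
project_pairs <- function(mesh, correspondences, pose, cam) {
  stopifnot(inherits(cam, "camera"),
            inherits(correspondences, "correspondence_set"))
  posed <- apply_pose(mesh, pose)
  pts <- posed$vertices
  pl <- correspondences$plane
  n_cam <- as.numeric(pose$rotation %*% pl$normal)
  c_cam <- pl$offset + sum(n_cam * pose$translation)
  posed_plane <- symmetry_plane(n_cam, c_cam)
  pairs <- correspondences$pairs
  if (nrow(pairs) == 0) stop("empty correspondence set")
  side <- (pts %*% posed_plane$normal)[, 1] - posed_plane$offset
  ai <- ifelse(side[pairs[, 1]] <= side[pairs[, 2]], pairs[, 1], pairs[, 2])
  bi <- ifelse(side[pairs[, 1]] <= side[pairs[, 2]], pairs[, 2], pairs[, 1])
  proj <- function(p) {
    out <- if (cam$projection == "orthographic") p[, 1:2, drop = FALSE]
    else {
      if (any(p[, 3] <= 0))
        stop("vertex at or behind the center of projection")
      cam$distance * p[, 1:2, drop = FALSE] / p[, 3]
    }
    dimnames(out) <- NULL
    out
  }
  st <- plane_slant_tilt(posed_plane)
  structure(list(a = proj(pts[ai, , drop = FALSE]),
                 b = proj(pts[bi, , drop = FALSE]),
                 camera = cam,
                 meta = list(slant_deg = st$slant_deg,
                             tilt_deg = st$tilt_deg)),
            class = "pair_image")
}

#' @export
print.pair_image <- function(x, ...) {
  cat(sprintf("pair_image: %d pairs, %s projection, gamma %.2f deg\n",
              nrow(x$a), x$camera$projection, angular_size(x)))
  invisible(x)
}

segment_lengths <- function(image) sqrt(rowSums((image$b - image$a)^2))

#' Perturb segment orientations (image noise model)
#'
#' Rotates each symmetry segment about its own midpoint by an independent
#' draw from Normal(0, sd_deg); segment lengths and midpoints are
#' unchanged. The default 1 degree matches known orientation-discrimination
#' thresholds; the model sees only the noisy image.
#'
#' @param image a `pair_image`
#' @param sd_deg noise standard deviation in degrees
#' @param seed integer seed
#' @return a `pair_image`
#' @export
perturb_orientations <- function(image, sd_deg = 1.0, seed = 1L) {
  stopifnot(sd_deg >= 0)
  if (sd_deg == 0) return(image)
  m <- nrow(image$a)
  with_seed(seed, {
    ang <- stats::rnorm(m, 0, sd_deg) * pi / 180
    mid <- (image$a + image$b) / 2
    rot2 <- function(p) {
      rel <- p - mid
      cbind(cos(ang) * rel[, 1] - sin(ang) * rel[, 2],
            sin(ang) * rel[, 1] + cos(ang) * rel[, 2]) + mid
    }
    image$a <- rot2(image$a)
    image$b <- rot2(image$b)
    image
  })
}

# Minimal enclosing circle of 2D points (Welzl). Point count per image is
# small (tens), so the simple recursive form is adequate.
min_enclosing_circle <- function(pts) {
  circ2 <- function(p, q) {
    c_ <- (p + q) / 2
    list(c = c_, r = sqrt(sum((p - c_)^2)))
  }
  circ3 <- function(p, q, r) {
    ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-14) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c_ <- c(ux, uy)
    list(c = c_, r = sqrt(sum((p - c_)^2)))
  }
  inside <- function(circ, p) sqrt(sum((p - circ$c)^2)) <= circ$r * (1 + 1e-12)
  n <- nrow(pts)
  if (n == 0) return(list(c = c(0, 0), r = 0))
  if (n == 1) return(list(c = pts[1, ], r = 0))
  circ <- circ2(pts[1, ], pts[2, ])
  for (i in seq_len(n)) {
    if (inside(circ, pts[i, ])) next
    circ <- list(c = pts[i, ], r = 0)
    for (j in seq_len(i - 1L)) {
      if (inside(circ, pts[j, ])) next
      circ <- circ2(pts[i, ], pts[j, ])
      for (k in seq_len(j - 1L)) {
        if (inside(circ, pts[k, ])) next
        cc <- circ3(pts[i, ], pts[j, ], pts[k, ])
        if (!is.null(cc)) circ <- cc
      }
    }
  }
  circ
}

#' Angular size of a pair image
#'
#' gamma = 2 atan(r / d) where r is the radius of the smallest circle
#' enclosing all endpoints on the picture plane and d the viewing
#' distance. This is the reliability signal for perspective information in
#' the cue-combination model (the experiment's perspective images spanned
#' about 20 degrees, orthographic about 7).
#'
#' @param image a `pair_image` or `corrected_pair_image`
#' @return angular size in degrees
#' @export
angular_size <- function(image) {
  pts <- rbind(image$a, image$b)
  if (nrow(pts) == 0) return(0)
  circ <- min_enclosing_circle(pts)
  2 * atan(circ$r / image$camera$distance) * 180 / pi
}

#' Correct a pair image to a valid orthographic image
#'
#' A noiseless orthographic image of a mirror-symmetric shape has all
#' symmetry segments parallel; noise and perspective break this. The
#' correction finds the common unit direction u minimizing
#' sum_i || (b_i - a_i) - L_i u ||^2 (closed form: u is the normalized sum
#' of the segment vectors) and rotates each segment about its own midpoint
#' onto u, preserving lengths and midpoints. Only after this step is the
#' one-parameter family of 3D interpretations defined.
#'
#' @param image a `pair_image`
#' @return a `corrected_pair_image`: endpoint matrices `a`, `b`, common
#'   direction `u`, `tilt_deg`, the `camera`, and `meta` carried over
#' @export
correct_to_orthographic <- function(image) {
  d <- image$b - image$a
  len <- sqrt(rowSums(d^2))
  if (all(len == 0)) stop("all segments are zero length")
  u <- colSums(d)
  un <- sqrt(sum(u^2))
  if (un == 0) stop("segment directions cancel; no common direction")
  u <- u / un
  mid <- (image$a + image$b) / 2
  half <- outer(len / 2, u)
  structure(list(a = mid - half, b = mid + half, u = u,
                 tilt_deg = (atan2(u[2], u[1]) * 180 / pi) %% 360,
                 camera = image$camera, meta = image$meta),
            class = c("corrected_pair_image", "pair_image"))
}

#' @export
print.corrected_pair_image <- function(x, ...) {
  cat(sprintf("corrected_pair_image: %d pairs, tilt %.2f deg\n",
              nrow(x$a), x$tilt_deg))
  invisible(x)
}

#' Perspective image of rotated frontoparallel rectangles
#'
#' The textbook construction for the vanishing-point estimator: rectangles
#' of equal height start in a plane parallel to the picture plane (their
#' vertical sides, read as symmetry segments, then imply a symmetry plane
#' at slant 90). Rotating them by `rot_deg` about their common horizontal
#' bottom edge slants that plane to 90 - `rot_deg` degrees; the rotation
#' default 75 gives slant 15.
#'
#' @param rot_deg rotation about the bottom edge, degrees in (0, 90)
#' @param distance viewing distance to the bottom edge
#' @param height common rectangle height
#' @param xs left-side x positions of the rectangles
#' @param widths rectangle widths
#' @param y_bottom y position of the shared bottom edge
#' @return a `pair_image` (perspective) whose pairs are the rectangles'
#'   vertical sides, bottom endpoint first
#' @export
rotated_rectangles_image <- function(rot_deg = 75, distance = 50.8,
                                     height = 8,
                                     xs = c(-12, -5, 3, 10),
                                     widths = c(3, 4, 5, 3.5),
                                     y_bottom = -4) {
  stopifnot(rot_deg > 0, rot_deg < 90, length(xs) == length(widths))
  rot <- rot_deg * pi / 180
  side_x <- unlist(mapply(function(x, w) c(x, x + w), xs, widths,
                          SIMPLIFY = FALSE))
  bot <- cbind(side_x, y_bottom, distance)
  top <- cbind(side_x, y_bottom + height * cos(rot),
               distance + height * sin(rot))
  proj <- function(p) distance * p[, 1:2, drop = FALSE] / p[, 3]
  structure(list(a = proj(bot), b = proj(top),
                 camera = camera("perspective", distance),
                 meta = list(slant_deg = 90 - rot_deg)),
            class = "pair_image")
}

#' Serialize / read a pair image as JSON
#'
#' Schema: projection, viewing_distance, pairs = [[[ax, ay], [bx, by]],
#' ...], meta.
#'
#' @param image a `pair_image`
#' @param path output file
#' @return `path` invisibly; `read_pair_image` returns a `pair_image`
#' @export
write_pair_image <- function(image, path) {
  obj <- list(projection = image$camera$projection,
              viewing_distance = image$camera$distance,
              pairs = lapply(seq_len(nrow(image$a)), function(i)
                list(as.numeric(image$a[i, ]), as.numeric(image$b[i, ]))),
              meta = image$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pair_image
#' @export
read_pair_image <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- obj$pairs
  a <- t(vapply(seq_len(dim(pairs)[1]), function(i) pairs[i, 1, ],
                numeric(2)))
  b <- t(vapply(seq_len(dim(pairs)[1]), function(i) pairs[i, 2, ],
                numeric(2)))
  structure(list(a = a, b = b,
                 camera = camera(obj$projection, obj$viewing_distance),
                 meta = obj$meta),
            class = "pair_image")
}
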
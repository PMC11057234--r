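# Seeded generation of the two synthetic stimulus classes: random
# mirror-symmetric polyhedra (two appended box-like parts, no right angles
# on any face) and rectangular mirror-symmetric polyhedra (two appended
# rectangular prisms). Both are exactly symmetric about the YZ plane by
# construction: every vertex (x, y, z) has a mirror twin (-x, y, z).

#' Stimulus generation parameters
#'
#' Cross-section edge lengths (depths and heights of the two box-like
#' parts) and box widths are drawn uniformly from the same configured
#' ranges in both stimulus classes, so the two classes share their edge
#' length distribution. The second box is shrunk by a relative size ratio
#' drawn from `size_ratio_range`, making the relative sizes of the two
#' parts vary over a wide range.
#'
#' @param edge_range length-2: bounds of the uniform cross-section edge
#'   length distribution (arbitrary length units)
#' @param width_range length-2: bounds of the uniform box width
#'   distribution
#' @param size_ratio_range length-2 in (0, 1]: relative size of the second
#'   box
#' @param max_aspect maximum allowed aspect ratio of an emitted object
#' @param angle_margin_deg soft margin: at most `angle_soft_frac` of a
#'   random polyhedron's face angles may lie within this margin of 90
#'   degrees
#' @param angle_hard_margin_deg hard margin: no face angle of a random
#'   polyhedron may lie within this margin of 90 degrees
#' @param angle_soft_frac maximum fraction of face angles inside the soft
#'   margin
#' @param max_resample rejection-sampling budget per object
#' @return a list of class `stimulus_params`
#' @export
stimulus_params <- function(edge_range = c(1, 4),
                            width_range = c(1, 4),
                            size_ratio_range = c(0.3, 1.0),
                            max_aspect = 9,
                            angle_margin_deg = 5,
                            angle_hard_margin_deg = 0.5,
                            angle_soft_frac = 0.05,
                            max_resample = 10000L) {
  stopifnot(edge_range[1] > 0, edge_range[2] >= edge_range[1],
            width_range[1] > 0, width_range[2] >= width_range[1],
            size_ratio_range[1] > 0, size_ratio_range[2] <= 1,
            max_aspect >= 1)
  structure(list(edge_range = edge_range, width_range = width_range,
                 size_ratio_range = size_ratio_range,
                 max_aspect = max_aspect,
                 angle_margin_deg = angle_margin_deg,
                 angle_hard_margin_deg = angle_hard_margin_deg,
                 angle_soft_frac = angle_soft_frac,
                 max_resample = as.integer(max_resample)),
            class = "stimulus_params")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

# Build one box-like part from a 4-corner cross-section in the symmetry
# plane (columns y, z; cyclic order bottom-near, bottom-far, top-far,
# top-near) and one width per corner. Returns 8 vertices and 6 faces
# oriented outward.
box_from_cross_section <- function(cs, widths) {
  v <- rbind(cbind(widths / 2, cs), cbind(-widths / 2, cs))
  faces <- list(c(1, 2, 3, 4), c(8, 7, 6, 5),
                c(1, 5, 6, 2), c(2, 6, 7, 3),
                c(3, 7, 8, 4), c(4, 8, 5, 1))
  m <- mesh3(v, faces)
  tri <- triangulate_faces(m)
  signed <- sum(rowSums(m$vertices[tri[, 1], , drop = FALSE] *
                          vec_cross(m$vertices[tri[, 2], , drop = FALSE],
                                    m$vertices[tri[, 3], , drop = FALSE]))) / 6
  if (signed < 0) m$faces <- lapply(m$faces, rev)
  m
}

merge_meshes <- function(a, b) {
  off <- nrow(a$vertices)
  mesh3(rbind(a$vertices, b$vertices),
        c(a$faces, lapply(b$faces, function(f) f + off)))
}

quad_angles_2d <- function(q) {
  # q: 4 x 2 cyclic corners; interior angles in degrees
  vapply(1:4, function(i) {
    p <- q[i, ]
    e1 <- q[ifelse(i == 1, 4, i - 1), ] - p
    e2 <- q[ifelse(i == 4, 1, i + 1), ] - p
    acos(pmin(1, pmax(-1, sum(e1 * e2) /
                        sqrt(sum(e1^2) * sum(e2^2))))) * 180 / pi
  }, numeric(1))
}

quad_convex_2d <- function(q) {
  crs <- vapply(1:4, function(i) {
    a <- q[i, ]; b <- q[ifelse(i == 4, 1, i + 1), ]
    c_ <- q[ifelse(i >= 3, i - 2, i + 2), ]
    (b[1] - a[1]) * (c_[2] - b[2]) - (b[2] - a[2]) * (c_[1] - b[1])
  }, numeric(1))
  all(crs > 0) || all(crs < 0)
}

# Sample a convex cross-section quadrilateral for one box of a random
# polyhedron. Bottom corners sit on y = 0 (coplanar bottoms across boxes).
# The side edges' deviation from vertical is drawn directly as an angle
# well clear of 0 (so no bottom angle can come near 90 degrees), the two
# inward leans jointly capped at 0.6 x depth so the quad stays box-like;
# the side adjacent to the
# abutting plane leans inward only, so the two parts touch but do not
# interpenetrate.
sample_cross_section <- function(params, scale, z_lo, depth, abut) {
  y3 <- runif1(params$edge_range) * scale
  y4 <- runif1(params$edge_range) * scale
  lean <- function(y, inward_only) {
    ang <- stats::runif(1, params$angle_margin_deg + 1, 18) * pi / 180
    sgn <- if (inward_only) 1 else sample(c(-1, 1), 1)
    sgn * y * tan(ang)
  }
  d3 <- lean(y3, abut == "far")   # far edge abuts the join plane
  d4 <- lean(y4, abut == "near")  # near edge abuts the join plane
  if (max(d3, 0) + max(d4, 0) > 0.6 * depth) return(NULL)
  rbind(c(0, z_lo),
        c(0, z_lo + depth),
        c(y3, z_lo + depth - d3),
        c(y4, z_lo + d4))
}

# Width of corner 4 forced by planarity of the side face through corners
# 1..3 (points (w_i/2, y_i, z_i) must be coplanar). Returns NA when the
# plane is parallel to the x axis.
solve_planar_width <- function(cs, w123) {
  p <- cbind(w123 / 2, cs[1:3, , drop = FALSE])
  n <- vec_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])[1, ]
  if (abs(n[1]) < 1e-12) return(NA_real_)
  w4_half <- p[1, 1] - (n[2] * (cs[4, 1] - p[1, 2]) +
                          n[3] * (cs[4, 2] - p[1, 3])) / n[1]
  2 * w4_half
}

planar_quad_ok <- function(pts) {
  # convex, non-self-intersecting planar quad (projected onto its plane)
  n <- vec_cross(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])[1, ]
  nn <- sqrt(sum(n^2))
  if (nn == 0) return(FALSE)
  n <- n / nn
  e1 <- pts[2, ] - pts[1, ]; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- vec_cross(n, e1)[1, ]
  q <- cbind((pts %*% e1)[, 1], (pts %*% e2)[, 1])
  quad_convex_2d(q)
}

#' Generate one random mirror-symmetric polyhedron
#'
#' The object is two appended box-like parts whose bottom faces are
#' coplanar (y = 0) and which abut along the plane z = depth of the first
#' part. Each part is an extrusion of a convex cross-section quadrilateral
#' lying in the symmetry (YZ) plane, with an independent width at three of
#' its four corners; the fourth width is solved from the planarity of the
#' side faces, and the draw is rejected if the solved width is negative,
#' exceeds three times the largest sampled width, or yields a
#' self-intersecting side face. Emitted objects have no face angle within
#' `angle_hard_margin_deg` of 90 degrees, at most `angle_soft_frac` of
#' angles within `angle_margin_deg` of 90 degrees, and aspect ratio at most
#' `max_aspect`.
#'
#' @param params a `stimulus_params`
#' @param seed integer seed; the same seed reproduces the same mesh
#' @return a `mesh3`, exactly symmetric about the YZ plane
#' @export
generate_random_polyhedron <- function(params = stimulus_params(),
                                       seed = 1L) {
  stopifnot(inherits(params, "stimulus_params"))
  with_seed(seed, {
    last_violation <- "none"
    for (attempt in seq_len(params$max_resample)) {
      r <- runif1(params$size_ratio_range)
      c1 <- runif1(params$edge_range)
      c2 <- runif1(params$edge_range) * r
      cs1 <- sample_cross_section(params, 1, 0, c1, abut = "far")
      cs2 <- sample_cross_section(params, r, c1, c2, abut = "near")
      q_ok <- function(cs) {
        !is.null(cs) && quad_convex_2d(cs[, 2:1]) &&
          all(abs(quad_angles_2d(cs[, 2:1]) - 90) >
                params$angle_margin_deg)
      }
      if (!q_ok(cs1) || !q_ok(cs2)) {
        last_violation <- "cross-section quadrilateral shape"
        next
      }
      # widths are resampled on their own (the cross-section is kept) when
      # the planarity-forced fourth width is too large or self-intersecting
      make_part <- function(cs, scale) {
        for (wt in 1:20) {
          w123 <- c(runif1(params$width_range), runif1(params$width_range),
                    runif1(params$width_range)) * scale
          w4 <- solve_planar_width(cs, w123)
          if (!is.finite(w4) || w4 <= 0 || w4 > 3 * max(w123)) next
          widths <- c(w123, w4)
          side <- cbind(widths / 2, cs)
          if (!planar_quad_ok(side)) next
          return(box_from_cross_section(cs, widths))
        }
        NULL
      }
      b1 <- make_part(cs1, 1)
      b2 <- make_part(cs2, r)
      if (is.null(b1) || is.null(b2)) {
        last_violation <- "planarity-forced fourth width"
        next
      }
      m <- merge_meshes(b1, b2)
      ang <- face_angles(m)
      dev <- abs(ang - 90)
      if (any(dev <= params$angle_hard_margin_deg)) {
        last_violation <- "face angle too close to 90 degrees"
        next
      }
      if (mean(dev <= params$angle_margin_deg) > params$angle_soft_frac) {
        last_violation <- "too many face angles near 90 degrees"
        next
      }
      ar <- tryCatch(aspect_ratio(m), error = function(e) Inf)
      if (ar > params$max_aspect) {
        last_violation <- "aspect ratio"
        next
      }
      return(m)
    }
    stop("rejection budget exceeded; last violated constraint: ",
         last_violation)
  })
}

#' Generate one rectangular mirror-symmetric polyhedron
#'
#' Two appended axis-aligned rectangular prisms with coplanar bottom faces
#' (y = 0), abutting along a shared vertical face region, mirror-symmetric
#' about the YZ plane. Edge lengths and widths are drawn from the same
#' distributions as in [generate_random_polyhedron()]; every face angle is
#' exactly 90 degrees and the aspect ratio never exceeds `max_aspect`.
#'
#' @inheritParams generate_random_polyhedron
#' @return a `mesh3`
#' @export
generate_rectangular_polyhedron <- function(params = stimulus_params(),
                                            seed = 1L) {
  stopifnot(inherits(params, "stimulus_params"))
  with_seed(seed, {
    for (attempt in seq_len(params$max_resample)) {
      r <- runif1(params$size_ratio_range)
      c1 <- runif1(params$edge_range)
      h1 <- runif1(params$edge_range)
      w1 <- runif1(params$width_range)
      c2 <- runif1(params$edge_range) * r
      h2 <- runif1(params$edge_range) * r
      w2 <- runif1(params$width_range) * r
      rect_cs <- function(z_lo, depth, h) {
        rbind(c(0, z_lo), c(0, z_lo + depth),
              c(h, z_lo + depth), c(h, z_lo))
      }
      b1 <- box_from_cross_section(rect_cs(0, c1, h1), rep(w1, 4))
      b2 <- box_from_cross_section(rect_cs(c1, c2, h2), rep(w2, 4))
      m <- merge_meshes(b1, b2)
      ar <- aspect_ratio(m)
      if (ar <= params$max_aspect) return(m)
    }
    stop("rejection budget exceeded; last violated constraint: aspect ratio")
  })
}

#' Viewing orientation of one trial
#'
#' Slant is the angle between the symmetry-plane normal and the camera's
#' line of sight, restricted to the experimental set {15, 30, 45, 60, 75}
#' degrees; tilt is the image-plane orientation of the projected normal,
#' with tilt mod 90 restricted to [15, 75] degrees.
#'
#' @param slant_deg one of 15, 30, 45, 60, 75
#' @param tilt_deg tilt in degrees with (tilt mod 90) in [15, 75]
#' @param spin_deg rotation of the object about its symmetry-plane normal
#'   before slant/tilt posing; it does not change the primary plane's
#'   slant or tilt but completes the 3 orientation degrees of freedom
#' @return a list of class `view_spec`
#' @export
view_spec <- function(slant_deg, tilt_deg, spin_deg = 0) {
  if (!slant_deg %in% c(15, 30, 45, 60, 75))
    stop("slant must be one of 15, 30, 45, 60, 75 degrees")
  tm <- tilt_deg %% 90
  if (tm < 15 - 1e-9 || tm > 75 + 1e-9)
    stop("tilt mod 90 must lie in [15, 75] degrees")
  structure(list(slant_deg = slant_deg, tilt_deg = tilt_deg,
                 spin_deg = spin_deg),
            class = "view_spec")
}

#' Sample a random trial orientation
#' @param seed integer seed
#' @param slant_deg optionally fix the slant; otherwise drawn uniformly
#'   from the experimental set
#' @return a `view_spec`
#' @export
sample_view <- function(seed = 1L, slant_deg = NULL) {
  with_seed(seed, {
    s <- if (is.null(slant_deg)) sample(c(15, 30, 45, 60, 75), 1)
         else slant_deg
    tilt <- stats::runif(1, 15, 75) + 90 * sample(0:3, 1)
    view_spec(s, tilt, spin_deg = stats::runif(1, 0, 360))
  })
}

rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  rbind(c(ca, 0, sa), c(0, 1, 0), c(-sa, 0, ca))
}

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1))
}

#' Rigid pose realizing a viewing orientation
#'
#' Rotates the object so that its symmetry-plane normal (the +x axis of the
#' construction frame) makes the view's slant angle with the camera axis
#' (+z) and projects into the image plane at the view's tilt orientation,
#' then translates the object to `distance` along the camera axis.
#'
#' @param view a `view_spec`
#' @param distance camera-axis translation (viewing distance for
#'   perspective projection; irrelevant under orthographic projection)
#' @param center optionally, a length-3 point of the object subtracted
#'   before rotation so the object is centered on the optical axis
#' @return a `rigid_pose`
#' @export
view_pose <- function(view, distance = 0, center = c(0, 0, 0)) {
  stopifnot(inherits(view, "view_spec"))
  sig <- view$slant_deg * pi / 180
  tau <- view$tilt_deg * pi / 180
  psi <- (if (is.null(view$spin_deg)) 0 else view$spin_deg) * pi / 180
  rot_x <- rbind(c(1, 0, 0),
                 c(0, cos(psi), -sin(psi)),
                 c(0, sin(psi), cos(psi)))
  R <- rot_z(tau) %*% rot_y(sig - pi / 2) %*% rot_x
  t <- c(0, 0, distance) - as.numeric(R %*% as.numeric(center))
  rigid_pose(R, t)
}

#' Generate a full set of trials for one condition
#'
#' `n_per_slant` trials at each slant in {15, 30, 45, 60, 75} degrees
#' (the experiment used 20, i.e. 100 trials per condition). One global seed
#' drives a per-trial seed sequence (`seed + trial index`) so any single
#' trial is reproducible in isolation.
#'
#' @param n_per_slant trials per slant level
#' @param type "random" or "rectangular"
#' @param params a `stimulus_params`
#' @param seed global integer seed
#' @return list with `trials` (list of lists with elements `mesh`, `view`)
#'   and `manifest` (data.frame: trial_id, object_type, seed, slant_deg,
#'   tilt_deg)
#' @export
generate_condition_set <- function(n_per_slant = 20L,
                                   type = c("random", "rectangular"),
                                   params = stimulus_params(),
                                   seed = 1L) {
  type <- match.arg(type)
  stopifnot(n_per_slant >= 1)
  gen <- switch(type, random = generate_random_polyhedron,
                rectangular = generate_rectangular_polyhedron)
  slants <- rep(c(15, 30, 45, 60, 75), each = n_per_slant)
  trials <- vector("list", length(slants))
  man <- data.frame(trial_id = seq_along(slants),
                    object_type = type,
                    seed = seed + seq_along(slants),
                    slant_deg = slants,
                    tilt_deg = NA_real_)
  for (i in seq_along(slants)) {
    si <- seed + i
    mesh <- gen(params, seed = si)
    view <- sample_view(seed = si, slant_deg = slants[i])
    trials[[i]] <- list(mesh = mesh, view = view)
    man$tilt_deg[i] <- view$tilt_deg
  }
  list(trials = trials, manifest = man)
}
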
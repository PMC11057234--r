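#' Construct a triangle/polygon mesh
#'
#' A mesh is the carrier of all 3D shape computations in this package:
#' volume, surface area, convex hull, aspect ratio, symmetry detection and
#' projection all consume it. Vertices live in a right-handed coordinate
#' system in which the Z-axis is depth (the camera's line of sight), the
#' X-axis is horizontal and the Y-axis is vertical.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z), one row per
#'   vertex. All coordinates must be finite.
#' @param faces list of integer vectors, each of length >= 3, giving
#'   1-based vertex indices into `vertices` (R convention; file
#'   readers/writers translate to each format's convention).
#' @return an object of class `mesh3`, a list with elements `vertices`
#'   (numeric matrix) and `faces` (list of integer vectors).
#' @examples
#' m <- unit_cube()
#' mesh_volume(m)       # 1
#' mesh_surface_area(m) # 6
#' @export
mesh3 <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L)
    stop("vertices must be an n x 3 matrix")
  storage.mode(vertices) <- "double"
  if (!all(is.finite(vertices)))
    stop("vertex coordinates must be finite")
  dimnames(vertices) <- NULL
  faces <- lapply(faces, function(f) {
    f <- as.integer(f)
    if (length(f) < 3L) stop("each face needs >= 3 vertices")
    if (any(f < 1L) || any(f > nrow(vertices)))
      stop("face index out of range")
    f
  })
  structure(list(vertices = vertices, faces = faces), class = "mesh3")
}

#' @export
print.mesh3 <- function(x, ...) {
  cat(sprintf("mesh3: %d vertices, %d faces, diameter %.4g\n",
              nrow(x$vertices), length(x$faces), mesh_diameter(x)))
  invisible(x)
}

#' Axis-aligned unit cube on [0,1]^3 (test and example fixture)
#' @return a `mesh3` with 8 vertices and 6 quad faces
#' @export
unit_cube <- function() box_mesh(c(1, 1, 1))

#' Axis-aligned box mesh with one corner at the origin
#' @param dims numeric length-3: extents along x, y, z
#' @param origin numeric length-3 corner position
#' @return a `mesh3` with quad faces, outward-oriented
#' @export
box_mesh <- function(dims, origin = c(0, 0, 0)) {
  d <- as.numeric(dims)
  v <- as.matrix(expand.grid(x = c(0, d[1]), y = c(0, d[2]), z = c(0, d[3])))
  v <- sweep(v, 2, as.numeric(origin), `+`)
  # vertex order from expand.grid: index = 1 + x + 2y + 4z (bits)
  f <- list(
    c(1, 3, 4, 2), # z = 0, normal -z
    c(5, 6, 8, 7), # z = d3, normal +z
    c(1, 2, 6, 5), # y = 0, normal -y
    c(3, 7, 8, 4), # y = d2, normal +y
    c(1, 5, 7, 3), # x = 0, normal -x
    c(2, 4, 8, 6)  # x = d1, normal +x
  )
  mesh3(v, f)
}

mesh_diameter <- function(mesh) {
  rng <- apply(mesh$vertices, 2, range)
  sqrt(sum((rng[2, ] - rng[1, ])^2))
}

face_vertex_rows <- function(mesh, f) mesh$vertices[f, , drop = FALSE]

# fan triangulation of one polygonal face -> k x 3 index matrix
fan_triangles <- function(f) {
  k <- length(f) - 2L
  cbind(rep.int(f[1L], k), f[2:(k + 1L)], f[3:(k + 2L)])
}

triangulate_faces <- function(mesh) {
  do.call(rbind, lapply(mesh$faces, fan_triangles))
}

#' Enclosed volume of a watertight mesh
#'
#' Signed sum of tetrahedra spanned by the origin and each (fan-triangulated)
#' face. Orientation is fixed up internally so the result is positive for
#' any consistently oriented closed mesh; meshes made of several closed
#' components (e.g. two appended boxes sharing a face) sum their component
#' volumes. The watertightness check requires every edge to be used by an
#' even number of face sides.
#'
#' @param mesh a `mesh3`
#' @return volume in cubic length units
#' @export
mesh_volume <- function(mesh) {
  if (!is_watertight(mesh))
    stop("mesh is not watertight (open edges); volume undefined")
  tri <- triangulate_faces(mesh)
  v <- mesh$vertices
  a <- v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 2], , drop = FALSE]
  c_ <- v[tri[, 3], , drop = FALSE]
  signed <- rowSums(a * vec_cross(b, c_)) / 6
  abs(sum(signed))
}

is_watertight <- function(mesh) {
  edges <- do.call(rbind, lapply(mesh$faces, function(f) {
    nf <- length(f)
    cbind(f, f[c(2:nf, 1L)])
  }))
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  all(table(key) %% 2L == 0L)
}

vec_cross <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1)
  if (is.null(dim(b))) b <- matrix(b, 1)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Total surface area of a mesh
#'
#' Sum of face areas with planar polygon faces fan-triangulated. A
#' degenerate (zero-area) face contributes 0 with a warning.
#'
#' @param mesh a `mesh3`
#' @return area in squared length units
#' @export
mesh_surface_area <- function(mesh) {
  tri <- triangulate_faces(mesh)
  v <- mesh$vertices
  cr <- vec_cross(v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE],
                  v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE])
  areas <- sqrt(rowSums(cr^2)) / 2
  # report per original face, not per fan triangle
  per_face <- vapply(mesh$faces, function(f) {
    t2 <- fan_triangles(f)
    c2 <- vec_cross(v[t2[, 2], , drop = FALSE] - v[t2[, 1], , drop = FALSE],
                    v[t2[, 3], , drop = FALSE] - v[t2[, 1], , drop = FALSE])
    sum(sqrt(rowSums(c2^2)) / 2)
  }, numeric(1))
  if (any(per_face == 0))
    warning("degenerate zero-area face contributes 0 to surface area")
  sum(areas)
}

#' Convex hull of a 3D point set
#'
#' Incremental hull: seeded with an extreme tetrahedron, each remaining
#' point outside the current hull deletes its visible faces and is stitched
#' to the horizon. Used by the compactness constraints, which score shapes
#' by hull volume and area because part volume of thin structures is
#' unreliable.
#'
#' @param points numeric n x 3 matrix (or a `mesh3`, whose vertices are
#'   used), n >= 4, not all coplanar
#' @param tol relative tolerance for the visibility predicate, scaled by
#'   the point-cloud diameter
#' @return a watertight triangle `mesh3` whose vertices are the hull
#'   vertices (a subset of the input points)
#' @export
convex_hull <- function(points, tol = 1e-10) {
  if (inherits(points, "mesh3")) points <- points$vertices
  pts <- as.matrix(points)
  if (ncol(pts) != 3L) stop("points must be n x 3")
  n <- nrow(pts)
  if (n < 4L) stop("convex hull needs >= 4 points")
  diam <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
  if (diam == 0) stop("degenerate hull: all points coincide")
  eps <- tol * diam

  # seed tetrahedron from extreme points
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (isTRUE(all.equal(pts[i1, ], pts[i2, ]))) {
    i2 <- which.max(rowSums(sweep(pts, 2, pts[i1, ])^2))
  }
  d12 <- pts[i2, ] - pts[i1, ]
  # farthest from line i1-i2
  rel <- sweep(pts, 2, pts[i1, ])
  crs <- vec_cross(rel, matrix(d12, n, 3, byrow = TRUE))
  i3 <- which.max(rowSums(crs^2))
  nrm <- vec_cross(pts[i3, ] - pts[i1, ], d12)[1, ]
  if (sqrt(sum(nrm^2)) <= eps * sqrt(sum(d12^2)))
    stop("degenerate hull: points are collinear")
  dist4 <- abs(rel %*% (nrm / sqrt(sum(nrm^2))))
  i4 <- which.max(dist4)
  if (dist4[i4] <= eps) stop("degenerate hull: points are coplanar")

  # faces as a matrix of vertex-index triples, outward-oriented w.r.t. the
  # seed centroid; unit normals and base offsets cached per face so the
  # visibility test for each inserted point is a single matrix product
  centroid <- colMeans(pts[c(i1, i2, i3, i4), ])
  orient <- function(tri) {
    a <- pts[tri[1], ]; b <- pts[tri[2], ]; c_ <- pts[tri[3], ]
    nn <- vec_cross(b - a, c_ - a)[1, ]
    if (sum(nn * (centroid - a)) > 0) tri[c(1, 3, 2)] else tri
  }
  faces <- rbind(orient(c(i1, i2, i3)), orient(c(i1, i2, i4)),
                 orient(c(i1, i3, i4)), orient(c(i2, i3, i4)))
  face_geometry <- function(tris) {
    a <- pts[tris[, 1], , drop = FALSE]
    nn <- vec_cross(pts[tris[, 2], , drop = FALSE] - a,
                    pts[tris[, 3], , drop = FALSE] - a)
    nn <- nn / sqrt(rowSums(nn^2))
    list(normals = nn, offsets = rowSums(nn * a))
  }
  geom <- face_geometry(faces)

  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in remaining) {
    vis <- (geom$normals %*% pts[p, ])[, 1] - geom$offsets > eps
    if (!any(vis)) next
    # horizon: edges of visible faces not shared with another visible face
    vis_faces <- faces[vis, , drop = FALSE]
    edges <- rbind(vis_faces[, 1:2, drop = FALSE],
                   vis_faces[, 2:3, drop = FALSE],
                   vis_faces[, c(3, 1), drop = FALSE])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    # winding: each horizon edge is kept in visible-face order, so
    # appending p preserves the outward orientation of the replaced face
    new_faces <- cbind(horizon, p)
    faces <- rbind(faces[!vis, , drop = FALSE], new_faces)
    geom_new <- face_geometry(new_faces)
    geom <- list(normals = rbind(geom$normals[!vis, , drop = FALSE],
                                 geom_new$normals),
                 offsets = c(geom$offsets[!vis], geom_new$offsets))
  }

  used <- sort(unique(as.vector(faces)))
  remap <- integer(n); remap[used] <- seq_along(used)
  mesh3(pts[used, , drop = FALSE],
        lapply(seq_len(nrow(faces)), function(k) remap[faces[k, ]]))
}

#' Aspect ratio of a mesh in a given axis frame
#'
#' Ratio of the longest to the shortest extent of the bounding box measured
#' along the supplied (orthonormal) axes. For generated stimuli the natural
#' frame is the construction frame: x = symmetry-plane normal, y = vertical,
#' z = their cross product; that is the default.
#'
#' @param mesh a `mesh3` or an n x 3 point matrix
#' @param axes 3 x 3 matrix whose columns are the measurement axes
#' @return aspect ratio >= 1
#' @export
aspect_ratio <- function(mesh, axes = diag(3)) {
  pts <- if (inherits(mesh, "mesh3")) mesh$vertices else as.matrix(mesh)
  proj <- pts %*% axes
  ext <- apply(proj, 2, function(col) diff(range(col)))
  if (min(ext) <= 0) stop("flat object: zero extent along an axis")
  max(ext) / min(ext)
}

#' Rigid pose (rotation + translation)
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1
#' @param translation numeric length-3
#' @return an object of class `rigid_pose`
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation must be proper (det +1)")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "rigid_pose")
}

#' Apply a rigid pose to a mesh or point matrix
#' @param mesh a `mesh3` or n x 3 matrix
#' @param pose a `rigid_pose`
#' @return object of the same kind with vertices mapped to R v + t
#' @export
apply_pose <- function(mesh, pose) {
  stopifnot(inherits(pose, "rigid_pose"))
  if (inherits(mesh, "mesh3")) {
    v <- mesh$vertices %*% t(pose$rotation)
    v <- sweep(v, 2, pose$translation, `+`)
    mesh3(v, mesh$faces)
  } else {
    v <- as.matrix(mesh) %*% t(pose$rotation)
    sweep(v, 2, pose$translation, `+`)
  }
}

#' Interior angles of every face of a mesh
#'
#' For each polygonal face, the angle at each of its vertices between the
#' two incident edges. The stimulus generator's non-rectangularity
#' constraint ("no 90-degree face angle") is checked on these.
#'
#' @param mesh a `mesh3`
#' @return numeric vector of angles in degrees, one per face corner
#' @export
face_angles <- function(mesh) {
  v <- mesh$vertices
  unlist(lapply(mesh$faces, function(f) {
    nf <- length(f)
    prev <- f[c(nf, 1:(nf - 1L))]
    nxt <- f[c(2:nf, 1L)]
    e1 <- v[prev, , drop = FALSE] - v[f, , drop = FALSE]
    e2 <- v[nxt, , drop = FALSE] - v[f, , drop = FALSE]
    cosang <- rowSums(e1 * e2) /
      (sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)))
    acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }))
}

#' Icosphere approximation of a sphere (test oracle shape)
#'
#' Repeated midpoint subdivision of an icosahedron, vertices re-projected
#' onto the sphere.
#' @param subdivisions number of subdivision rounds
#' @param radius sphere radius
#' @return a triangle `mesh3`
#' @export
icosphere <- function(subdivisions = 4, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (vlist[[i]] + vlist[[j]]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1L]] <<- m
      idx <- length(vlist)
      midcache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[(k - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  mesh3(v * radius, lapply(seq_len(nrow(f)), function(k) f[k, ]))
}
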
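# The one-parameter family of 3D mirror-symmetric interpretations of a
# corrected orthographic pair image. A corrected image fixes every
# endpoint's (x, y); the free parameter is the slant sigma of the symmetry
# plane. With tilt tau read off the common segment direction, the plane
# normal is n = (cos tau sin sigma, sin tau sin sigma, cos sigma), gauge
# c = 0 (depth is only ever defined up to a constant shift). Pair
# midpoints must lie on the plane, which fixes the midpoint depth; the
# endpoints sit at -/+ (L/2) cot sigma around it, the second (b) endpoint
# deeper by the pair-ordering convention.

#' Reconstruct one member of the one-parameter family
#'
#' @param image a `corrected_pair_image`
#' @param slant_deg slant of the symmetry plane, strictly inside (0, 90)
#' @return a list of class `reconstruction3d`: `points` (2m x 3; rows
#'   1..m are the a endpoints, m+1..2m the b endpoints), `slant_deg`,
#'   `tilt_deg`, `normal`
#' @export
reconstruct_at_slant <- function(image, slant_deg) {
  stopifnot(inherits(image, "corrected_pair_image"))
  if (slant_deg <= 0 || slant_deg >= 90)
    stop("slant must lie strictly inside (0, 90) degrees")
  sig <- slant_deg * pi / 180
  tau <- image$tilt_deg * pi / 180
  u <- c(cos(tau), sin(tau))
  mid <- (image$a + image$b) / 2
  len <- segment_lengths(image)
  q <- mid %*% u              # in-plane coordinate driving midpoint depth
  z_mid <- -as.numeric(q) * tan(sig)
  dz <- (len / 2) / tan(sig)  # (L/2) cot sigma
  za <- z_mid - dz
  zb <- z_mid + dz
  pts <- rbind(cbind(image$a, za), cbind(image$b, zb))
  dimnames(pts) <- NULL
  structure(list(points = pts,
                 slant_deg = slant_deg,
                 tilt_deg = image$tilt_deg,
                 normal = c(cos(tau) * sin(sig), sin(tau) * sin(sig),
                            cos(sig))),
            class = "reconstruction3d")
}

#' @export
print.reconstruction3d <- function(x, ...) {
  cat(sprintf(
    "reconstruction3d: %d points, slant %.2f deg, tilt %.2f deg\n",
    nrow(x$points), x$slant_deg, x$tilt_deg))
  invisible(x)
}

#' Depth range of a reconstruction
#' @param recon a `reconstruction3d`
#' @return max depth minus min depth (shift-invariant)
#' @export
depth_range <- function(recon) {
  z <- recon$points[, 3]
  max(z) - min(z)
}

#' Slant grid of the one-parameter family
#'
#' The experiment's adjustable range and step: slants from 0.2 rad to
#' pi/2 - 0.2 rad in steps of 0.01 rad (the per-key-press step).
#'
#' @param image a `corrected_pair_image`
#' @param lo,hi grid bounds in radians
#' @param step grid step in radians
#' @return a list of class `family_grid` with `image` and `slants_deg`
#' @export
family_grid <- function(image, lo = 0.2, hi = pi / 2 - 0.2, step = 0.01) {
  stopifnot(inherits(image, "corrected_pair_image"),
            lo > 0, hi < pi / 2, hi >= lo, step > 0)
  structure(list(image = image,
                 slants_deg = seq(lo, hi, by = step) * 180 / pi),
            class = "family_grid")
}

#' Shape dissimilarity between two members of a one-parameter family
#'
#' The binary logarithm of tan(slant_ref) / tan(slant_rec). Zero means the
#' reconstruction is veridical; a value x means the reconstructed aspect
#' ratio is 2^x times the reference aspect ratio; negative values mean the
#' reconstructed slant exceeds the reference slant.
#'
#' @param slant_ref_deg,slant_rec_deg slants in degrees, strictly inside
#'   (0, 90)
#' @return dissimilarity in log2 units
#' @export
shape_dissimilarity <- function(slant_ref_deg, slant_rec_deg) {
  if (any(c(slant_ref_deg, slant_rec_deg) <= 0) ||
      any(c(slant_ref_deg, slant_rec_deg) >= 90))
    stop("slants must lie strictly inside (0, 90) degrees")
  log2(tan(slant_ref_deg * pi / 180) / tan(slant_rec_deg * pi / 180))
}

#' Aspect-ratio factor implied by a dissimilarity value
#'
#' A dissimilarity of x corresponds to a reconstructed aspect ratio 2^x
#' times the reference one: x = 0.15 is an 11% difference, x = 0.3 a 23%
#' difference, x = -1 a factor of one half.
#'
#' @param x dissimilarity (log2 units)
#' @return 2^x
#' @export
aspect_ratio_factor <- function(x) 2^x

#' Export a reconstruction as an OBJ point cloud plus JSON metadata
#' @param recon a `reconstruction3d`
#' @param obj_path OBJ output path (vertices only)
#' @param json_path optional JSON path for slant/tilt/pair metadata
#' @return `obj_path` invisibly
#' @export
write_reconstruction <- function(recon, obj_path, json_path = NULL) {
  p <- recon$points
  writeLines(sprintf("v %.17g %.17g %.17g", p[, 1], p[, 2], p[, 3]),
             obj_path)
  if (!is.null(json_path)) {
    m <- nrow(p) / 2
    jsonlite::write_json(
      list(slant_deg = recon$slant_deg, tilt_deg = recon$tilt_deg,
           pairs = lapply(seq_len(m), function(i) c(i, i + m))),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(obj_path)
}
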
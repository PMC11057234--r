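# Readers/writers for the three ASCII mesh dialects used for stimuli and
# user-supplied objects. Indices are 1-based in memory, translated per
# format (OBJ is 1-based on disk, OFF and PLY are 0-based).

#' Read a mesh from OBJ, OFF or ASCII PLY
#'
#' The format is chosen by file extension. Only geometry is read: OBJ `v`
#' and `f` records (texture/normal slots in `f` entries like `1/2/3` are
#' stripped), OFF vertex/face blocks, PLY ASCII `vertex`/`face` elements.
#'
#' @param path file path ending in .obj, .off or .ply
#' @return a `mesh3`
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  reader <- switch(ext,
    obj = read_obj_lines,
    off = read_off_lines,
    ply = read_ply_lines,
    stop("unknown mesh extension: ", ext)
  )
  reader(readLines(path, warn = FALSE), path)
}

#' Write a mesh to OBJ, OFF or ASCII PLY
#' @param mesh a `mesh3`
#' @param path output path; extension selects the format
#' @return `path`, invisibly
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "mesh3"))
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  fmt_v <- sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
  lines <- switch(ext,
    obj = c(paste("v", fmt_v),
            vapply(mesh$faces, function(f)
              paste("f", paste(f, collapse = " ")), character(1))),
    off = c("OFF",
            sprintf("%d %d 0", nrow(v), length(mesh$faces)),
            fmt_v,
            vapply(mesh$faces, function(f)
              paste(length(f), paste(f - 1L, collapse = " ")), character(1))),
    ply = c("ply", "format ascii 1.0",
            sprintf("element vertex %d", nrow(v)),
            "property double x", "property double y", "property double z",
            sprintf("element face %d", length(mesh$faces)),
            "property list uchar int vertex_indices", "end_header",
            fmt_v,
            vapply(mesh$faces, function(f)
              paste(length(f), paste(f - 1L, collapse = " ")), character(1))),
    stop("unknown mesh extension: ", ext)
  )
  writeLines(lines, path)
  invisible(path)
}

parse_error <- function(path, lineno, msg) {
  stop(sprintf("%s:%d: %s", path, lineno, msg), call. = FALSE)
}

split_fields <- function(line) strsplit(trimws(line), "[[:space:]]+")[[1]]

read_obj_lines <- function(lines, path) {
  verts <- list(); faces <- list()
  for (i in seq_along(lines)) {
    fields <- split_fields(lines[i])
    if (length(fields) == 0 || fields[1] %in% c("", "#")) next
    if (fields[1] == "v") {
      xyz <- suppressWarnings(as.numeric(fields[2:4]))
      if (length(fields) < 4 || anyNA(xyz))
        parse_error(path, i, "malformed OBJ vertex")
      verts[[length(verts) + 1L]] <- xyz
    } else if (fields[1] == "f") {
      idx <- suppressWarnings(
        as.integer(sub("/.*$", "", fields[-1])))
      if (length(idx) < 3 || anyNA(idx))
        parse_error(path, i, "malformed OBJ face")
      faces[[length(faces) + 1L]] <- idx
    }
  }
  if (length(verts) == 0) parse_error(path, 1L, "no vertices found")
  mesh3(do.call(rbind, verts), faces)
}

read_off_lines <- function(lines, path) {
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) parse_error(path, 1L, "empty OFF file")
  if (trimws(lines[keep[1]]) != "OFF")
    parse_error(path, keep[1], "missing OFF header")
  counts <- suppressWarnings(as.integer(split_fields(lines[keep[2]])))
  if (length(counts) < 2 || anyNA(counts[1:2]))
    parse_error(path, keep[2], "malformed OFF count line")
  nv <- counts[1]; nf <- counts[2]
  body <- keep[-(1:2)]
  if (length(body) < nv + nf) parse_error(path, keep[2], "truncated OFF body")
  verts <- t(vapply(body[seq_len(nv)], function(i) {
    xyz <- suppressWarnings(as.numeric(split_fields(lines[i])[1:3]))
    if (anyNA(xyz)) parse_error(path, i, "malformed OFF vertex")
    xyz
  }, numeric(3)))
  faces <- lapply(body[nv + seq_len(nf)], function(i) {
    fields <- suppressWarnings(as.integer(split_fields(lines[i])))
    if (anyNA(fields) || length(fields) < fields[1] + 1L)
      parse_error(path, i, "malformed OFF face")
    fields[1L + seq_len(fields[1])] + 1L
  })
  mesh3(verts, faces)
}

read_ply_lines <- function(lines, path) {
  if (length(lines) == 0 || trimws(lines[1]) != "ply")
    parse_error(path, 1L, "missing ply magic")
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) parse_error(path, length(lines), "no end_header")
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", trimws(hdr))))
    stop("only ASCII PLY is supported")
  get_count <- function(el) {
    ln <- grep(sprintf("^element\\s+%s\\s", el), trimws(hdr), value = TRUE)
    if (length(ln) == 0) return(0L)
    as.integer(split_fields(ln[1])[3])
  }
  nv <- get_count("vertex"); nf <- get_count("face")
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[!grepl("^\\s*$", body)]
  if (length(body) < nv + nf) parse_error(path, hdr_end, "truncated PLY body")
  verts <- t(vapply(seq_len(nv), function(k) {
    xyz <- suppressWarnings(as.numeric(split_fields(body[k])[1:3]))
    if (anyNA(xyz)) parse_error(path, hdr_end + k, "malformed PLY vertex")
    xyz
  }, numeric(3)))
  faces <- lapply(seq_len(nf), function(k) {
    fields <- suppressWarnings(as.integer(split_fields(body[nv + k])))
    if (anyNA(fields) || length(fields) < fields[1] + 1L)
      parse_error(path, hdr_end + nv + k, "malformed PLY face")
    fields[1L + seq_len(fields[1])] + 1L
  })
  mesh3(verts, faces)
}
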
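#' Indexed triangle surface mesh
#'
#' Container for a lumen surface: an `n x 3` vertex matrix (millimetres), an
#' `m x 3` integer face matrix (1-based vertex indices, counter-clockwise when
#' viewed from outside), and a unit axial direction. The axial direction is the
#' cranio-caudal axis along which heights are measured; the default `(0, 0, 1)`
#' matches the synthetic-anatomy generators.
#'
#' On construction duplicate vertices are merged (tolerance `1e-6` mm) and
#' zero-area faces (area below `1e-12` mm^2) are dropped, so downstream area
#' and volume sums never see degenerate triangles.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param axis numeric length-3 axial direction; normalised internally.
#' @param clean logical; merge duplicate vertices and drop degenerate faces.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, axis = c(0, 0, 1), clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) < 1L || nrow(vertices) < 3L) stop("mesh is empty")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range")
  }
  axis <- as.numeric(axis)
  if (length(axis) != 3L || !all(is.finite(axis)) || sum(axis^2) == 0) {
    stop("axis must be a finite non-zero 3-vector")
  }
  axis <- axis / sqrt(sum(axis^2))
  mesh <- structure(list(vertices = vertices, faces = faces, axis = axis),
                    class = "tri_mesh")
  if (clean) mesh <- clean_mesh(mesh)
  mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  ext <- axial_height(x)
  cat(sprintf("tri_mesh: %d vertices, %d faces, axial extent %.3f mm\n",
              nrow(x$vertices), nrow(x$faces), ext))
  invisible(x)
}

is_tri_mesh <- function(x) inherits(x, "tri_mesh")

stop_if_not_mesh <- function(mesh) {
  if (!is_tri_mesh(mesh)) stop("expected a 'tri_mesh' object")
  if (nrow(mesh$faces) == 0L) stop("mesh is empty")
  invisible(mesh)
}

# Merge near-coincident vertices (grid rounding at `tol`) and drop faces whose
# area falls below `area_tol`; reindexes faces accordingly.
clean_mesh <- function(mesh, tol = 1e-6, area_tol = 1e-12) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  v2 <- v[first, , drop = FALSE]
  f2 <- matrix(map[mesh$faces], ncol = 3L)
  # drop collapsed / degenerate faces
  areas <- triangle_areas(v2, f2)
  ok <- areas > area_tol &
    f2[, 1] != f2[, 2] & f2[, 2] != f2[, 3] & f2[, 1] != f2[, 3]
  f2 <- f2[ok, , drop = FALSE]
  if (nrow(f2) == 0L) stop("mesh has no non-degenerate faces after cleaning")
  # drop unreferenced vertices
  used <- sort(unique(as.vector(f2)))
  remap <- integer(nrow(v2))
  remap[used] <- seq_along(used)
  structure(list(vertices = v2[used, , drop = FALSE],
                 faces = matrix(remap[f2], ncol = 3L),
                 axis = mesh$axis),
            class = "tri_mesh")
}

# Per-face areas for an arbitrary vertex/face pair (used before cleaning too).
triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Unit face normals (rows); degenerate faces get a zero normal.
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Read a triangle mesh from an STL file
#'
#' Reads binary or ASCII stereolithography files (auto-detected), merges
#' duplicate vertices and drops degenerate faces. Units are taken as
#' millimetres, the convention for vascular surface models.
#'
#' @param path path to an STL file.
#' @param axis axial direction to attach to the mesh.
#' @return A [tri_mesh].
#' @export
read_stl <- function(path, axis = c(0, 0, 1)) {
  if (!file.exists(path)) stop("file not found: ", path)
  size <- file.info(path)$size
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", n = min(512, size))
  close(con)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, fixed = TRUE, useBytes = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, size)
  soup_to_mesh(tri, axis)
}

# `tri` is a (3*ntri) x 3 matrix of vertex rows, consecutive triples = faces.
soup_to_mesh <- function(tri, axis) {
  ntri <- nrow(tri) / 3L
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  tri_mesh(tri, faces, axis = axis, clean = TRUE)
}

read_stl_binary <- function(path, size) {
  if (size < 84) stop("corrupt binary STL (file shorter than 84 bytes): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(ntri) || ntri < 0) stop("corrupt binary STL header at byte 80: ", path)
  expected <- 84 + 50 * as.numeric(ntri)
  if (size < expected) {
    stop(sprintf("corrupt binary STL: %d triangles declared, file truncated at byte %.0f",
                 ntri, size))
  }
  body <- readBin(con, "raw", n = 50 * ntri)
  body <- matrix(body, nrow = 50L)
  float_bytes <- as.vector(body[1:48, , drop = FALSE])
  vals <- readBin(float_bytes, "numeric", n = 12L * ntri, size = 4,
                  endian = "little")
  vals <- matrix(vals, nrow = 12L)  # normal(3), v1(3), v2(3), v3(3) per column
  tri <- matrix(0, nrow = 3L * ntri, ncol = 3L)
  tri[seq(1L, 3L * ntri, by = 3L), ] <- t(vals[4:6, , drop = FALSE])
  tri[seq(2L, 3L * ntri, by = 3L), ] <- t(vals[7:9, , drop = FALSE])
  tri[seq(3L, 3L * ntri, by = 3L), ] <- t(vals[10:12, , drop = FALSE])
  tri
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L) {
    bad <- if (length(vlines)) vlines[length(vlines)] else 1L
    stop(sprintf("corrupt ASCII STL near line %d: vertex count %d not a multiple of 3",
                 bad, length(vlines)))
  }
  txt <- sub("^\\s*vertex\\s+", "", lines[vlines])
  nums <- suppressWarnings(
    matrix(as.numeric(unlist(strsplit(trimws(txt), "\\s+"))),
           ncol = 3L, byrow = TRUE))
  if (anyNA(nums) || nrow(nums) != length(vlines)) {
    stop("corrupt ASCII STL: unparsable vertex line near line ", vlines[1])
  }
  nums
}

#' Write a triangle mesh to an STL file
#'
#' Binary STL is the compact interchange default (80-byte header, 4-byte
#' triangle count, 50 bytes per facet). ASCII output stores coordinates at
#' full double precision and is preferred when meshes must round-trip exactly
#' (binary STL stores 32-bit floats).
#'
#' @param mesh a [tri_mesh].
#' @param path output path.
#' @param format `"binary"` or `"ascii"`.
#' @return Invisibly, `path`.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii")) {
  stop_if_not_mesh(mesh)
  format <- match.arg(format)
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  if (format == "binary") {
    ntri <- nrow(f)
    floats <- rbind(t(n), t(v[f[, 1], , drop = FALSE]),
                    t(v[f[, 2], , drop = FALSE]),
                    t(v[f[, 3], , drop = FALSE]))  # 12 x ntri
    fr <- writeBin(as.vector(floats), raw(), size = 4, endian = "little")
    fr <- matrix(fr, nrow = 48L)
    block <- rbind(fr, matrix(as.raw(0), nrow = 2L, ncol = ntri))
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(ntri), con, size = 4, endian = "little")
    writeBin(as.vector(block), con)
  } else {
    fmt <- paste0(
      " facet normal %.9g %.9g %.9g\n  outer loop\n",
      "   vertex %.17g %.17g %.17g\n   vertex %.17g %.17g %.17g\n",
      "   vertex %.17g %.17g %.17g\n  endloop\n endfacet")
    body <- sprintf(fmt, n[, 1], n[, 2], n[, 3],
                    v[f[, 1], 1], v[f[, 1], 2], v[f[, 1], 3],
                    v[f[, 2], 1], v[f[, 2], 2], v[f[, 2], 3],
                    v[f[, 3], 1], v[f[, 3], 2], v[f[, 3], 3])
    writeLines(c("solid graftgauge", body, "endsolid graftgauge"), path)
  }
  invisible(path)
}
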
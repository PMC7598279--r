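#' Axial height of a mesh
#'
#' Extent of the vertex projections onto the mesh axis (max minus min), in mm.
#' Heights are axis-aligned scalar distances, not centreline arc lengths: the
#' reference-cylinder construction treats an object's height as the single
#' cranio-caudal distance it spans.
#'
#' @param mesh a [tri_mesh].
#' @return Height in mm (strictly positive for 3-D objects).
#' @export
axial_height <- function(mesh) {
  stop_if_not_mesh(mesh)
  proj <- as.vector(mesh$vertices %*% mesh$axis)
  diff(range(proj))
}

#' Side (lateral) surface area of a mesh
#'
#' Sum of triangle areas in mm^2. The side-surface convention excludes end
#' caps: synthetic lumens are generated open-ended, and capped external meshes
#' should first pass through [strip_caps()].
#'
#' @param mesh a [tri_mesh].
#' @return Area in mm^2.
#' @export
side_surface_area <- function(mesh) {
  stop_if_not_mesh(mesh)
  sum(triangle_areas(mesh$vertices, mesh$faces))
}

#' Remove end-cap faces from a capped tube mesh
#'
#' Drops faces whose normals lie within `tol_deg` of the (signed) axis *and*
#' whose centroids sit within 1% of the axial extremes, converting a capped
#' tube into the open-ended form the side-surface convention expects.
#'
#' @param mesh a [tri_mesh].
#' @param tol_deg angular tolerance in degrees, in (0, 45].
#' @return A [tri_mesh] without cap faces.
#' @export
strip_caps <- function(mesh, tol_deg = 15) {
  stop_if_not_mesh(mesh)
  if (tol_deg <= 0 || tol_deg > 45) stop("tol_deg must be in (0, 45]")
  n <- face_normals(mesh)
  ca <- abs(as.vector(n %*% mesh$axis))
  axis_aligned <- ca >= cos(tol_deg * pi / 180)
  f <- mesh$faces
  v <- mesh$vertices
  cz <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
           v[f[, 3], , drop = FALSE]) / 3
  proj <- as.vector(cz %*% mesh$axis)
  rng <- range(as.vector(v %*% mesh$axis))
  band <- 0.01 * diff(rng)
  at_ends <- proj <= rng[1] + band | proj >= rng[2] - band
  keep <- !(axis_aligned & at_ends)
  if (!any(keep)) stop("mesh is all caps")
  tri_mesh(v, f[keep, , drop = FALSE], axis = mesh$axis, clean = TRUE)
}

# Boundary edges (appear in exactly one face), returned oriented as in their
# face; errors on non-manifold edges (> 2 incident faces).
boundary_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt > 2)) stop("non-manifold surface: edge shared by >2 faces")
  e[cnt[key] == 1L, , drop = FALSE]
}

# Group boundary edges into loops (connected components over shared vertices).
boundary_loops <- function(edges) {
  verts <- sort(unique(as.vector(edges)))
  comp <- seq_along(verts)          # union-find over loop vertices
  idx <- match(edges, verts)
  dim(idx) <- dim(edges)
  find <- function(i) {
    while (comp[i] != i) {
      comp[i] <<- comp[comp[i]]
      i <- comp[i]
    }
    i
  }
  for (k in seq_len(nrow(idx))) {
    a <- find(idx[k, 1]); b <- find(idx[k, 2])
    if (a != b) comp[a] <- b
  }
  roots <- vapply(idx[, 1], find, integer(1))
  split(seq_len(nrow(edges)), roots)
}

#' Enclosed volume of a mesh
#'
#' Volume in mm^3 via the signed-tetrahedron (divergence theorem) sum. Open
#' tubes are virtually capped first: each boundary loop is closed with a
#' planar fan to its own centroid, oriented consistently with the adjacent
#' faces, so open-ended lumens and bifurcated grafts (several boundary loops)
#' are handled without modifying the input. The result is
#' orientation-normalised (absolute value).
#'
#' @param mesh a [tri_mesh]; must be closed or cappable (manifold edges).
#' @return Volume in mm^3.
#' @export
enclosed_volume <- function(mesh) {
  stop_if_not_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  vol6 <- signed_volume6(v, f)
  be <- boundary_edges(mesh)
  if (nrow(be) > 0L) {
    for (loop in boundary_loops(be)) {
      le <- be[loop, , drop = FALSE]
      centroid <- colMeans(v[unique(as.vector(le)), , drop = FALSE])
      # cap triangle (b, a, centroid) reverses the boundary edge, keeping a
      # consistent closed orientation with the existing faces
      a <- v[le[, 1], , drop = FALSE]
      b <- v[le[, 2], , drop = FALSE]
      vol6 <- vol6 + sum(det3(b, a, matrix(centroid, nrow(le), 3, byrow = TRUE)))
    }
  }
  abs(vol6) / 6
}

# 6x the signed volume contribution of every face: det(v1, v2, v3).
signed_volume6 <- function(v, f) {
  sum(det3(v[f[, 1], , drop = FALSE],
           v[f[, 2], , drop = FALSE],
           v[f[, 3], , drop = FALSE]))
}

det3 <- function(a, b, c_) {
  a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
}

#' Reference cylinder of a mesh
#'
#' The equivalent cylinder sharing the object's axial height and lateral
#' (side) surface: `diameter = side_surface / (pi * height)`. A
#' `height_override` lets two objects (aneurysm and stent-graft from the same
#' patient) be referenced at a common height.
#'
#' @param mesh a [tri_mesh].
#' @param height_override optional common height in mm (> 0).
#' @return An object of class `reference_cylinder` with fields `height`,
#'   `diameter`, `side_surface` (mm^2) and `volume` (mm^3).
#' @export
build_reference_cylinder <- function(mesh, height_override = NULL) {
  stop_if_not_mesh(mesh)
  h <- if (is.null(height_override)) axial_height(mesh) else height_override
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("reference height must be a single positive number")
  }
  a <- side_surface_area(mesh)
  d <- a / (pi * h)
  structure(list(height = h, diameter = d, side_surface = a,
                 volume = pi * d^2 / 4 * h),
            class = "reference_cylinder")
}

#' @export
print.reference_cylinder <- function(x, ...) {
  cat(sprintf(
    "reference_cylinder: height %.3f mm, diameter %.3f mm, side surface %.1f mm^2, volume %.1f mm^3\n",
    x$height, x$diameter, x$side_surface, x$volume))
  invisible(x)
}

#' Shape factor of a mesh against its reference cylinder
#'
#' Dimensionless ratio `V_reference_cylinder / V_object`. A perfect open
#' cylinder is its own reference and scores 1; bulged or bifurcated lumens
#' carry more lateral surface per unit volume, so their reference cylinder is
#' wider and the factor exceeds 1. The `definition` switch also exposes a
#' diameter-based variant (reference diameter over the volume-equivalent
#' cylinder diameter at the same height), kept configurable because the
#' volume form is a modelling choice rather than a community standard.
#'
#' @param mesh a [tri_mesh].
#' @param height_override optional reference height in mm.
#' @param definition `"volume"` (default) or `"diameter"`.
#' @return Dimensionless shape factor (> 0).
#' @export
shape_factor_vs_cylinder <- function(mesh, height_override = NULL,
                                     definition = c("volume", "diameter")) {
  definition <- match.arg(definition)
  rc <- build_reference_cylinder(mesh, height_override)
  vol <- enclosed_volume(mesh)
  if (vol <= 0) stop("mesh encloses zero volume")
  if (definition == "volume") {
    rc$volume / vol
  } else {
    d_eq <- 2 * sqrt(vol / (pi * rc$height))
    rc$diameter / d_eq
  }
}

#' Shape-factor comparison of an aneurysm and its stent-graft
#'
#' Builds both reference cylinders at the *same* height — the aneurysm's
#' axial height, the per-patient common-height convention — and reports the
#' ratio of reference side surfaces together with each object's own shape
#' factor and the graft/aneurysm enclosed-volume ratio.
#'
#' @param aaa aneurysm [tri_mesh].
#' @param graft stent-graft [tri_mesh]; axial extent must not exceed the
#'   aneurysm's by more than 1% (a warning is raised and the aneurysm height
#'   used otherwise).
#' @param direction `"aneurysm_over_graft"` (side-surface ratio
#'   `A_aneurysm / A_graft`) or `"graft_over_aneurysm"` (its reciprocal).
#' @return An object of class `shape_factor_report`: `phi_ref_aaa`,
#'   `phi_ref_graft`, `phi_AS`, `direction`, `volume_ratio`
#'   (`V_graft / V_aaa`) and `height` (mm).
#' @export
shape_factor_pair <- function(aaa, graft,
                              direction = c("aneurysm_over_graft",
                                            "graft_over_aneurysm")) {
  direction <- match.arg(direction)
  stop_if_not_mesh(aaa)
  stop_if_not_mesh(graft)
  h_a <- axial_height(aaa)
  h_g <- axial_height(graft)
  if (h_g > h_a * 1.01) {
    warning(sprintf(
      "graft height %.3f mm exceeds aneurysm height %.3f mm by >1%%; using aneurysm height",
      h_g, h_a))
  }
  rc_a <- build_reference_cylinder(aaa, height_override = h_a)
  rc_g <- build_reference_cylinder(graft, height_override = h_a)
  phi_ag <- rc_a$side_surface / rc_g$side_surface
  v_a <- enclosed_volume(aaa)
  v_g <- enclosed_volume(graft)
  structure(list(
    phi_ref_aaa = rc_a$volume / v_a,
    phi_ref_graft = rc_g$volume / v_g,
    phi_AS = if (direction == "aneurysm_over_graft") phi_ag else 1 / phi_ag,
    direction = direction,
    volume_ratio = v_g / v_a,
    height = h_a),
    class = "shape_factor_report")
}

#' @export
print.shape_factor_report <- function(x, ...) {
  cat(sprintf("shape_factor_report (height %.2f mm)\n", x$height))
  cat(sprintf("  phi_ref (AAA)   : %.4f\n", x$phi_ref_aaa))
  cat(sprintf("  phi_ref (graft) : %.4f\n", x$phi_ref_graft))
  cat(sprintf("  phi_AS [%s] : %.4f\n", x$direction, x$phi_AS))
  cat(sprintf("  volume ratio (graft/AAA) : %.4f\n", x$volume_ratio))
  invisible(x)
}
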
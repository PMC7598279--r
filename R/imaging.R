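#' Voxel volume container
#'
#' A 3-D scalar intensity grid with per-axis spacing (mm) and origin, the
#' working representation of a CT-angiography-like acquisition.
#'
#' @param intensities 3-D numeric array.
#' @param spacing numeric length-3 voxel spacing, mm (> 0).
#' @param origin numeric length-3 origin, mm.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, spacing = c(0.78, 0.78, 0.8),
                         origin = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3L) stop("intensities must be a 3-D array")
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive values")
  }
  structure(list(intensities = intensities, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("voxel_volume: %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' In-plane circular region of interest
#'
#' A circle of the given physical area centred at a voxel index within one
#' slice — the ROI convention for intensity and noise measurements (object
#' ROIs of 80 mm^2, noise ROIs of 100 mm^2 outside the body).
#'
#' @param center integer length-3 voxel index (x, y, slice).
#' @param area_mm2 in-plane area, mm^2 (> 0).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center, area_mm2 = 80) {
  center <- as.integer(center)
  if (length(center) != 3L) stop("center must be a length-3 voxel index")
  if (area_mm2 <= 0) stop("area_mm2 must be > 0")
  structure(list(center = center, area_mm2 = area_mm2), class = "roi_spec")
}

# Intensities inside a circular in-plane ROI.
roi_values <- function(vol, roi) {
  d <- dim(vol$intensities)
  cx <- roi$center[1]
  cy <- roi$center[2]
  sl <- roi$center[3]
  if (any(roi$center < 1L) || cx > d[1] || cy > d[2] || sl > d[3]) {
    stop("ROI centre outside volume")
  }
  r_mm <- sqrt(roi$area_mm2 / pi)
  sx <- vol$spacing[1]
  sy <- vol$spacing[2]
  ix <- seq_len(d[1])
  iy <- seq_len(d[2])
  dx2 <- ((ix - cx) * sx)^2
  dy2 <- ((iy - cy) * sy)^2
  inside <- outer(dx2, dy2, "+") <= r_mm^2
  if (!any(inside)) stop("ROI smaller than one voxel")
  vol$intensities[, , sl][inside]
}

#' Synthetic imaging phantom: bright sphere over a noisy background
#'
#' A uniform background with a brighter spherical object plus seeded Gaussian
#' noise, the stand-in for a contrast-filled lumen in CT angiography. The
#' default levels reproduce the image-quality regime of clinical acquisitions
#' of this kind: brightness-to-noise about 25 and contrast-to-noise about 4.4.
#'
#' @param object_radius sphere radius, mm.
#' @param object_intensity,background_intensity intensity levels.
#' @param noise_sigma Gaussian noise SD (>= 0).
#' @param shape grid dimensions (3 integers).
#' @param spacing voxel spacing, mm.
#' @param center sphere centre in voxel indices (defaults to the grid centre).
#' @param seed RNG seed for the noise.
#' @return List with `volume` (a [voxel_volume]) and `truth` (logical array,
#'   the noiseless object mask).
#' @export
make_phantom <- function(object_radius = 15, object_intensity = 249,
                         background_intensity = 205.2, noise_sigma = 10,
                         shape = c(80, 80, 80), spacing = c(0.78, 0.78, 0.8),
                         center = NULL, seed = 1) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  shape <- as.integer(shape)
  if (is.null(center)) center <- (shape + 1) / 2
  ext <- (shape - 1) * spacing
  cmm <- (center - 1) * spacing
  if (any(cmm - object_radius < 0) || any(cmm + object_radius > ext)) {
    stop("object does not fit inside the grid")
  }
  dx2 <- ((seq_len(shape[1]) - center[1]) * spacing[1])^2
  dy2 <- ((seq_len(shape[2]) - center[2]) * spacing[2])^2
  dz2 <- ((seq_len(shape[3]) - center[3]) * spacing[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  truth <- r2 <= object_radius^2
  img <- array(background_intensity, dim = shape)
  img[truth] <- object_intensity
  if (noise_sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    img <- img + array(stats::rnorm(prod(shape), 0, noise_sigma), dim = shape)
  }
  list(volume = voxel_volume(img, spacing), truth = truth)
}

# 6-connected neighbours of linear indices in a d[1] x d[2] x d[3] grid.
neighbors6 <- function(idx, d) {
  n12 <- d[1] * d[2]
  i <- ((idx - 1L) %% d[1]) + 1L
  j <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  k <- ((idx - 1L) %/% n12) + 1L
  c(idx[i > 1L] - 1L, idx[i < d[1]] + 1L,
    idx[j > 1L] - d[1], idx[j < d[2]] + d[1],
    idx[k > 1L] - n12, idx[k < d[3]] + n12)
}

#' Region growing segmentation
#'
#' Breadth-first growth of the 6-connected region around a seed voxel:
#' a neighbouring voxel joins the region when its intensity lies within
#' `tolerance` of the *running region mean* (adaptive acceptance). After the
#' frontier stalls, all region-adjacent voxels are re-examined against the
#' final mean until a fixed point is reached, so the result does not depend
#' on visit order.
#'
#' @param vol a [voxel_volume].
#' @param seed_voxel integer length-3 voxel index.
#' @param tolerance intensity tolerance (> 0).
#' @return Logical array of the same shape (the region mask).
#' @export
region_grow <- function(vol, seed_voxel, tolerance) {
  if (!inherits(vol, "voxel_volume")) stop("vol must be a voxel_volume")
  d <- dim(vol$intensities)
  seed_voxel <- as.integer(seed_voxel)
  if (length(seed_voxel) != 3L || any(seed_voxel < 1L) ||
      any(seed_voxel > d)) {
    stop("seed voxel outside volume")
  }
  img <- as.vector(vol$intensities)
  seed_idx <- seed_voxel[1] + (seed_voxel[2] - 1L) * d[1] +
    (seed_voxel[3] - 1L) * d[1] * d[2]
  mask <- logical(length(img))
  mask[seed_idx] <- TRUE
  total <- img[seed_idx]
  count <- 1L
  frontier <- seed_idx
  repeat {
    repeat {
      cand <- unique(neighbors6(frontier, d))
      cand <- cand[!mask[cand]]
      if (length(cand) == 0L) break
      ok <- abs(img[cand] - total / count) <= tolerance
      acc <- cand[ok]
      if (length(acc) == 0L) break
      mask[acc] <- TRUE
      total <- total + sum(img[acc])
      count <- count + length(acc)
      frontier <- acc
    }
    # fixed-point sweep: re-offer every region-adjacent voxel to the final mean
    edge <- unique(neighbors6(which(mask), d))
    edge <- edge[!mask[edge]]
    acc <- edge[abs(img[edge] - total / count) <= tolerance]
    if (length(acc) == 0L) break
    mask[acc] <- TRUE
    total <- total + sum(img[acc])
    count <- count + length(acc)
    frontier <- acc
  }
  array(mask, dim = d)
}

#' Morphological hole filling
#'
#' Sets interior cavities — background components with no 6-connected path to
#' the grid border — to foreground. Idempotent; never removes foreground.
#'
#' @param mask logical 3-D array.
#' @return Logical array with cavities filled.
#' @export
fill_holes <- function(mask) {
  if (!is.logical(mask) || length(dim(mask)) != 3L) {
    stop("mask must be a logical 3-D array")
  }
  d <- dim(mask)
  bg <- !as.vector(mask)
  reached <- logical(length(bg))
  # all border voxels that are background
  idx <- array(seq_along(bg), dim = d)
  border <- unique(c(idx[c(1, d[1]), , ], idx[, c(1, d[2]), ],
                     idx[, , c(1, d[3])]))
  frontier <- border[bg[border]]
  reached[frontier] <- TRUE
  while (length(frontier) > 0L) {
    cand <- unique(neighbors6(frontier, d))
    cand <- cand[bg[cand] & !reached[cand]]
    reached[cand] <- TRUE
    frontier <- cand
  }
  array(as.vector(mask) | (bg & !reached), dim = d)
}

# Pooled image-noise estimate from ROIs outside the body. `definition`
# selects between the plain pooled SD (default) and the ratio mean/SD
# reading of the acquisition protocol.
image_noise <- function(vol, noise_rois, definition = c("sd", "mean_over_sd")) {
  definition <- match.arg(definition)
  vals <- lapply(noise_rois, function(r) roi_values(vol, r))
  sds <- vapply(vals, stats::sd, numeric(1))
  pooled_sd <- sqrt(mean(sds^2))
  if (definition == "sd") pooled_sd else {
    mean(vapply(vals, mean, numeric(1))) / pooled_sd
  }
}

#' Brightness-intensity-to-noise ratio (BI)
#'
#' Mean object-ROI intensity (averaged across the supplied per-slice ROIs)
#' divided by the image noise pooled over the noise ROIs.
#'
#' @param vol a [voxel_volume].
#' @param object_rois list of [roi_spec()] centred on the object
#'   (conventionally 80 mm^2, one per analysed slice).
#' @param noise_rois list of [roi_spec()] outside the body (conventionally
#'   two regions of 100 mm^2).
#' @param noise_definition `"sd"` (pooled SD, default) or `"mean_over_sd"`.
#' @return Dimensionless BI.
#' @export
brightness_to_noise <- function(vol, object_rois, noise_rois,
                                noise_definition = c("sd", "mean_over_sd")) {
  if (length(object_rois) < 1L || length(noise_rois) < 1L) {
    stop("need at least one object ROI and one noise ROI")
  }
  noise <- image_noise(vol, noise_rois, noise_definition)
  if (noise == 0) stop("zero image noise: BI undefined")
  obj <- mean(vapply(object_rois, function(r) mean(roi_values(vol, r)),
                     numeric(1)))
  obj / noise
}

#' Contrast-to-noise ratio (CNR)
#'
#' Difference between the mean object and mean background ROI intensities,
#' divided by the pooled image noise.
#'
#' @inheritParams brightness_to_noise
#' @param background_rois list of [roi_spec()] on representative background.
#' @return Dimensionless CNR.
#' @export
contrast_to_noise <- function(vol, object_rois, background_rois, noise_rois,
                              noise_definition = c("sd", "mean_over_sd")) {
  if (length(object_rois) < 1L || length(background_rois) < 1L ||
      length(noise_rois) < 1L) {
    stop("need object, background and noise ROIs")
  }
  noise <- image_noise(vol, noise_rois, noise_definition)
  if (noise == 0) stop("zero image noise: CNR undefined")
  obj <- mean(vapply(object_rois, function(r) mean(roi_values(vol, r)),
                     numeric(1)))
  bg <- mean(vapply(background_rois, function(r) mean(roi_values(vol, r)),
                    numeric(1)))
  (obj - bg) / noise
}
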
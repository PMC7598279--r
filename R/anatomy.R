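#' Parameters of the synthetic AAA / stent-graft anatomy
#'
#' Patient-scale defaults: aortic neck diameter 20 mm, sac diameter 55 mm
#' (the surgical-repair threshold), cranio-caudal height 130 mm, iliac limb
#' diameter 12 mm — a fusiform aneurysm with a bifurcated endoprosthesis.
#' `graft_body_frac_long` / `graft_body_frac_short` give the trunk length of
#' the long- and short-body graft as a fraction of total height; the two
#' configurations differ *only* in this fraction.
#'
#' @param neck_radius aortic neck radius, mm.
#' @param sac_radius maximal sac radius, mm (> neck_radius).
#' @param height total cranio-caudal height, mm.
#' @param sac_center_frac axial position of the sac centre, fraction of height.
#' @param sac_length_frac axial width of the sac bulge, fraction of height.
#' @param graft_body_frac_long trunk fraction of the long-body graft.
#' @param graft_body_frac_short trunk fraction of the short-body graft.
#' @param limb_radius iliac limb radius, mm (< neck_radius).
#' @param bifurcation_angle full angle between the two limbs, degrees, in
#'   `[0, 45]`.
#' @param circumferential_segments,axial_segments mesh resolution (>= 16).
#' @return An object of class `anatomy_params`.
#' @export
anatomy_params <- function(neck_radius = 10,
                           sac_radius = 27.5,
                           height = 130,
                           sac_center_frac = 0.45,
                           sac_length_frac = 0.5,
                           graft_body_frac_long = 0.6,
                           graft_body_frac_short = 0.25,
                           limb_radius = 6,
                           bifurcation_angle = 15,
                           circumferential_segments = 64,
                           axial_segments = 80) {
  p <- list(neck_radius = neck_radius, sac_radius = sac_radius,
            height = height, sac_center_frac = sac_center_frac,
            sac_length_frac = sac_length_frac,
            graft_body_frac_long = graft_body_frac_long,
            graft_body_frac_short = graft_body_frac_short,
            limb_radius = limb_radius,
            bifurcation_angle = bifurcation_angle,
            circumferential_segments = as.integer(circumferential_segments),
            axial_segments = as.integer(axial_segments))
  validate_anatomy_params(p)
  structure(p, class = "anatomy_params")
}

validate_anatomy_params <- function(p) {
  bad <- character(0)
  # equality gives the degenerate (bump-free) cylinder, useful for self-tests
  if (!(p$sac_radius >= p$neck_radius)) bad <- c(bad, "sac_radius >= neck_radius")
  if (!(p$neck_radius > p$limb_radius)) bad <- c(bad, "neck_radius > limb_radius")
  if (!(p$limb_radius > 0)) bad <- c(bad, "limb_radius > 0")
  if (!(p$height > 0)) bad <- c(bad, "height > 0")
  if (!(p$sac_center_frac > 0 && p$sac_center_frac < 1)) {
    bad <- c(bad, "sac_center_frac in (0,1)")
  }
  if (!(p$sac_length_frac > 0 && p$sac_length_frac < 1)) {
    bad <- c(bad, "sac_length_frac in (0,1)")
  }
  if (!(p$graft_body_frac_short > 0 &&
        p$graft_body_frac_short < p$graft_body_frac_long &&
        p$graft_body_frac_long < 1)) {
    bad <- c(bad, "0 < graft_body_frac_short < graft_body_frac_long < 1")
  }
  if (p$circumferential_segments < 16L || p$axial_segments < 16L) {
    bad <- c(bad, "segments >= 16")
  }
  if (length(bad)) {
    stop("invalid anatomy parameters; violated: ", paste(bad, collapse = "; "))
  }
  invisible(p)
}

# Open surface of revolution about +z: radius_fun(z) over [z0, z0 + height],
# nc points around, na axial intervals. Outward orientation.
revolution_mesh <- function(radius_fun, height, nc, na, z0 = 0,
                            center_fun = NULL) {
  z <- z0 + seq(0, height, length.out = na + 1L)
  r <- radius_fun(z)
  theta <- 2 * pi * (seq_len(nc) - 1L) / nc
  ct <- cos(theta)
  st <- sin(theta)
  cx <- if (is.null(center_fun)) rep(0, length(z)) else center_fun(z)
  verts <- cbind(as.vector(outer(ct, r)) + rep(cx, each = nc),
                 as.vector(outer(st, r)),
                 rep(z, each = nc))
  # ring j (0-based) starts at j*nc
  i <- seq_len(nc)
  inext <- c(i[-1L], i[1L])
  f1 <- f2 <- vector("list", na)
  for (j in seq_len(na) - 1L) {
    a <- j * nc + i
    b <- j * nc + inext
    c_ <- (j + 1L) * nc + i
    d <- (j + 1L) * nc + inext
    f1[[j + 1L]] <- cbind(a, b, c_)
    f2[[j + 1L]] <- cbind(b, d, c_)
  }
  tri_mesh(verts, rbind(do.call(rbind, f1), do.call(rbind, f2)), clean = FALSE)
}

#' Open right-cylinder test mesh
#'
#' @param radius radius, mm.
#' @param height height, mm.
#' @param circumferential_segments,axial_segments resolution (>= 3 around).
#' @param capped also emit planar end caps (fans), e.g. to exercise
#'   [strip_caps()].
#' @return A [tri_mesh] aligned with +z, base at z = 0.
#' @export
make_cylinder_mesh <- function(radius, height, circumferential_segments = 64,
                               axial_segments = 32, capped = FALSE) {
  if (radius <= 0 || height <= 0) stop("radius and height must be positive")
  nc <- as.integer(circumferential_segments)
  na <- as.integer(axial_segments)
  if (nc < 3L || na < 1L) stop("need >= 3 circumferential and >= 1 axial segments")
  mesh <- revolution_mesh(function(z) rep(radius, length(z)), height, nc, na)
  if (capped) {
    v <- mesh$vertices
    f <- mesh$faces
    nv <- nrow(v)
    bot <- seq_len(nc)                 # ring at z = 0
    top <- (na * nc) + seq_len(nc)     # ring at z = height
    v <- rbind(v, c(0, 0, 0), c(0, 0, height))
    cb <- nv + 1L
    ctp <- nv + 2L
    i <- seq_len(nc)
    inext <- c(i[-1L], i[1L])
    f <- rbind(f,
               cbind(bot[inext], bot[i], cb),     # downward-facing base
               cbind(top[i], top[inext], ctp))    # upward-facing top
    mesh <- tri_mesh(v, f, clean = FALSE)
  }
  mesh
}

#' UV-sphere test mesh
#'
#' Latitude/longitude sphere centred at the origin; closed (pole fans). Used
#' as an analytic oracle for area (4 pi r^2) and volume (4/3 pi r^3).
#'
#' @param radius radius, mm.
#' @param circumferential_segments,latitude_segments resolution.
#' @return A closed [tri_mesh].
#' @export
make_sphere_mesh <- function(radius, circumferential_segments = 128,
                             latitude_segments = 64) {
  if (radius <= 0) stop("radius must be positive")
  nc <- as.integer(circumferential_segments)
  nl <- as.integer(latitude_segments)
  if (nc < 3L || nl < 3L) stop("too few segments")
  phi <- seq(0, pi, length.out = nl + 1L)[2:nl]  # interior latitudes
  theta <- 2 * pi * (seq_len(nc) - 1L) / nc
  verts <- cbind(as.vector(outer(cos(theta), radius * sin(phi))),
                 as.vector(outer(sin(theta), radius * sin(phi))),
                 rep(radius * cos(phi), each = nc))
  npole <- c(0, 0, radius)
  spole <- c(0, 0, -radius)
  verts <- rbind(npole, verts, spole)
  np <- 1L
  sp <- nrow(verts)
  ring <- function(j) 1L + (j - 1L) * nc + seq_len(nc)  # j = 1..nl-1
  i <- seq_len(nc)
  inext <- c(i[-1L], i[1L])
  faces <- list(cbind(np, ring(1)[i], ring(1)[inext]))
  if (nl > 2L) {
    for (j in seq_len(nl - 2L)) {
      a <- ring(j)
      b <- ring(j + 1L)
      faces[[length(faces) + 1L]] <- cbind(a[i], b[i], a[inext])
      faces[[length(faces) + 1L]] <- cbind(a[inext], b[i], b[inext])
    }
  }
  last <- ring(nl - 1L)
  faces[[length(faces) + 1L]] <- cbind(sp, last[inext], last[i])
  tri_mesh(verts, do.call(rbind, faces), clean = FALSE)
}

#' Synthetic fusiform AAA lumen
#'
#' Surface of revolution `r(z) = neck_radius + (sac_radius - neck_radius) *
#' bump(z)` where `bump` is a C1 raised-cosine window centred at
#' `sac_center_frac` with full width `sac_length_frac` (fractions of height).
#' Open-ended; the maximal cross-section diameter equals `2 * sac_radius`.
#'
#' @param params an [anatomy_params()] object.
#' @return A [tri_mesh].
#' @export
make_aaa_mesh <- function(params) {
  validate_anatomy_params(params)
  h <- params$height
  rfun <- function(z) {
    u <- (z / h - params$sac_center_frac) / (params$sac_length_frac / 2)
    bump <- ifelse(abs(u) <= 1, 0.5 * (1 + cos(pi * u)), 0)
    params$neck_radius + (params$sac_radius - params$neck_radius) * bump
  }
  revolution_mesh(rfun, h, params$circumferential_segments,
                  params$axial_segments)
}

#' Synthetic bifurcated stent-graft lumen
#'
#' A single trunk of radius `neck_radius` occupying the proximal
#' `body_frac * height`, continued by two iliac limbs of radius `limb_radius`
#' diverging at `bifurcation_angle` down to the same total height, so the
#' graft always matches the aneurysm's axial extent. Limb circles start with
#' a 5% clearance at the bifurcation so the two limb surfaces never touch.
#' Long and short bodies differ only in `body_frac`.
#'
#' @param params an [anatomy_params()] object.
#' @param body `"long"` or `"short"`.
#' @return A [tri_mesh] (three open tube components: trunk + two limbs).
#' @export
make_stentgraft_mesh <- function(params, body = c("long", "short")) {
  body <- match.arg(body)
  validate_anatomy_params(params)
  if (params$bifurcation_angle < 0 || params$bifurcation_angle > 45) {
    stop("limbs would intersect at this bifurcation angle; ",
         "choose a smaller angle in [0, 45] degrees")
  }
  h <- params$height
  frac <- if (body == "long") params$graft_body_frac_long else
    params$graft_body_frac_short
  zb <- h * (1 - frac)                 # bifurcation plane (trunk above)
  nc <- params$circumferential_segments
  na <- params$axial_segments
  na_trunk <- max(8L, as.integer(round(na * frac)))
  na_limb <- max(8L, na - na_trunk)
  trunk <- revolution_mesh(function(z) rep(params$neck_radius, length(z)),
                           h - zb, nc, na_trunk, z0 = zb)
  half <- tan(params$bifurcation_angle / 2 * pi / 180)
  off <- function(z) 1.05 * params$limb_radius + half * (zb - z)
  limb <- function(sgn) {
    revolution_mesh(function(z) rep(params$limb_radius, length(z)),
                    zb, nc, na_limb, z0 = 0,
                    center_fun = function(z) sgn * off(z))
  }
  merge_meshes(list(trunk, limb(1), limb(-1)))
}

# Concatenate meshes into one tri_mesh (no vertex welding across parts unless
# coordinates coincide; cleaning merges exact duplicates only).
merge_meshes <- function(meshes) {
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices), integer(1))))
  verts <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  faces <- do.call(rbind, Map(function(m, o) m$faces + o, meshes,
                              offs[seq_along(meshes)]))
  tri_mesh(verts, faces, axis = meshes[[1]]$axis, clean = TRUE)
}

#' Specification of a synthetic cohort
#'
#' @param n_patients number of synthetic patients (>= 1).
#' @param seed integer RNG seed; per-patient streams are derived from it so a
#'   cohort is reproducible and insensitive to evaluation order.
#' @param param_jitter relative log-normal spread applied per patient to the
#'   dimensional anatomy parameters, in `[0, 0.5)`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 20, seed = 1, param_jitter = 0.08) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (param_jitter < 0 || param_jitter >= 0.5) {
    stop("param_jitter must be in [0, 0.5)")
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 param_jitter = param_jitter),
            class = "cohort_spec")
}

# Per-patient anatomy: multiplicative log-normal jitter on the dimensional
# parameters, one RNG stream per patient id.
jitter_params <- function(base, seed, patient_id, sigma) {
  if (sigma == 0) return(base)
  stream <- (as.numeric(seed) * 10007 + patient_id * 104729) %% 2147483647
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(stream))
  z <- stats::rnorm(4, 0, sigma)
  p <- unclass(base)
  p$neck_radius <- base$neck_radius * exp(z[1])
  p$sac_radius <- base$sac_radius * exp(z[2])
  p$height <- base$height * exp(z[3])
  p$limb_radius <- base$limb_radius * exp(z[4])
  # keep the anatomical ordering sac > neck > limb under extreme draws
  p$sac_radius <- max(p$sac_radius, 1.2 * p$neck_radius)
  p$limb_radius <- min(p$limb_radius, 0.9 * p$neck_radius)
  structure(p, class = "anatomy_params")
}

#' Generate a synthetic AAA / stent-graft cohort
#'
#' For each patient: a fusiform AAA lumen plus long-body (SL) and short-body
#' (SS) stent-graft lumens built from the same jittered parameters, so all
#' three share the axial height exactly.
#'
#' @param spec a [cohort_spec()].
#' @param base an [anatomy_params()] object used as the cohort centre.
#' @return A list of per-patient records, each with `patient_id`, `params`,
#'   and meshes `aaa`, `sl`, `ss`.
#' @export
make_cohort <- function(spec = cohort_spec(), base = anatomy_params()) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  validate_anatomy_params(base)
  lapply(seq_len(spec$n_patients), function(id) {
    p <- jitter_params(base, spec$seed, id, spec$param_jitter)
    list(patient_id = id,
         params = p,
         aaa = make_aaa_mesh(p),
         sl = make_stentgraft_mesh(p, "long"),
         ss = make_stentgraft_mesh(p, "short"))
  })
}

#' Write a cohort to STL files plus a manifest
#'
#' One STL per object, named `P{ID}_{AAA|SL|SS}.stl`, and a `manifest.csv`
#' recording the per-patient parameters and file names. ASCII STL (the
#' default) preserves coordinates at full double precision so that reloading
#' reproduces all geometric factors.
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if needed).
#' @param format STL flavour passed to [write_stl()].
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir, format = c("ascii", "binary")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(rec) {
    files <- sprintf("P%03d_%s.stl", rec$patient_id, c("AAA", "SL", "SS"))
    write_stl(rec$aaa, file.path(dir, files[1]), format = format)
    write_stl(rec$sl, file.path(dir, files[2]), format = format)
    write_stl(rec$ss, file.path(dir, files[3]), format = format)
    data.frame(patient_id = rec$patient_id,
               aaa_file = files[1], sl_file = files[2], ss_file = files[3],
               neck_radius = rec$params$neck_radius,
               sac_radius = rec$params$sac_radius,
               height = rec$params$height,
               limb_radius = rec$params$limb_radius,
               graft_body_frac_long = rec$params$graft_body_frac_long,
               graft_body_frac_short = rec$params$graft_body_frac_short,
               bifurcation_angle = rec$params$bifurcation_angle)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load a cohort previously written by [write_cohort()]
#'
#' @param manifest_path path to `manifest.csv` (STLs are read from the same
#'   directory).
#' @return A list of per-patient records with meshes `aaa`, `sl`, `ss`.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path)
  dir <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    list(patient_id = manifest$patient_id[i],
         params = NULL,
         aaa = read_stl(file.path(dir, manifest$aaa_file[i])),
         sl = read_stl(file.path(dir, manifest$sl_file[i])),
         ss = read_stl(file.path(dir, manifest$ss_file[i])))
  })
}
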
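#' Quasi-1D centreline tube from a lumen mesh
#'
#' Reduces a tube-like mesh to axial stations with an equivalent circular
#' radius `r = sqrt(A / pi)`, where `A` is the cross-section area of the mesh
#' slice at the station. Below a bifurcation the slice contains two limb
#' loops and `A` is their summed area, i.e. the limbs are pooled into one
#' equivalent tube. Stations sit at the centres of `n_stations` equal axial
#' bins, avoiding the open ends. The inlet is the proximal (maximum-axis) end.
#'
#' @param mesh a [tri_mesh].
#' @param n_stations number of axial stations (>= 3).
#' @return An object of class `centerline_tube`: `stations` (ascending axial
#'   positions, mm), `radii` (mm), `inlet_radius` (mm), `weights`
#'   (per-station lateral-area weights, mm^2).
#' @export
tube_from_mesh <- function(mesh, n_stations = 33) {
  stop_if_not_mesh(mesh)
  n_stations <- as.integer(n_stations)
  if (n_stations < 3L) stop("need at least 3 stations")
  proj <- as.vector(mesh$vertices %*% mesh$axis)
  rng <- range(proj)
  h <- diff(rng)
  dz <- h / n_stations
  z <- rng[1] + (seq_len(n_stations) - 0.5) * dz
  areas <- vapply(z, function(zi) slice_area(mesh, proj, zi), numeric(1))
  if (any(areas <= 0)) {
    stop("empty mesh slice at station(s) ",
         paste(which(areas <= 0), collapse = ", "))
  }
  radii <- sqrt(areas / pi)
  structure(list(stations = z, radii = radii,
                 inlet_radius = radii[n_stations],  # proximal end
                 dz = dz,
                 weights = 2 * pi * radii * dz),
            class = "centerline_tube")
}

#' @export
print.centerline_tube <- function(x, ...) {
  cat(sprintf("centerline_tube: %d stations, radii %.2f-%.2f mm, inlet %.2f mm\n",
              length(x$stations), min(x$radii), max(x$radii), x$inlet_radius))
  invisible(x)
}

# Signed in-plane cross-section area of the mesh slice at axial position z0.
# Each crossing triangle contributes one oriented segment; orienting segments
# along axis x facet-normal makes every closed slice loop counter-clockwise
# (outward normals assumed), so the shoelace sum gives the summed loop areas.
slice_area <- function(mesh, proj, z0) {
  f <- mesh$faces
  s <- proj[f] - z0
  dim(s) <- dim(f)
  s[s == 0] <- 1e-12             # deterministic tie-break onto the + side
  pos <- s > 0
  npos <- rowSums(pos)
  cross_f <- which(npos == 1L | npos == 2L)
  if (length(cross_f) == 0L) return(0)
  v <- mesh$vertices
  # in-plane 2D basis orthogonal to the axis
  ax <- mesh$axis
  ref <- if (abs(ax[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * ax) * ax
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  total <- 0
  n_all <- face_normals(mesh)
  for (k in cross_f) {
    vs <- f[k, ]
    sk <- s[k, ]
    lone <- if (npos[k] == 1L) which(sk > 0) else which(sk < 0)
    other <- setdiff(1:3, lone)
    p <- lapply(other, function(j) {
      t <- sk[lone] / (sk[lone] - sk[j])
      v[vs[lone], ] + t * (v[vs[j], ] - v[vs[lone], ])
    })
    a2 <- c(sum(p[[1]] * e1), sum(p[[1]] * e2))
    b2 <- c(sum(p[[2]] * e1), sum(p[[2]] * e2))
    # orient segment along axis x normal (CCW tangent of the slice loop)
    nk <- n_all[k, ]
    tg <- c(ax[2] * nk[3] - ax[3] * nk[2],
            ax[3] * nk[1] - ax[1] * nk[3],
            ax[1] * nk[2] - ax[2] * nk[1])
    tg2 <- c(sum(tg * e1), sum(tg * e2))
    if (sum((b2 - a2) * tg2) < 0) {
      tmp <- a2; a2 <- b2; b2 <- tmp
    }
    total <- total + 0.5 * (a2[1] * b2[2] - b2[1] * a2[2])
  }
  abs(total)
}

# Rabinowitsch-Mooney: for fully developed laminar pipe flow of a generalized
# Newtonian fluid, Q = (pi R^3 / tau_w^3) * int_0^tau_w tau^2 gdot(tau) dtau.
# Substituting tau = tau(g) turns the integral into
# int_0^gw tau(g)^2 g tau'(g) dg with gw the wall shear rate, all explicit.
# Returns the reduced flow parameter Gamma = 4 Q / (pi R^3) for wall shear
# rate gw (Gamma = gw exactly for a Newtonian fluid).
rm_reduced_flow <- function(gw, tau, dtau) {
  if (gw <= 0) return(0)
  f <- function(g) tau(g)^2 * g * dtau(g)
  val <- tryCatch(
    stats::integrate(f, 0, gw, rel.tol = 1e-10, abs.tol = 0,
                     subdivisions = 200L)$value,
    error = function(e) {
      # integrands with an endpoint derivative singularity (e.g. power law)
      # cannot reach 1e-10; retry at the solver's own tolerance
      stats::integrate(f, 0, gw, rel.tol = 1e-9, subdivisions = 200L)$value
    })
  4 * val / tau(gw)^3
}

# Solve Gamma(gw) = 4 Q / (pi R^3) for the wall shear rate by bracketed
# root-finding; relative tolerance 1e-8.
rm_wall_shear_rate <- function(gamma_target, tau, dtau) {
  if (gamma_target <= 0) return(0)
  f <- function(gw) rm_reduced_flow(gw, tau, dtau) - gamma_target
  lo <- gamma_target * 1e-2
  hi <- gamma_target * 1e2
  for (i in 1:12) {
    if (f(lo) <= 0) break
    lo <- lo / 10
  }
  for (i in 1:12) {
    if (f(hi) >= 0) break
    hi <- hi * 10
  }
  if (f(lo) > 0 || f(hi) < 0) {
    stop(sprintf(
      "no bracket for wall shear rate (target Gamma = %.4g, tried [%.3g, %.3g])",
      gamma_target, lo, hi))
  }
  stats::uniroot(f, c(lo, hi), tol = gamma_target * 1e-10)$root
}

#' Wall shear stress of steady laminar pipe flow
#'
#' Solves the Rabinowitsch-Mooney relation for the wall shear stress of fully
#' developed laminar flow of a generalized Newtonian fluid through a circular
#' pipe. The default fluid is the Quemada blood model from `rheo`; an
#' arbitrary monotone shear-stress law `tau_fun(gammadot)` (with optional
#' analytic derivative `dtau_fun`) may be supplied instead, e.g. a power law
#' for verification against its closed form.
#'
#' @param flow_rate volumetric flow rate, m^3/s (>= 0).
#' @param radius pipe radius, m (> 0).
#' @param rheo a [rheology_params()] object (ignored if `tau_fun` given).
#' @param tau_fun optional function: shear stress (Pa) of shear rate (1/s).
#' @param dtau_fun optional derivative of `tau_fun`; numerically
#'   differentiated when absent.
#' @return Wall shear stress in Pa; exactly 0 for zero flow.
#' @export
wall_shear_stress_tube <- function(flow_rate, radius, rheo = rheology_params(),
                                   tau_fun = NULL, dtau_fun = NULL) {
  if (flow_rate < 0) stop("flow_rate must be >= 0")
  if (radius <= 0) stop("radius must be > 0")
  if (flow_rate == 0) return(0)
  if (is.null(tau_fun)) {
    funs <- quemada_tau_funs(rheo)
    tau_fun <- funs$tau
    dtau_fun <- funs$dtau
  } else if (is.null(dtau_fun)) {
    dtau_fun <- function(g) {
      h <- pmax(1e-8 * g, 1e-300)
      (tau_fun(g + h) - tau_fun(pmax(g - h, 0))) / (h + pmin(g, h))
    }
  }
  gamma_target <- 4 * flow_rate / (pi * radius^3)
  gw <- rm_wall_shear_rate(gamma_target, tau_fun, dtau_fun)
  tau_fun(gw)
}

#' Instantaneous wall shear stress over the cardiac cycle
#'
#' Quasi-static surrogate for the pulsatile solve: at each waveform sample the
#' inlet velocity sets the flow rate `Q(t) = v(t) * pi * inlet_radius^2`;
#' incompressibility carries the same `Q` to every station, where the
#' steady-state Rabinowitsch-Mooney wall shear stress is evaluated for the
#' local equivalent radius. The series value is the lateral-area-weighted mean
#' of the station stresses. Reverse-flow samples use `|Q|`: WSS is reported as
#' a magnitude.
#'
#' Exact solves are run for up to 48 distinct reduced-flow values; beyond
#' that, exact solves on a 48-point logarithmic grid are interpolated with a
#' natural spline in log-log space (exact for Newtonian fluids, and orders of
#' magnitude below the solver tolerance for shear-thinning laws).
#'
#' @param tube a [tube_from_mesh()] result.
#' @param waveform a [make_waveform()] / [velocity_waveform()] object.
#' @param rheo a [rheology_params()] object.
#' @return An object of class `wss_series`: `times` (s), `wss` (Pa, spatial
#'   mean over the side surface), `dt` (s).
#' @export
wss_series <- function(tube, waveform, rheo = rheology_params()) {
  if (!inherits(tube, "centerline_tube")) stop("tube must be a centerline_tube")
  if (!inherits(waveform, "velocity_waveform")) {
    stop("waveform must be a velocity_waveform")
  }
  r_m <- tube$radii * 1e-3
  inlet_m <- tube$inlet_radius * 1e-3
  q <- abs(waveform$velocities) * pi * inlet_m^2          # m^3/s, magnitude
  gam <- as.vector(outer(4 * q / pi, 1 / r_m^3))          # reduced flow, all (t, station)
  funs <- quemada_tau_funs(rheo)
  tau_of_gamma <- rm_tau_map(gam, funs$tau, funs$dtau)
  tau <- matrix(tau_of_gamma(gam), nrow = length(q))      # t x station
  w <- tube$weights / sum(tube$weights)
  wss <- as.vector(tau %*% w)
  n <- length(waveform$times)
  dt <- if (n > 1) waveform$times[2] - waveform$times[1] else NA_real_
  structure(list(times = waveform$times, wss = wss, dt = dt,
                 kind = waveform$kind),
            class = "wss_series")
}

# Map from reduced flow Gamma to wall shear stress tau_w, exact for few
# distinct values, spline-accelerated (log-log, natural) for many.
rm_tau_map <- function(gam, tau, dtau, max_exact = 48L) {
  pos <- sort(unique(gam[gam > 0]))
  solve_one <- function(g) tau(rm_wall_shear_rate(g, tau, dtau))
  if (length(pos) == 0L) {
    return(function(g) rep(0, length(g)))
  }
  if (length(pos) <= max_exact) {
    tw <- vapply(pos, solve_one, numeric(1))
    return(function(g) {
      out <- numeric(length(g))
      nz <- g > 0
      out[nz] <- tw[match(g[nz], pos)]
      out
    })
  }
  grid <- exp(seq(log(min(pos)), log(max(pos)), length.out = max_exact))
  tw <- vapply(grid, solve_one, numeric(1))
  sf <- stats::splinefun(log(grid), log(tw), method = "natural")
  function(g) {
    out <- numeric(length(g))
    nz <- g > 0
    out[nz] <- exp(sf(log(g[nz])))
    out
  }
}

#' @export
print.wss_series <- function(x, ...) {
  cat(sprintf("wss_series ('%s'): %d steps, dt %.4g s, mean %.4g Pa, peak %.4g Pa\n",
              x$kind, length(x$wss), x$dt, mean(x$wss), max(x$wss)))
  invisible(x)
}

#' @export
plot.wss_series <- function(x, ...) {
  graphics::plot(x$times, x$wss, type = "l", xlab = "time [s]",
                 ylab = "wall shear stress [Pa]",
                 main = sprintf("WSS over cycle ('%s')", x$kind), ...)
  invisible(x)
}

#' Cycle-aggregated wall shear stress
#'
#' Arithmetic mean of the instantaneous WSS over the `n` uniform time steps of
#' one cardiac cycle — the time integral of the series divided by the period.
#'
#' @param series a [wss_series()] result.
#' @return Cycle-average WSS in Pa.
#' @export
wss_total <- function(series) {
  if (!inherits(series, "wss_series")) stop("series must be a wss_series")
  if (length(series$wss) == 0L) stop("empty WSS series")
  mean(series$wss)
}

#' Drag (pushing) force on a side surface
#'
#' Total tangential force `F = WSS_tot * A`, converting the side surface from
#' mm^2 to m^2 so the result is in newtons.
#'
#' @param series a [wss_series()] result.
#' @param side_surface side surface area in mm^2 (> 0).
#' @return Force in N (>= 0).
#' @export
drag_force <- function(series, side_surface) {
  if (side_surface <= 0) stop("side_surface must be > 0")
  wss_total(series) * side_surface * 1e-6
}
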
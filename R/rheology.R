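#' Quemada blood rheology parameters
#'
#' Shear-thinning generalized-Newtonian blood model
#' `mu = mu_p * (1 - 0.5 * k(g) * Hct)^(-2)` with the intrinsic viscosity
#' `k(g) = (k0 + k_inf * sqrt(g / gamma_c)) / (1 + sqrt(g / gamma_c))`
#' interpolating between its low-shear (`k0`, rouleaux aggregates) and
#' high-shear (`k_inf`, dispersed cells) limits around the critical shear
#' rate `gamma_c`. Defaults are literature-typical for whole blood at 40%
#' hematocrit, the value used for the modelled patients; density is constant
#' (incompressible flow).
#'
#' @param plasma_viscosity plasma viscosity, Pa s.
#' @param hematocrit red-cell volume fraction in `[0, 1)`.
#' @param k0 low-shear intrinsic viscosity (dimensionless).
#' @param k_inf high-shear intrinsic viscosity (dimensionless, <= k0).
#' @param gamma_c critical shear rate, 1/s.
#' @param density blood density, kg/m^3.
#' @return An object of class `rheology_params`.
#' @export
rheology_params <- function(plasma_viscosity = 1.2e-3,
                            hematocrit = 0.40,
                            k0 = 4.33,
                            k_inf = 2.07,
                            gamma_c = 1.88,
                            density = 1050) {
  if (plasma_viscosity <= 0) stop("plasma_viscosity must be > 0")
  if (hematocrit < 0 || hematocrit >= 1) stop("hematocrit must be in [0, 1)")
  if (!(k0 >= k_inf && k_inf > 0)) stop("need k0 >= k_inf > 0")
  if (gamma_c <= 0) stop("gamma_c must be > 0")
  if (density <= 0) stop("density must be > 0")
  if (0.5 * k0 * hematocrit >= 1) {
    stop("0.5 * k0 * hematocrit must be < 1 (viscosity finite at zero shear)")
  }
  structure(list(plasma_viscosity = plasma_viscosity, hematocrit = hematocrit,
                 k0 = k0, k_inf = k_inf, gamma_c = gamma_c, density = density),
            class = "rheology_params")
}

#' Quemada apparent viscosity
#'
#' @param shear_rate shear rate(s), 1/s (>= 0); vectorised.
#' @param rheo a [rheology_params()] object.
#' @return Apparent viscosity in Pa s (finite, > 0).
#' @export
quemada_viscosity <- function(shear_rate, rheo = rheology_params()) {
  if (!inherits(rheo, "rheology_params")) stop("rheo must be rheology_params")
  if (any(shear_rate < 0)) stop("shear_rate must be >= 0")
  s <- sqrt(shear_rate / rheo$gamma_c)
  k <- (rheo$k0 + rheo$k_inf * s) / (1 + s)
  rheo$plasma_viscosity * (1 - 0.5 * k * rheo$hematocrit)^(-2)
}

# Shear stress tau(g) = mu(g) * g for the Quemada law, plus its analytic
# derivative d tau / d g (needed by the Rabinowitsch-Mooney quadrature).
quemada_tau_funs <- function(rheo) {
  mu_p <- rheo$plasma_viscosity
  H <- rheo$hematocrit
  k0 <- rheo$k0
  ki <- rheo$k_inf
  gc <- rheo$gamma_c
  tau <- function(g) {
    s <- sqrt(g / gc)
    a <- 0.5 * H * (k0 + ki * s) / (1 + s)
    mu_p * g / (1 - a)^2
  }
  dtau <- function(g) {
    s <- sqrt(pmax(g, 0) / gc)
    a <- 0.5 * H * (k0 + ki * s) / (1 + s)
    # da/dg = 0.5 H (ki - k0) / (1+s)^2 * ds/dg, ds/dg = 1 / (2 sqrt(g gc))
    dadg <- ifelse(g > 0,
                   0.5 * H * (ki - k0) / (1 + s)^2 / (2 * sqrt(g * gc)),
                   0)
    mu_p * ((1 - a)^-2 + 2 * g * (1 - a)^-3 * dadg)
  }
  list(tau = tau, dtau = dtau)
}
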
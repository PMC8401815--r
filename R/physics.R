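#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

#' Boltzmann constant (J/K), 2019 SI exact value
#' @keywords internal
kB <- 1.380649e-23

#' Describe the suspending fluid
#'
#' A fluid medium is the triple (temperature, dynamic viscosity, density)
#' that every diffusivity and settling calculation needs. [water_medium()]
#' fills viscosity and density from temperature using the liquid-water
#' correlations, which is what you want for aqueous samples.
#'
#' @param temperature Absolute temperature (K).
#' @param viscosity Dynamic viscosity (Pa s).
#' @param density Fluid density (kg/m^3).
#' @return A `fluid_medium` object (named list).
#' @examples
#' fluid_medium(293.15, 1.002e-3, 998)
#' water_medium(293.15)
#' @export
fluid_medium <- function(temperature, viscosity, density) {
  if (!is.numeric(temperature) || temperature <= 0)
    abort("`temperature` must be a positive absolute temperature in K.")
  if (!is.numeric(viscosity) || viscosity <= 0)
    abort("`viscosity` must be a positive dynamic viscosity in Pa s.")
  if (!is.numeric(density) || density <= 0)
    abort("`density` must be a positive fluid density in kg/m^3.")
  structure(
    list(temperature = temperature, viscosity = viscosity, density = density),
    class = "fluid_medium"
  )
}

#' @rdname fluid_medium
#' @export
water_medium <- function(temperature = 293.15) {
  fluid_medium(temperature,
               viscosity = water_viscosity(temperature),
               density = water_density(temperature))
}

#' @export
print.fluid_medium <- function(x, ...) {
  cat(sprintf("<fluid_medium> T = %.2f K, eta = %.4g mPa s, rho_f = %.1f kg/m^3\n",
              x$temperature, 1e3 * x$viscosity, x$density))
  invisible(x)
}

#' Describe a (possibly hypothetical) particle
#'
#' @param radius Hydrodynamic radius (m).
#' @param density Particle density (kg/m^3).
#' @param label Material name.
#' @return A `particle_spec` object.
#' @examples
#' particle_spec(0.75e-6, 2930, "Alumina")
#' @export
particle_spec <- function(radius, density, label = NA_character_) {
  if (!is.numeric(radius) || any(radius <= 0))
    abort("`radius` must be a positive hydrodynamic radius in m.")
  if (!is.numeric(density) || any(density <= 0))
    abort("`density` must be a positive density in kg/m^3.")
  structure(list(radius = radius, density = density, label = label),
            class = "particle_spec")
}

#' Describe a gravity environment for observation planning
#'
#' Bundles a gravitational acceleration with the fluid the particles are
#' suspended in. [mission_environments()] lists the bodies shipped with the
#' package (Earth, Mars, Europa, Enceladus).
#'
#' @param name Body name, e.g. `"Earth"` or any name from
#'   [mission_environments()].
#' @param gravity Gravitational acceleration (m/s^2). Looked up by `name`
#'   when omitted.
#' @param fluid A [fluid_medium()]; liquid water at 20 degC by default.
#' @return A `mission_environment` object.
#' @examples
#' mission_environment("Earth")
#' mission_environment("Enceladus", fluid = water_medium(273.15 + 4))
#' @export
mission_environment <- function(name, gravity = NULL, fluid = water_medium()) {
  if (is.null(gravity)) {
    envs <- mission_environments()
    hit <- match(tolower(name), tolower(envs$body))
    if (is.na(hit))
      abort(sprintf("Unknown body '%s'; give `gravity` or one of: %s.",
                    name, paste(envs$body, collapse = ", ")))
    gravity <- envs$gravity_m_s2[hit]
  }
  if (!is.numeric(gravity) || gravity <= 0)
    abort("`gravity` must be a positive acceleration in m/s^2.")
  stopifnot(inherits(fluid, "fluid_medium"))
  structure(list(name = name, gravity = gravity, fluid = fluid),
            class = "mission_environment")
}

#' @export
print.mission_environment <- function(x, ...) {
  cat(sprintf("<mission_environment> %s, g = %.3f m/s^2\n", x$name, x$gravity))
  print(x$fluid)
  invisible(x)
}

# ---- liquid water properties ------------------------------------------------

#' Density of liquid water at atmospheric pressure
#'
#' Kell's (1975) rational polynomial for air-free water at 1 atm.
#'
#' @param temperature Absolute temperature (K); vectorised.
#' @return Density (kg/m^3).
#' @export
water_density <- function(temperature) {
  t <- temperature - 273.15
  (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 - 46.170461e-6 * t^3 +
      105.56302e-9 * t^4 - 280.54253e-12 * t^5) / (1 + 16.879850e-3 * t)
}

# IAPWS 2008 residual-viscosity coefficients H[i+1, j+1], i temperature power,
# j density power; zeros are structural.
.iapws_H <- local({
  H <- matrix(0, 6, 7)
  H[1, 1] <- 5.20094e-1;  H[2, 1] <- 8.50895e-2
  H[3, 1] <- -1.08374;    H[4, 1] <- -2.89555e-1
  H[1, 2] <- 2.22531e-1;  H[2, 2] <- 9.99115e-1
  H[3, 2] <- 1.88797;     H[4, 2] <- 1.26613;    H[6, 2] <- 1.20573e-1
  H[1, 3] <- -2.81378e-1; H[2, 3] <- -9.06851e-1
  H[3, 3] <- -7.72479e-1; H[4, 3] <- -4.89837e-1; H[5, 3] <- -2.57040e-1
  H[1, 4] <- 1.61913e-1;  H[2, 4] <- 2.57399e-1
  H[1, 5] <- -3.25372e-2; H[4, 5] <- 6.98452e-2
  H[5, 6] <- 8.72102e-3
  H[4, 7] <- -4.35673e-3; H[6, 7] <- -5.93264e-4
  H
})

#' Dynamic viscosity of liquid water
#'
#' IAPWS (2008) correlation for ordinary water, evaluated on the liquid
#' branch at atmospheric pressure: the dilute-gas term times the
#' finite-density term, with the density supplied by [water_density()].
#' The critical enhancement is negligible here and omitted. Reproduces
#' 1.0016 mPa s at 20 degC and 0.31417 mPa s at 90 degC.
#'
#' @param temperature Absolute temperature (K), between 263 and 373 K;
#'   vectorised.
#' @return Dynamic viscosity (Pa s).
#' @examples
#' water_viscosity(293.15) # ~1.0016e-3 Pa s
#' @export
water_viscosity <- function(temperature) {
  if (any(temperature < 263) || any(temperature > 373))
    abort("`temperature` outside the supported liquid-water range 263..373 K.")
  vapply(temperature, function(TK) {
    Tbar <- TK / 647.096
    rbar <- water_density(TK) / 322
    mu0 <- 100 * sqrt(Tbar) /
      sum(c(1.67752, 2.20462, 0.6366564, -0.241605) / Tbar^(0:3))
    s <- sum((1 / Tbar - 1)^(0:5) * (.iapws_H %*% (rbar - 1)^(0:6)))
    mu0 * exp(rbar * s) * 1e-6
  }, numeric(1))
}

# ---- Einstein / Stokes relations -------------------------------------------

#' Einstein-Stokes diffusion coefficient
#'
#' D = kB T / (6 pi eta r): the translational diffusivity of a sphere of
#' hydrodynamic radius r in a fluid of viscosity eta at temperature T.
#'
#' @param radius Particle radius (m); vectorised.
#' @param fluid A [fluid_medium()].
#' @return Diffusion coefficient (m^2/s).
#' @examples
#' diffusion_coefficient(1e-6, fluid_medium(293.15, 1.002e-3, 998)) # ~2.14e-13
#' @export
diffusion_coefficient <- function(radius, fluid) {
  if (any(radius <= 0)) abort("`radius` must be positive.")
  kB * fluid$temperature / (6 * pi * fluid$viscosity * radius)
}

#' Hydrodynamic radius from a measured diffusivity
#'
#' Exact inverse of [diffusion_coefficient()].
#'
#' @param D Diffusion coefficient (m^2/s); vectorised.
#' @inheritParams diffusion_coefficient
#' @return Radius (m).
#' @export
radius_from_diffusivity <- function(D, fluid) {
  if (any(D <= 0)) abort("`D` must be positive.")
  kB * fluid$temperature / (6 * pi * fluid$viscosity * D)
}

#' Brownian timescale to cover an RMS distance
#'
#' In one dimension tau_B = x_RMS^2 / (2 D); in two, (x^2 + y^2)_RMS / (4 D).
#'
#' @param rms_distance RMS distance to cover (m).
#' @param D Diffusion coefficient (m^2/s).
#' @param dimensions 1 or 2.
#' @return Time (s).
#' @export
brownian_time <- function(rms_distance, D, dimensions = 1) {
  if (any(rms_distance <= 0)) abort("`rms_distance` must be positive.")
  if (any(D <= 0)) abort("`D` must be positive.")
  if (!all(dimensions %in% c(1, 2)))
    abort("`dimensions` must be 1 or 2.")
  rms_distance^2 / (2 * dimensions * D)
}

#' Stokes settling (or rising) velocity
#'
#' v = 2 (rho_p - rho_f) g r^2 / (9 eta). Positive means sinking: the z axis
#' points downward throughout the physics layer.
#'
#' @param particle A [particle_spec()].
#' @param env A [mission_environment()].
#' @return Signed terminal velocity (m/s), positive = sinking.
#' @examples
#' env <- mission_environment("Earth", fluid = fluid_medium(293.15, 1.002e-3, 998))
#' stokes_velocity(particle_spec(0.75e-6, 998 + 1932), env) # ~2.36e-6 m/s
#' @export
stokes_velocity <- function(particle, env) {
  f <- env$fluid
  2 * (particle$density - f$density) * env$gravity * particle$radius^2 /
    (9 * f$viscosity)
}

#' Density difference from a measured axial velocity
#'
#' Inverts Stokes' law at known radius: rho_p - rho_f = 9 eta v / (2 g r^2).
#'
#' @param v Axial velocity (m/s), sinking positive; vectorised.
#' @param radius Particle radius (m).
#' @param env A [mission_environment()].
#' @return Density difference rho_p - rho_f (kg/m^3).
#' @export
density_diff_from_velocity <- function(v, radius, env) {
  if (any(radius <= 0)) abort("`radius` must be positive.")
  9 * env$fluid$viscosity * v / (2 * env$gravity * radius^2)
}

#' Gravitational timescale to traverse a distance
#'
#' tau_g = 9 eta d / (2 |rho_p - rho_f| g r^2) = d / |v_stokes|. Neutrally
#' buoyant particles never traverse: `Inf` is returned, not an error, so
#' sweeps over density grids keep going.
#'
#' @param distance Distance to traverse (m).
#' @inheritParams stokes_velocity
#' @return Time (s); `Inf` when rho_p = rho_f.
#' @export
gravity_time <- function(distance, particle, env) {
  if (any(distance <= 0)) abort("`distance` must be positive.")
  v <- abs(stokes_velocity(particle, env))
  ifelse(v == 0, Inf, distance / v)
}

#' Particle Strouhal number
#'
#' The ratio of the gravitational transit timescale to the Brownian
#' timescale over one particle radius,
#' Sr_p = 3 kB T / (4 pi |rho_p - rho_f| g r^4).
#' Sr_p >> 1 means Brownian-dominated motion, Sr_p << 1 gravity-dominated;
#' the two compete near Sr_p ~ 1. Sr_p is independent of viscosity and
#' linear in temperature, and falls off as the fourth power of radius.
#'
#' @inheritParams stokes_velocity
#' @return Dimensionless Strouhal number; `Inf` for neutral buoyancy.
#' @examples
#' env <- mission_environment("Earth", fluid = fluid_medium(293.15, 1.002e-3, 998))
#' strouhal_number(particle_spec(0.75e-6, 998 + 1932), env) # ~0.161
#' @export
strouhal_number <- function(particle, env) {
  drho <- abs(particle$density - env$fluid$density)
  ifelse(drho == 0, Inf,
         3 * kB * env$fluid$temperature /
           (4 * pi * drho * env$gravity * particle$radius^4))
}

#' Label the motion regime from a Strouhal number
#'
#' @param sr Strouhal number(s), >= 0.
#' @param lower,upper Regime thresholds around Sr ~ 1: below `lower` the
#'   motion is gravity-dominated, above `upper` Brownian-dominated.
#' @return Character vector in `c("gravity", "mixed", "brownian")`.
#' @export
motion_regime <- function(sr, lower = 0.1, upper = 10) {
  if (any(sr < 0, na.rm = TRUE)) abort("`sr` must be non-negative.")
  stopifnot(lower < upper)
  dplyr::case_when(
    is.na(sr) ~ NA_character_,
    sr < lower ~ "gravity",
    sr > upper ~ "brownian",
    TRUE ~ "mixed"
  )
}

#' Observation time needed to resolve a density difference
#'
#' The recording must last long enough for the axial drift to exceed the
#' axial resolution of the instrument: t = d_axial / |v_stokes|. Linear in
#' 1/g, so a body with 1% of Earth's gravity needs 100 times the time.
#'
#' @param delta_rho Density difference to resolve (kg/m^3).
#' @param radius Particle radius (m).
#' @param axial_resolution Axial resolution of the instrument (m).
#' @param env A [mission_environment()].
#' @return Required time (s); `Inf` at delta_rho = 0.
#' @export
required_observation_time <- function(delta_rho, radius, axial_resolution, env) {
  if (any(radius <= 0) || any(axial_resolution <= 0))
    abort("`radius` and `axial_resolution` must be positive.")
  v <- abs(2 * delta_rho * env$gravity * radius^2 / (9 * env$fluid$viscosity))
  ifelse(v == 0, Inf, axial_resolution / v)
}

#' Strouhal regime map over a radius x density grid
#'
#' Evaluates log10(Sr_p) on the outer grid of radii and particle densities
#' for one gravity environment — the regime map used to plan which particle
#' classes a mission can classify. Cells at the fluid density are `Inf`.
#'
#' @param radii Radii (m).
#' @param densities Particle densities (kg/m^3).
#' @param env A [mission_environment()].
#' @return Numeric matrix `length(radii)` x `length(densities)` of
#'   log10(Sr_p), with radii/densities as dimnames. See
#'   [write_strouhal_grid()] for the CSV form and [plot_strouhal_map()].
#' @export
strouhal_grid <- function(radii, densities, env) {
  if (length(radii) == 0 || length(densities) == 0)
    abort("`radii` and `densities` must be non-empty.")
  out <- outer(radii, densities, function(r, rho)
    log10(strouhal_number(particle_spec(r, rho), env)))
  dimnames(out) <- list(radius_m = format(radii, digits = 6),
                        density_kg_m3 = format(densities, digits = 6))
  out
}
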
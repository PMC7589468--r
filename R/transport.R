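#' Stokes-Einstein diffusivity of a spherical particle
#'
#' D = kB * T / (3 * pi * eta * d) for a sphere of diameter d in a fluid
#' of viscosity eta at absolute temperature T.
#'
#' @param diameter Particle diameter (m).
#' @param temperature Absolute temperature (K).
#' @param viscosity Dynamic viscosity (Pa s).
#' @return Diffusion coefficient (m^2/s).
#' @examples
#' stokes_einstein_diffusivity(150e-9, 298, 0.89e-3) # ~3.3e-12 m^2/s
#' @export
stokes_einstein_diffusivity <- function(diameter, temperature = 298,
                                        viscosity = 1.0e-3) {
  stopifnot(all(diameter > 0), all(temperature > 0), all(viscosity > 0))
  kb <- 1.380649e-23
  kb * temperature / (3 * pi * viscosity * diameter)
}

#' Transport context: fluid, particle and operating flow
#'
#' Bundles the quantities that determine particle transport: temperature,
#' viscosity, particle diameter (hence Stokes-Einstein diffusivity, which
#' may be overridden) and the device-level volumetric flow rate.
#'
#' The default fluid is a water-like plasma surrogate (eta = 1.0 mPa s at
#' 298 K): diluted or low-protein plasma behaves close to water at these
#' shear rates, and using a round value keeps derived quantities easy to
#' check by hand.
#'
#' @param flow_rate_ul_min Volumetric flow rate into the device (uL/min).
#' @param particle_diameter_nm Particle diameter (nm).
#' @param temperature_K Absolute temperature (K).
#' @param viscosity_Pa_s Dynamic viscosity (Pa s).
#' @param diffusivity Optional override of the Stokes-Einstein value
#'   (m^2/s).
#' @return An object of class `transport_context`.
#' @examples
#' transport_context(5)
#' @export
transport_context <- function(flow_rate_ul_min,
                              particle_diameter_nm = 150,
                              temperature_K = 298,
                              viscosity_Pa_s = 1.0e-3,
                              diffusivity = NULL) {
  stopifnot(is.finite(flow_rate_ul_min), flow_rate_ul_min >= 0,
            particle_diameter_nm > 0, temperature_K > 0, viscosity_Pa_s > 0)
  d <- particle_diameter_nm * 1e-9
  D <- diffusivity %||%
    stokes_einstein_diffusivity(d, temperature_K, viscosity_Pa_s)
  stopifnot(D > 0)
  structure(
    list(
      flow_rate = flow_rate_ul_min * 1e-9 / 60, # uL/min -> m^3/s
      flow_rate_ul_min = flow_rate_ul_min,
      particle_diameter = d,
      temperature = temperature_K,
      viscosity = viscosity_Pa_s,
      diffusivity = D
    ),
    class = "transport_context"
  )
}

#' @export
print.transport_context <- function(x, ...) {
  cat(sprintf(
    "<transport_context> Q = %.4g uL/min, d = %.4g nm, T = %.4g K, eta = %.4g mPa s, D = %.4g m^2/s\n",
    x$flow_rate_ul_min, x$particle_diameter * 1e9, x$temperature,
    x$viscosity * 1e3, x$diffusivity
  ))
  invisible(x)
}

#' Plane-Poiseuille velocity profile
#'
#' Pressure-driven flow between parallel plates a distance `gap` apart:
#' u(y) = 6 u_mean (y/gap)(1 - y/gap). Zero at both walls (no slip),
#' 1.5 u_mean at the centreline.
#'
#' @param y Lateral position(s) in `[0, gap]` (m).
#' @param gap Plate separation (m).
#' @param mean_velocity Cross-sectional mean velocity u_mean (m/s).
#' @return Local velocity (m/s), vectorized over `y`.
#' @export
poiseuille_velocity <- function(y, gap, mean_velocity) {
  stopifnot(gap > 0)
  if (any(y < 0 | y > gap)) {
    stop("`y` must lie within [0, gap]", call. = FALSE)
  }
  z <- y / gap
  6 * mean_velocity * z * (1 - z)
}

#' Mean interstitial velocity in a device
#'
#' Volumetric flow divided by the open cross-section between pillars.
#' For a parallel device the flow is split evenly, so the per-bed
#' velocity equals Q / n_beds divided by the single-bed open area
#' (identical to Q over the summed area).
#'
#' @param ctx A [transport_context()].
#' @param device A `device_geometry` or `bed_geometry`.
#' @return Mean velocity (m/s).
#' @export
mean_interstitial_velocity <- function(ctx, device) {
  area <- open_cross_section(device)
  if (area <= 0) stop("open cross-section must be positive", call. = FALSE)
  ctx$flow_rate / area
}

#' Brownian displacement over one time step
#'
#' Each component is sqrt(2 D dt) times an independent standard normal
#' draw; longitudinal (x) and lateral (y) diffusion are both active.
#'
#' @param D Diffusion coefficient (m^2/s).
#' @param dt Time step (s).
#' @param n Number of steps to draw.
#' @return A tibble with columns `dx`, `dy` (m).
#' @export
brownian_step <- function(D, dt, n = 1) {
  stopifnot(D >= 0, dt > 0, n >= 1)
  s <- sqrt(2 * D * dt)
  tibble::tibble(dx = s * stats::rnorm(n), dy = s * stats::rnorm(n))
}
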
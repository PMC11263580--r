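# Physical constants (SI). Everything internal to the package is strict SI:
# Pa, m, s, K, particles per m^3. Unit helpers below convert at the I/O edge.
.kB <- 1.380649e-23      # Boltzmann constant, J/K (2019 SI definition)
.N_AVOGADRO <- 6.02214076e23  # 1/mol

.check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single positive finite number", call. = FALSE)
  }
  invisible(x)
}

#' Fluid environment
#'
#' Viscosity and temperature of the carrier fluid. Defaults are water at room
#' temperature (eta = 1e-3 Pa s, T = 295 K).
#'
#' @param viscosity Dynamic viscosity in Pa s.
#' @param temperature Absolute temperature in K.
#' @return An object of class `fluid_env`.
#' @export
#' @examples
#' fluid_env()                  # water at 295 K
#' fluid_env(temperature = 310) # body temperature
fluid_env <- function(viscosity = 1e-3, temperature = 295) {
  .check_positive_scalar(viscosity, "viscosity")
  .check_positive_scalar(temperature, "temperature")
  structure(list(viscosity = viscosity, temperature = temperature),
            class = "fluid_env")
}

#' Cylindrical pore geometry
#'
#' Radius and length of a cylindrical nanopore, in metres. The long-channel
#' (Poiseuille) regime assumed throughout requires length >= radius.
#'
#' @param radius Pore radius in m.
#' @param length Pore length in m.
#' @return An object of class `pore_geometry`.
#' @export
#' @examples
#' pore_geometry(radius = 100e-9, length = 10e-6) # a "200 nm" track-etched pore
pore_geometry <- function(radius, length) {
  .check_positive_scalar(radius, "radius")
  .check_positive_scalar(length, "length")
  if (length < radius) {
    stop("`length` must be >= `radius` (long-channel Poiseuille regime)",
         call. = FALSE)
  }
  structure(list(radius = radius, length = length), class = "pore_geometry")
}

#' Particle (virus) parameters
#'
#' @param hydrodynamic_radius Hydrodynamic radius in m (as measured by NTA or
#'   DLS), used in the Stokes-Einstein diffusion coefficient.
#' @param label Free-text label for the particle.
#' @return An object of class `virus_params`.
#' @export
virus_params <- function(hydrodynamic_radius, label = "") {
  .check_positive_scalar(hydrodynamic_radius, "hydrodynamic_radius")
  structure(list(hydrodynamic_radius = hydrodynamic_radius,
                 label = as.character(label)[1L]),
            class = "virus_params")
}

#' Hydraulic resistance of a cylindrical pore
#'
#' R_h = 8 eta L / (pi R^4): the pressure-to-volumetric-flow ratio of a long
#' cylindrical channel under Poiseuille flow.
#'
#' @param geom A [pore_geometry()].
#' @param fluid A [fluid_env()].
#' @return Hydraulic resistance in Pa s m^-3.
#' @export
#' @examples
#' hydraulic_resistance(pore_geometry(100e-9, 10e-6), fluid_env()) # ~2.5e20
hydraulic_resistance <- function(geom, fluid) {
  stopifnot(inherits(geom, "pore_geometry"), inherits(fluid, "fluid_env"))
  8 * fluid$viscosity * geom$length / (pi * geom$radius^4)
}

#' Mean Poiseuille flow speed in the pore
#'
#' v = P / (pi R^2 R_h) = P R^2 / (8 eta L): the flux-averaged speed at an
#' applied pressure difference P. Linear in P; vectorized over `pressure`.
#'
#' @param pressure Applied pressure difference in Pa (>= 0).
#' @inheritParams hydraulic_resistance
#' @return Flow speed in m/s.
#' @export
flow_speed <- function(pressure, geom, fluid) {
  stopifnot(inherits(geom, "pore_geometry"), inherits(fluid, "fluid_env"))
  if (any(!is.finite(pressure)) || any(pressure < 0)) {
    stop("`pressure` must be finite and >= 0", call. = FALSE)
  }
  pressure * geom$radius^2 / (8 * fluid$viscosity * geom$length)
}

#' Advection time through the pore
#'
#' t_adv = L / v = 8 eta L^2 / (P R^2): the time for a particle carried by the
#' mean flow to traverse the channel.
#'
#' @param pressure Applied pressure difference in Pa (> 0).
#' @inheritParams hydraulic_resistance
#' @return Advection time in s.
#' @export
#' @examples
#' # ~0.1 s for a 10 um long, 200 nm diameter pore at 800 Pa in water
#' advection_time(800, pore_geometry(100e-9, 10e-6), fluid_env())
advection_time <- function(pressure, geom, fluid) {
  if (any(!is.finite(pressure)) || any(pressure <= 0)) {
    stop("`pressure` must be finite and > 0 (advection time diverges at P = 0)",
         call. = FALSE)
  }
  geom$length / flow_speed(pressure, geom, fluid)
}

#' Stokes-Einstein diffusion coefficient
#'
#' D = k_B T / (6 pi eta R_particle).
#'
#' @param virus A [virus_params()].
#' @param fluid A [fluid_env()].
#' @return Diffusion coefficient in m^2/s.
#' @export
diffusion_coefficient <- function(virus, fluid) {
  stopifnot(inherits(virus, "virus_params"), inherits(fluid, "fluid_env"))
  .kB * fluid$temperature /
    (6 * pi * fluid$viscosity * virus$hydrodynamic_radius)
}

#' Diffusion time over the pore length
#'
#' t_diff = L^2 / D: the diffusive timescale over the channel length, the
#' natural comparison for clog-formation transients.
#'
#' @inheritParams hydraulic_resistance
#' @inheritParams diffusion_coefficient
#' @return Diffusion time in s.
#' @export
diffusion_time <- function(geom, virus, fluid) {
  geom$length^2 / diffusion_coefficient(virus, fluid)
}

#' Peclet number over the pore length
#'
#' Pe = t_diff / t_adv = v L / D. Pe > 1 means transport through the channel
#' is advection-dominated. The pore length L is used as the length scale
#' because the advection/diffusion comparison is made over the channel.
#'
#' @inheritParams advection_time
#' @inheritParams diffusion_coefficient
#' @return Dimensionless Peclet number.
#' @export
peclet_number <- function(pressure, geom, virus, fluid) {
  flow_speed(pressure, geom, fluid) * geom$length /
    diffusion_coefficient(virus, fluid)
}

# ---- unit helpers ---------------------------------------------------------

#' Concentration unit conversions
#'
#' The package works internally in particles per m^3; experimental tables use
#' particles per mL and dissociation constants are quoted in molar units.
#'
#' @param x Numeric vector of concentrations.
#' @return Converted numeric vector.
#' @name unit-conversions
NULL

#' @rdname unit-conversions
#' @export
per_ml_to_per_m3 <- function(x) x * 1e6

#' @rdname unit-conversions
#' @export
per_m3_to_per_ml <- function(x) x * 1e-6

#' @rdname unit-conversions
#' @export
molar_to_per_m3 <- function(x) x * .N_AVOGADRO * 1e3

#' @rdname unit-conversions
#' @export
per_m3_to_molar <- function(x) x / (.N_AVOGADRO * 1e3)
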
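# The soft-jamming forward model. A translocation decomposes into an entry
# time gated by Langmuir occupancy of the pore mouth by clog-bound particles,
# and a transit time set by the competition between wall adhesion and
# advection. Fundamental parameters are (kon_pore, koff_clog, kd_clog);
# the prefactor k and critical pressure P_c are derived, never stored.

#' Jamming interaction parameters
#'
#' The three interaction parameters of the soft-jamming model:
#' * `kon_pore` (1/s): characteristic rate at which a particle sticks to the
#'   pore's central channel wall.
#' * `koff_clog` (1/s): rate at which a particle detaches from the clog,
#'   freeing the pore mouth.
#' * `kd_clog` (particles/m^3): dissociation constant between a free particle
#'   and the clog; sets the Langmuir occupancy C/(C + K_d).
#'
#' @param kon_pore Wall sticking on-rate, 1/s.
#' @param koff_clog Clog detachment rate, 1/s.
#' @param kd_clog Clog dissociation constant, particles/m^3 (use
#'   [molar_to_per_m3()] for molar input).
#' @return An object of class `jamming_params`.
#' @export
#' @examples
#' jamming_params(kon_pore = 0.625, koff_clog = 1.2e-4,
#'                kd_clog = molar_to_per_m3(1.5e-13))
jamming_params <- function(kon_pore, koff_clog, kd_clog) {
  .check_positive_scalar(kon_pore, "kon_pore")
  .check_positive_scalar(koff_clog, "koff_clog")
  .check_positive_scalar(kd_clog, "kd_clog")
  structure(list(kon_pore = kon_pore, koff_clog = koff_clog,
                 kd_clog = kd_clog),
            class = "jamming_params")
}

.kon_of <- function(params) {
  if (inherits(params, "jamming_params")) params$kon_pore else params
}

#' Critical pressure of the jamming model
#'
#' P_c = 8 eta k_on L^2 / R^2: the pressure below which wall adhesion
#' outcompetes advection over the channel length and pore exit is suppressed.
#'
#' @param params A [jamming_params()] object, or a bare numeric wall on-rate
#'   in 1/s (convenient for wall-only particles such as amino beads).
#' @inheritParams hydraulic_resistance
#' @return Critical pressure in Pa.
#' @export
#' @examples
#' critical_pressure(0.625, pore_geometry(100e-9, 10e-6), fluid_env()) # 50 Pa
critical_pressure <- function(params, geom, fluid) {
  kon <- .kon_of(params)
  8 * fluid$viscosity * kon * geom$length^2 / geom$radius^2
}

#' Wall on-rate from a measured critical pressure
#'
#' Inverts the critical-pressure relation: k_on = P_c R^2 / (8 eta L^2).
#' Round-trips with [critical_pressure()] to machine precision.
#'
#' @param pc Critical pressure in Pa (> 0).
#' @inheritParams hydraulic_resistance
#' @return Wall on-rate in 1/s.
#' @export
kon_from_critical_pressure <- function(pc, geom, fluid) {
  if (any(!is.finite(pc)) || any(pc <= 0)) {
    stop("`pc` must be finite and > 0", call. = FALSE)
  }
  pc * geom$radius^2 / (8 * fluid$viscosity * geom$length^2)
}

#' Frequency prefactor k
#'
#' k = pi k_on C L R^2: the rate scale of the transit-time branch; linear in
#' the upstream concentration C.
#'
#' @inheritParams critical_pressure
#' @param concentration Upstream particle concentration in particles/m^3.
#' @param geom A [pore_geometry()].
#' @return Prefactor in 1/s.
#' @export
prefactor_k <- function(params, concentration, geom) {
  kon <- .kon_of(params)
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    stop("`concentration` must be finite and >= 0", call. = FALSE)
  }
  if (any(concentration == 0)) {
    warning("concentration of 0: prefactor k is 0 and the transit time is undefined",
            call. = FALSE)
  }
  pi * kon * concentration * geom$length * geom$radius^2
}

#' Entry time (Langmuir-gated pore admission)
#'
#' tau_1(C) = (1/k_off) * C / (C + K_d): the mean wait for the pore mouth to
#' be free of clog-bound particles. Increases with C and saturates at
#' 1/k_off; independent of pressure.
#'
#' @inheritParams prefactor_k
#' @param params A [jamming_params()].
#' @return Entry time in s.
#' @export
entry_time <- function(params, concentration) {
  stopifnot(inherits(params, "jamming_params"))
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    stop("`concentration` must be finite and >= 0", call. = FALSE)
  }
  (1 / params$koff_clog) * concentration / (concentration + params$kd_clog)
}

# alpha(P) = (P_c/P) exp(P_c/P): the dimensionless adhesion-advection factor.
.alpha_factor <- function(pc, pressure) {
  r <- pc / pressure
  r * exp(r)
}

#' Transit time through the pore channel
#'
#' tau_2(C, P) = (1/k) (P_c/P) exp(P_c/P): the mean time to cross the channel
#' against wall adhesion, where k = pi k_on C L R^2. Strictly decreasing in P.
#'
#' @inheritParams prefactor_k
#' @param pressure Applied pressure in Pa (> 0).
#' @param fluid A [fluid_env()].
#' @return Transit time in s.
#' @export
transit_time <- function(params, pressure, concentration, geom, fluid) {
  if (any(!is.finite(pressure)) || any(pressure <= 0)) {
    stop("`pressure` must be finite and > 0 (transit time diverges at P = 0)",
         call. = FALSE)
  }
  if (any(concentration <= 0)) {
    stop("`concentration` must be > 0 for a finite transit time", call. = FALSE)
  }
  k <- prefactor_k(params, concentration, geom)
  pc <- critical_pressure(params, geom, fluid)
  .alpha_factor(pc, pressure) / k
}

#' Translocation frequency of the soft-jamming model
#'
#' f(C, P) = 1 / (tau_1(C) + tau_2(C, P)). Rises with pressure towards a
#' concentration-dependent plateau k_off (C + K_d)/C; at low concentration it
#' reduces to free advective transport attenuated by wall adhesion.
#'
#' Vectorized over `pressure` and `concentration` (recycled to a common
#' length).
#'
#' @inheritParams transit_time
#' @return Translocation frequency in 1/s.
#' @export
#' @examples
#' geom <- pore_geometry(100e-9, 10e-6); fl <- fluid_env()
#' pars <- jamming_params(0.625, 1.2e-4, molar_to_per_m3(1.5e-13))
#' translocation_frequency(pars, 800, per_ml_to_per_m3(1e8), geom, fl)
translocation_frequency <- function(params, pressure, concentration, geom, fluid) {
  1 / (entry_time(params, concentration) +
         transit_time(params, pressure, concentration, geom, fluid))
}

#' Stationary in-pore concentration profile
#'
#' C_n(x) = C exp(-k_on x / v): the depletion of free particles along the
#' channel when wall adhesion (rate k_on) competes with advection at speed v.
#' At x = L the survival factor equals exp(-P_c/P), the factor appearing in
#' the transit time.
#'
#' @inheritParams transit_time
#' @param x Position along the channel in m, within \[0, L\].
#' @return Concentration in particles/m^3.
#' @export
pore_concentration_profile <- function(params, pressure, concentration, geom,
                                       fluid, x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > geom$length)) {
    stop("`x` must lie within [0, L]", call. = FALSE)
  }
  v <- flow_speed(pressure, geom, fluid)
  concentration * exp(-.kon_of(params) * x / v)
}

#' Translocation frequency for wall-adhering beads (no self-interaction)
#'
#' Particles that stick to the pore wall but not to each other (amino-
#' functionalized beads) have tau_1 = 0, so f = 1/tau_2 =
#' k (P/P_c) exp(-P_c/P): an apparent critical pressure followed by a linear
#' regime, with no plateau and frequency increasing with concentration.
#'
#' @param kon_pore Wall on-rate in 1/s.
#' @inheritParams transit_time
#' @return Frequency in 1/s.
#' @export
amino_bead_frequency <- function(kon_pore, pressure, concentration, geom, fluid) {
  if (any(!is.finite(pressure)) || any(pressure <= 0)) {
    stop("`pressure` must be finite and > 0", call. = FALSE)
  }
  k <- prefactor_k(kon_pore, concentration, geom)
  pc <- critical_pressure(kon_pore, geom, fluid)
  k * (pressure / pc) * exp(-pc / pressure)
}

#' Translocation frequency for non-interacting beads
#'
#' Purely advective transport (carboxyl-functionalized beads): f = C v pi R^2,
#' linear in both pressure and concentration.
#'
#' @inheritParams transit_time
#' @return Frequency in 1/s.
#' @export
carboxyl_bead_frequency <- function(pressure, concentration, geom, fluid) {
  concentration * flow_speed(pressure, geom, fluid) * pi * geom$radius^2
}

#' Master-curve transform
#'
#' Rescales measured (or synthetic) frequency points into the model's
#' dimensionless master-curve coordinates: x = C/(C + K_d) and
#' y = (k_off/k)(k tau - alpha) with tau = 1/f and
#' alpha = (P_c/P) exp(P_c/P). Under the model, y = k_off tau_1 = x exactly,
#' so noiseless data from any geometry, particle or condition collapse onto
#' the identity line.
#'
#' Points with non-positive frequency are dropped with a warning; points at
#' C = 0 map to (0, 0) by continuity.
#'
#' @param curve A data frame with columns `pressure`, `concentration`,
#'   `frequency` (SI units), e.g. a [frequency_curve()].
#' @param params Fitted [jamming_params()].
#' @inheritParams transit_time
#' @return A data.frame with columns `x`, `y`, `alpha`.
#' @export
master_curve_points <- function(curve, params, geom, fluid) {
  stopifnot(is.data.frame(curve),
            all(c("pressure", "concentration", "frequency") %in% names(curve)))
  bad <- curve$frequency <= 0 & curve$concentration > 0
  if (any(bad)) {
    warning(sum(bad), " point(s) with non-positive frequency dropped from the master curve",
            call. = FALSE)
    curve <- curve[!bad, , drop = FALSE]
  }
  pc <- critical_pressure(params, geom, fluid)
  alpha <- .alpha_factor(pc, curve$pressure)
  x <- curve$concentration / (curve$concentration + params$kd_clog)
  y <- numeric(nrow(curve))
  pos <- curve$concentration > 0
  if (any(pos)) {
    k <- prefactor_k(params, curve$concentration[pos], geom)
    tau <- 1 / curve$frequency[pos]
    y[pos] <- (params$koff_clog / k) * (k * tau - alpha[pos])
  }
  data.frame(x = x, y = y, alpha = alpha)
}
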
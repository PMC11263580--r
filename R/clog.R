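# The clog probe: suction-model DNA translocation used as a caliper for the
# open lumen of a clogged pore, the exponential clog-formation transient, and
# derived quantities (effective in-pore concentration, corrected K_d,
# adhesion energy barrier).

#' Suction-model parameters
#'
#' @param f_suc Frequency prefactor in 1/s. Treated purely as a fit
#'   parameter: under the model the frequency at P = P_suc is f_suc/e.
#' @param p_suc Critical suction pressure in Pa, at which the energetic cost
#'   of polymer confinement is balanced by the work of the flow.
#' @return An object of class `suction_params`.
#' @export
suction_params <- function(f_suc, p_suc) {
  .check_positive_scalar(f_suc, "f_suc")
  .check_positive_scalar(p_suc, "p_suc")
  structure(list(f_suc = f_suc, p_suc = p_suc), class = "suction_params")
}

#' Clog layer structure
#'
#' An annular particle layer of thickness `layer_thickness` (R_e) lining a
#' pore of radius `pore_radius` (R), leaving an open cylindrical lumen of
#' radius R - R_e.
#'
#' @param layer_thickness Layer thickness R_e in m, in \[0, R).
#' @param pore_radius Pore radius R in m.
#' @return An object of class `clog_structure`.
#' @export
clog_structure <- function(layer_thickness, pore_radius) {
  .check_positive_scalar(pore_radius, "pore_radius")
  if (!is.numeric(layer_thickness) || length(layer_thickness) != 1L ||
      !is.finite(layer_thickness) || layer_thickness < 0 ||
      layer_thickness >= pore_radius) {
    stop("`layer_thickness` must lie in [0, pore_radius)", call. = FALSE)
  }
  structure(list(layer_thickness = layer_thickness, pore_radius = pore_radius),
            class = "clog_structure")
}

#' Clog-formation trace
#'
#' A frequency-contrast transient (f(t) - f_inf)/(f_0 - f_inf) recorded after
#' flushing the clog out at high pressure; decays from ~1 towards 0 as the
#' clog re-forms.
#'
#' @param times Sampling times in s: non-negative, strictly increasing.
#' @param contrast Dimensionless frequency contrast at each time.
#' @param f0 Translocation frequency at t = 0 (clog-free), 1/s.
#' @param f_inf Steady-state frequency (clog formed), 1/s.
#' @return An object of class `clog_trace`.
#' @export
clog_trace <- function(times, contrast, f0 = NA_real_, f_inf = NA_real_) {
  if (length(times) != length(contrast)) {
    stop("`times` and `contrast` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times < 0) || any(diff(times) <= 0)) {
    stop("`times` must be non-negative and strictly increasing", call. = FALSE)
  }
  if (abs(contrast[1L] - 1) > 0.5) {
    warning("contrast at the first time point is far from 1; is this a contrast trace?",
            call. = FALSE)
  }
  structure(list(times = as.numeric(times), contrast = as.numeric(contrast),
                 f0 = f0, f_inf = f_inf),
            class = "clog_trace")
}

#' Suction-model DNA translocation frequency
#'
#' f_DNA(P) = f_suc (P/P_suc) exp(-P_suc/P): barrier-crossing frequency for
#' flow-driven polymer translocation. Strictly increasing in P; extended
#' continuously to 0 at P = 0.
#'
#' @param p A [suction_params()].
#' @param pressure Applied pressure in Pa (>= 0); vectorized.
#' @return Frequency in 1/s.
#' @export
dna_frequency <- function(p, pressure) {
  stopifnot(inherits(p, "suction_params"))
  if (any(!is.finite(pressure)) || any(pressure < 0)) {
    stop("`pressure` must be finite and >= 0", call. = FALSE)
  }
  out <- numeric(length(pressure))
  pos <- pressure > 0
  out[pos] <- p$f_suc * (pressure[pos] / p$p_suc) * exp(-p$p_suc / pressure[pos])
  out
}

#' Critical suction pressure from pore geometry
#'
#' P_suc = J_c R_h with the critical flow J_c = k_B T / eta and
#' R_h = 8 eta L / (pi R^4), so P_suc = 8 k_B T L / (pi R^4): viscosity
#' cancels.
#'
#' @inheritParams hydraulic_resistance
#' @return Critical suction pressure in Pa.
#' @export
#' @examples
#' suction_critical_pressure(pore_geometry(100e-9, 10e-6), fluid_env()) # ~1 kPa
suction_critical_pressure <- function(geom, fluid) {
  (.kB * fluid$temperature / fluid$viscosity) * hydraulic_resistance(geom, fluid)
}

#' Clog layer thickness from paired suction probes
#'
#' Comparing the critical suction pressure of a naked pore (P_suc) and of the
#' same pore clogged with particles (P_suc^virus), and assuming a compact
#' annular layer with Poiseuille flow through the open lumen, the layer
#' thickness is R_e = R (1 - (P_suc^virus / P_suc)^(-1/4)).
#'
#' @param p_suc_naked Critical suction pressure of the naked pore, Pa.
#' @param p_suc_virus Critical suction pressure of the clogged pore, Pa
#'   (>= `p_suc_naked`: a clogged pore cannot have lower resistance).
#' @param geom A [pore_geometry()].
#' @return A [clog_structure()].
#' @export
#' @examples
#' # a pressure ratio of 16 means the layer fills half the radius
#' clog_thickness(1000, 16000, pore_geometry(100e-9, 10e-6))
clog_thickness <- function(p_suc_naked, p_suc_virus, geom) {
  .check_positive_scalar(p_suc_naked, "p_suc_naked")
  .check_positive_scalar(p_suc_virus, "p_suc_virus")
  ratio <- p_suc_virus / p_suc_naked
  if (ratio < 1) {
    stop("`p_suc_virus` < `p_suc_naked`: a clogged pore cannot have a lower ",
         "hydraulic resistance than the naked pore", call. = FALSE)
  }
  re <- geom$radius * (1 - ratio^(-0.25))
  # ratio -> Inf gives re -> R; clog_structure requires re < R strictly
  re <- min(re, geom$radius * (1 - 1e-12))
  clog_structure(layer_thickness = re, pore_radius = geom$radius)
}

#' Effective particle concentration inside the clogged pore
#'
#' With an annular layer of thickness R_e, the particle volume in the pore is
#' V = pi R^2 L (1 - (1 - R_e/R)^2); dividing by the particle volume
#' (4/3) pi R_virus^3 and the pore volume pi R^2 L gives the effective
#' number concentration C_n = (1 - (1 - R_e/R)^2) / ((4/3) pi R_virus^3),
#' which depends only on R_e/R and the particle radius.
#'
#' @param clog A [clog_structure()].
#' @param virus A [virus_params()].
#' @return Effective concentration in particles/m^3.
#' @export
effective_pore_concentration <- function(clog, virus) {
  stopifnot(inherits(clog, "clog_structure"), inherits(virus, "virus_params"))
  frac <- 1 - (1 - clog$layer_thickness / clog$pore_radius)^2
  frac / ((4 / 3) * pi * virus$hydrodynamic_radius^3)
}

#' Dissociation constant corrected for in-pore concentration
#'
#' The dissociation constant fitted against the upstream concentration scale
#' is rescaled to the effective in-pore concentration:
#' K_d^corrected = K_d * (C_pore / C_upstream).
#'
#' @param kd_clog Fitted dissociation constant (any unit; typically molar).
#' @param upstream_c Upstream concentration, particles/m^3.
#' @param pore_c Effective in-pore concentration, particles/m^3.
#' @return Corrected dissociation constant, same unit as `kd_clog`.
#' @export
corrected_kd <- function(kd_clog, upstream_c, pore_c) {
  .check_positive_scalar(kd_clog, "kd_clog")
  .check_positive_scalar(upstream_c, "upstream_c")
  .check_positive_scalar(pore_c, "pore_c")
  kd_clog * pore_c / upstream_c
}

#' Adhesion energy barrier from the wall on-rate
#'
#' Interpreting the wall on-rate as barrier crossing,
#' k_on = nu exp(-dF*/k_B T) with attempt rate nu, the barrier is
#' dF* = ln(nu / k_on) in units of k_B T. The attempt rate is not fixed by
#' the transport data; the default of 1e3 1/s is configurable and is recorded
#' in the `attempt_rate` attribute of the result.
#'
#' @param kon_pore Wall on-rate in 1/s.
#' @param attempt_rate Attempt rate nu in 1/s.
#' @return Barrier height in k_B T units, with attribute `attempt_rate`.
#' @export
#' @examples
#' adhesion_energy_barrier(0.5)            # ~7.6 kBT at the default 1e3 1/s
adhesion_energy_barrier <- function(kon_pore, attempt_rate = 1e3) {
  .check_positive_scalar(kon_pore, "kon_pore")
  .check_positive_scalar(attempt_rate, "attempt_rate")
  if (attempt_rate < kon_pore) {
    warning("attempt_rate < kon_pore gives a negative barrier", call. = FALSE)
  }
  structure(log(attempt_rate / kon_pore), attempt_rate = attempt_rate)
}

#' Exponential clog-formation model
#'
#' Frequency contrast during clog re-formation: exp(-t / t_clog).
#'
#' @param t Time in s (>= 0); vectorized.
#' @param t_clog Clog-formation time constant in s (> 0).
#' @return Dimensionless contrast.
#' @export
clog_formation_contrast <- function(t, t_clog) {
  .check_positive_scalar(t_clog, "t_clog")
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  exp(-t / t_clog)
}
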
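# Seeded synthetic-data generator. Emulates the statistical structure of
# zero-mode-waveguide translocation experiments: a membrane with many pores
# observed in parallel, event counts over a fixed acquisition window,
# technical replicates, and SEM error bars. Per-pore plateau rates are of
# order 1e-4 1/s, so the observable count rate is the per-pore frequency
# times the number of pores in the field of view.

# Evaluate code with a locally set RNG seed, restoring global state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Frequency-curve table
#'
#' The canonical container for measured or synthetic translocation-frequency
#' data: one row per (pressure, concentration) operating point, all in SI
#' units, with SEM uncertainties and replicate counts. Metadata (geometry,
#' fluid, side, condition label, generator truth) are carried as attributes.
#'
#' @param pressure Applied pressures in Pa (> 0).
#' @param concentration Upstream concentrations in particles/m^3 (>= 0).
#' @param frequency Translocation frequencies in 1/s (>= 0).
#' @param sem Standard errors of the mean, 1/s (> 0 wherever frequency > 0).
#' @param n_replicates Number of technical replicates per point.
#' @param geometry,fluid Optional [pore_geometry()] / [fluid_env()] metadata.
#' @param side `"exit"` or `"entry"`.
#' @param label Condition label (e.g. `"naked"`, `"grafted"`).
#' @param truth Optional named list of generator truth parameters.
#' @return A data.frame of class `frequency_curve`.
#' @export
frequency_curve <- function(pressure, concentration, frequency, sem,
                            n_replicates = 1L, geometry = NULL, fluid = NULL,
                            side = "exit", label = "", truth = NULL) {
  n <- length(pressure)
  stopifnot(length(concentration) == n, length(frequency) == n,
            length(sem) == n)
  if (any(!is.finite(pressure)) || any(pressure <= 0)) {
    stop("pressures must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(frequency)) || any(frequency < 0)) {
    stop("frequencies must be finite and >= 0", call. = FALSE)
  }
  if (any(frequency > 0 & !(sem > 0))) {
    stop("`sem` must be > 0 wherever frequency > 0", call. = FALSE)
  }
  out <- data.frame(pressure = as.numeric(pressure),
                    concentration = as.numeric(concentration),
                    frequency = as.numeric(frequency),
                    sem = as.numeric(sem),
                    n_replicates = as.integer(rep(n_replicates, length.out = n)))
  structure(out, class = c("frequency_curve", "data.frame"),
            geometry = geometry, fluid = fluid, side = side, label = label,
            truth = truth)
}

#' Simulation scenario
#'
#' Bundles everything needed to generate a synthetic experiment: geometry,
#' fluid, particle, jamming parameters, operating grids, acquisition window,
#' pore count in the field of view, replicate count, noise model and seed.
#'
#' @param geometry A [pore_geometry()].
#' @param fluid A [fluid_env()].
#' @param virus A [virus_params()].
#' @param params A [jamming_params()] (may be `NULL` for bead scenarios).
#' @param pressures Pressure grid in Pa (positive, non-empty).
#' @param concentrations Concentration grid in particles/m^3.
#' @param window Acquisition window per replicate in s.
#' @param n_pores Number of pores observed in parallel (events are pooled
#'   over the field of view).
#' @param replicates Technical replicates per operating point.
#' @param noise `"poisson_counting"` (event counts over the window) or
#'   `"gaussian_relative"` (multiplicative Gaussian noise of s.d.
#'   `noise_sigma`).
#' @param noise_sigma Relative noise level for the Gaussian model.
#' @param seed Integer RNG seed; identical scenarios generate bit-identical
#'   tables.
#' @param side,label Metadata passed to [frequency_curve()].
#' @return An object of class `jamming_scenario`.
#' @export
jamming_scenario <- function(geometry, fluid, virus, params, pressures,
                             concentrations, window = 60, n_pores = 1e4,
                             replicates = 36L,
                             noise = c("poisson_counting", "gaussian_relative"),
                             noise_sigma = 0.05, seed = 1L,
                             side = "exit", label = "") {
  noise <- match.arg(noise)
  if (length(pressures) == 0L || any(pressures <= 0)) {
    stop("`pressures` must be a non-empty positive grid", call. = FALSE)
  }
  if (length(concentrations) == 0L || any(concentrations < 0)) {
    stop("`concentrations` must be a non-empty non-negative grid", call. = FALSE)
  }
  .check_positive_scalar(window, "window")
  .check_positive_scalar(n_pores, "n_pores")
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  structure(list(geometry = geometry, fluid = fluid, virus = virus,
                 params = params, pressures = sort(as.numeric(pressures)),
                 concentrations = sort(as.numeric(concentrations)),
                 window = window, n_pores = n_pores,
                 replicates = as.integer(replicates), noise = noise,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 side = side, label = label),
            class = "jamming_scenario")
}

# noisy observation of a vector of true rates; returns list(freq, sem)
.observe_rates <- function(f_true, s) {
  n <- length(f_true)
  reps <- s$replicates
  if (s$noise == "poisson_counting") {
    scale <- s$window * s$n_pores      # counts per unit per-pore rate
    lambda <- f_true * scale
    counts <- matrix(stats::rpois(n * reps, rep(lambda, each = reps)),
                     nrow = reps)
    rates <- counts / scale
    freq <- colMeans(rates)
    sem <- if (reps > 1L) apply(rates, 2L, stats::sd) / sqrt(reps) else
      sqrt(pmax(lambda, 1)) / scale
    # zero-count points have an undefined sample SEM; floor at one count
    # over the total observation
    sem[sem <= 0] <- 1 / scale
    list(freq = freq, sem = sem, low_counts = all(lambda < 1))
  } else {
    sigma <- s$noise_sigma
    draws <- matrix(rep(f_true, each = reps) *
                      (1 + sigma * stats::rnorm(n * reps)), nrow = reps)
    freq <- colMeans(draws)
    # known relative noise: SEM from the noise model, not the tiny-sample sd
    sem <- pmax(sigma, 1e-6) * f_true / sqrt(reps)
    list(freq = pmax(freq, 0), sem = sem, low_counts = FALSE)
  }
}

.curve_from_truth <- function(f_true, grid, s, truth) {
  obs <- with_seed(s$seed, .observe_rates(f_true, s))
  if (isTRUE(obs$low_counts)) {
    warning("expected event counts < 1 at every operating point; ",
            "increase the window, pore count or concentrations", call. = FALSE)
  }
  frequency_curve(pressure = grid$pressure, concentration = grid$concentration,
                  frequency = obs$freq, sem = obs$sem,
                  n_replicates = s$replicates, geometry = s$geometry,
                  fluid = s$fluid, side = s$side, label = s$label,
                  truth = truth)
}

.scenario_grid <- function(s) {
  expand.grid(pressure = s$pressures, concentration = s$concentrations,
              KEEP.OUT.ATTRS = FALSE)
}

#' Generate synthetic jamming frequency curves
#'
#' Evaluates the soft-jamming model on the scenario's (pressure,
#' concentration) grid and adds counting or relative noise. Deterministic
#' given the scenario seed.
#'
#' @param s A [jamming_scenario()] with non-`NULL` `params`.
#' @return A [frequency_curve()] with generator truth in `attr(, "truth")`.
#' @export
#' @examples
#' curves <- generate_frequency_curves(preset_scenario("hiv_exit_200nm"))
#' head(curves)
generate_frequency_curves <- function(s) {
  stopifnot(inherits(s, "jamming_scenario"), inherits(s$params, "jamming_params"))
  grid <- .scenario_grid(s)
  f_true <- translocation_frequency(s$params, grid$pressure,
                                    grid$concentration, s$geometry, s$fluid)
  .curve_from_truth(f_true, grid, s,
                    truth = list(params = s$params, model = "jamming"))
}

#' Generate entry-side frequency curves
#'
#' Entry experiments show no critical pressure: particles do not adhere to
#' the pore at the channel entrance. The scenario's wall on-rate is replaced
#' by the value giving P_c = `pc_entry` (default 1e-3 Pa); the entry-time
#' branch (tau_1) is unchanged, so saturation with concentration persists.
#'
#' @inheritParams generate_frequency_curves
#' @param pc_entry Residual critical pressure in Pa.
#' @return A [frequency_curve()].
#' @export
generate_entry_curves <- function(s, pc_entry = 1e-3) {
  stopifnot(inherits(s, "jamming_scenario"), inherits(s$params, "jamming_params"))
  kon_entry <- kon_from_critical_pressure(pc_entry, s$geometry, s$fluid)
  s$params <- jamming_params(kon_entry, s$params$koff_clog, s$params$kd_clog)
  s$side <- "entry"
  generate_frequency_curves(s)
}

#' Generate synthetic nanobead curves
#'
#' Limiting cases of the transport model realised by polystyrene nanobeads:
#' `"carboxyl"` beads (no attractive interactions) follow purely advective
#' linear transport f = C v pi R^2; `"amino"` beads (wall adhesion only)
#' follow f = 1/tau_2 with a critical pressure but no plateau. `kon_pore`
#' is required for the amino kind.
#'
#' @inheritParams generate_frequency_curves
#' @param kind `"carboxyl"` or `"amino"`.
#' @param kon_pore Wall on-rate for amino beads, 1/s.
#' @return A [frequency_curve()].
#' @export
generate_bead_curves <- function(s, kind = c("carboxyl", "amino"),
                                 kon_pore = NULL) {
  stopifnot(inherits(s, "jamming_scenario"))
  kind <- match.arg(kind)
  grid <- .scenario_grid(s)
  if (kind == "carboxyl") {
    f_true <- carboxyl_bead_frequency(grid$pressure, grid$concentration,
                                      s$geometry, s$fluid)
  } else {
    if (is.null(kon_pore)) kon_pore <- if (!is.null(s$params)) s$params$kon_pore
    if (is.null(kon_pore)) stop("`kon_pore` is required for amino beads", call. = FALSE)
    f_true <- amino_bead_frequency(kon_pore, grid$pressure, grid$concentration,
                                   s$geometry, s$fluid)
  }
  s$label <- kind
  .curve_from_truth(f_true, grid, s,
                    truth = list(kind = kind, kon_pore = kon_pore,
                                 model = "bead"))
}

#' Generate a synthetic clog-formation trace
#'
#' Frequency contrast exp(-t/t_clog) with additive Gaussian noise on the
#' contrast.
#'
#' @param t_clog Clog-formation time constant in s.
#' @param times Sampling grid in s (strictly increasing, non-negative).
#' @param sigma Additive contrast noise s.d.
#' @param f0,f_inf Optional clog-free and steady-state frequencies (1/s)
#'   recorded as metadata.
#' @param seed Integer RNG seed.
#' @return A [clog_trace()] with the truth in `attr(, "truth")`.
#' @export
generate_clog_trace <- function(t_clog = 38, times = seq(0, 300, length.out = 30),
                                sigma = 0.05, f0 = NA_real_, f_inf = NA_real_,
                                seed = 1L) {
  contrast <- clog_formation_contrast(times, t_clog)
  if (sigma > 0) {
    contrast <- contrast + with_seed(seed, stats::rnorm(length(times), 0, sigma))
  }
  tr <- suppressWarnings(clog_trace(times, contrast, f0 = f0, f_inf = f_inf))
  attr(tr, "truth") <- list(t_clog = t_clog, sigma = sigma, seed = seed)
  tr
}

#' Generate paired naked/clogged DNA suction curves
#'
#' Emulates the clog-probing experiment: the same DNA probe is driven through
#' a naked pore (critical suction pressure `p_suc_naked`) and through the
#' pore clogged with particles, whose hydraulic resistance — and hence
#' critical suction pressure — is larger by `resistance_ratio`.
#'
#' @param p_suc_naked Critical suction pressure of the naked pore, Pa.
#' @param resistance_ratio P_suc^virus / P_suc (>= 1).
#' @param f_suc Suction prefactor in 1/s.
#' @param pressures Pressure grid in Pa.
#' @param sigma Relative Gaussian noise on the frequency.
#' @param replicates Technical replicates per point.
#' @param seed Integer RNG seed.
#' @return A list with [frequency_curve()] elements `naked` and `clogged`.
#' @export
generate_dna_curves <- function(p_suc_naked, resistance_ratio, f_suc,
                                pressures = NULL, sigma = 0.05,
                                replicates = 24L, seed = 1L) {
  .check_positive_scalar(p_suc_naked, "p_suc_naked")
  if (!is.numeric(resistance_ratio) || resistance_ratio < 1) {
    stop("`resistance_ratio` must be >= 1", call. = FALSE)
  }
  if (is.null(pressures)) {
    pressures <- exp(seq(log(p_suc_naked / 5),
                         log(p_suc_naked * resistance_ratio * 5),
                         length.out = 24))
  }
  one <- function(p_suc, seed_i, lab) {
    f_true <- dna_frequency(suction_params(f_suc, p_suc), pressures)
    n <- length(pressures)
    freq <- with_seed(seed_i, {
      draws <- matrix(rep(f_true, each = replicates) *
                        (1 + sigma * stats::rnorm(n * replicates)),
                      nrow = replicates)
      colMeans(draws)
    })
    sem <- pmax(sigma, 1e-6) * f_true / sqrt(replicates)
    frequency_curve(pressure = pressures, concentration = rep(0, n),
                    frequency = pmax(freq, 0), sem = sem,
                    n_replicates = replicates, label = lab,
                    truth = list(f_suc = f_suc, p_suc = p_suc, model = "suction"))
  }
  list(naked = one(p_suc_naked, seed, "naked"),
       clogged = one(p_suc_naked * resistance_ratio, seed + 1L, "clogged"))
}

# ---- presets --------------------------------------------------------------

.logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

.preset_table <- function() {
  geom200 <- pore_geometry(100e-9, 10e-6)
  geom400 <- pore_geometry(200e-9, 10e-6)
  fl <- fluid_env()
  # HIV hydrodynamic radius back-derived from the 38 s diffusion time over a
  # 10 um channel (synthetic preset value, not a measured radius).
  hiv <- virus_params(83e-9, "HIV VLP (synthetic preset)")
  kd_hiv <- molar_to_per_m3(1.5e-13)
  kon50 <- kon_from_critical_pressure(50, geom200, fl)
  list(
    hiv_exit_200nm = list(
      geometry = geom200, fluid = fl, virus = hiv,
      params = jamming_params(kon50, 1.2e-4, kd_hiv),
      pressures = .logspace(10, 2000, 20),
      concentrations = per_ml_to_per_m3(c(1e6, 1e7, 1e8)),
      replicates = 36L, side = "exit", label = "naked"),
    hiv_entry_200nm = list(
      geometry = geom200, fluid = fl, virus = hiv,
      params = jamming_params(kon_from_critical_pressure(1e-3, geom200, fl),
                              1.2e-4, kd_hiv),
      pressures = .logspace(10, 2000, 20),
      concentrations = per_ml_to_per_m3(c(1e6, 1e7, 1e8)),
      replicates = 24L, side = "entry", label = "naked"),
    hiv_grafted_200nm = list(
      geometry = geom200, fluid = fl, virus = hiv,
      params = jamming_params(kon_from_critical_pressure(30, geom200, fl),
                              1.5e-4, 4 * kd_hiv),
      pressures = .logspace(10, 2000, 20),
      concentrations = per_ml_to_per_m3(c(1e6, 1e7, 1e8)),
      replicates = 24L, side = "exit", label = "grafted"),
    hiv_salt_200nm = list(
      geometry = geom200, fluid = fl, virus = hiv,
      params = jamming_params(kon_from_critical_pressure(20, geom200, fl),
                              1.7e-4, 8 * kd_hiv),
      pressures = .logspace(10, 2000, 20),
      concentrations = per_ml_to_per_m3(c(1e6, 1e7, 1e8)),
      replicates = 24L, side = "exit", label = "salt"),
    carboxyl_beads_200nm = list(
      geometry = geom200, fluid = fl,
      virus = virus_params(38e-9, "carboxyl beads"), params = NULL,
      pressures = seq(100, 2000, length.out = 12),
      concentrations = per_ml_to_per_m3(c(1e8, 1e9, 1e10)),
      replicates = 24L, side = "exit", label = "carboxyl"),
    amino_beads_400nm = list(
      geometry = geom400, fluid = fl,
      virus = virus_params(85e-9, "amino beads"),
      params = jamming_params(5, 1e-4, molar_to_per_m3(1e-10)),
      pressures = .logspace(20, 4000, 16),
      concentrations = per_ml_to_per_m3(c(1e8, 1e9, 1e10)),
      replicates = 24L, side = "exit", label = "amino")
  )
}

#' Scenario presets
#'
#' Ready-made scenarios whose parameter values are assembled from the
#' experimentally reported ranges for HIV VLPs in 200 nm track-etched pores
#' (critical pressure 50 Pa on the exit side and ~1e-3 Pa on the entry side,
#' clog off-rate ~1.2e-4 1/s, clog dissociation constant ~1.5e-13 M) and
#' plausible bead parameters. All values are synthetic presets, not measured
#' data.
#'
#' @param name One of `"hiv_exit_200nm"`, `"hiv_entry_200nm"`,
#'   `"hiv_grafted_200nm"`, `"hiv_salt_200nm"`, `"carboxyl_beads_200nm"`,
#'   `"amino_beads_400nm"`.
#' @param seed Integer RNG seed for the scenario.
#' @param ... Overrides passed to [jamming_scenario()] (e.g. `noise`,
#'   `replicates`, `pressures`).
#' @return A [jamming_scenario()].
#' @export
#' @examples
#' preset_scenario("hiv_exit_200nm", seed = 7, noise = "gaussian_relative")
preset_scenario <- function(name, seed = 1L, ...) {
  tab <- .preset_table()
  if (!name %in% names(tab)) {
    stop("unknown preset '", name, "'; available presets: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  p <- tab[[name]]
  args <- list(geometry = p$geometry, fluid = p$fluid, virus = p$virus,
               params = p$params, pressures = p$pressures,
               concentrations = p$concentrations, replicates = p$replicates,
               side = p$side, label = p$label, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(jamming_scenario, args)
}
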
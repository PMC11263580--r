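# Weighted nonlinear estimation. All fitters minimise the chi-square
# sum(((f_obs - f_model)/sem)^2) by Levenberg-Marquardt (minpack.lm::nls.lm)
# over log-transformed parameters (positivity by construction), with a
# seeded multistart over log-uniform boxes. Deterministic given the seed.

.as_curve_df <- function(curve) {
  stopifnot(is.data.frame(curve))
  need <- c("pressure", "concentration", "frequency", "sem")
  miss <- setdiff(need, names(curve))
  if (length(miss)) {
    stop("curve is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  as.data.frame(curve)[need]
}

# Multistart LM over log-parameters.
# resid_fn takes a named numeric vector of *natural-scale* parameters.
.ms_fit <- function(resid_fn, lower, upper, n_starts = 8L, seed = 1L,
                    prefer_small = NULL, cov_scale = c("known_sem", "estimate")) {
  cov_scale <- match.arg(cov_scale)
  pn <- names(lower)
  stopifnot(!is.null(pn), identical(names(upper), pn), all(upper > lower))
  llo <- log(lower); lhi <- log(upper)
  wrapped <- function(lpar) {
    r <- resid_fn(stats::setNames(exp(lpar), pn))
    r[!is.finite(r)] <- 1e12
    r
  }
  mid <- (llo + lhi) / 2
  extra <- if (n_starts > 1L) {
    with_seed(seed, matrix(stats::runif((n_starts - 1L) * length(pn)),
                           ncol = length(pn)))
  } else NULL
  starts <- rbind(mid, if (!is.null(extra))
    sweep(sweep(extra, 2L, lhi - llo, `*`), 2L, llo, `+`))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                     ptol = 1e-12, gtol = 0)
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(minpack.lm::nls.lm(par = starts[i, ], fn = wrapped,
                                lower = llo, upper = lhi, control = ctrl),
             error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop("all optimizer starts failed", call. = FALSE)
  obj <- vapply(runs, function(r) sum(r$fvec^2), numeric(1))
  best_obj <- min(obj)
  near <- which(obj <= best_obj * (1 + 1e-6) + 1e-12)
  tie_broken <- FALSE
  if (!is.null(prefer_small) && length(near) > 1L) {
    vals <- vapply(runs[near], function(r) r$par[[match(prefer_small, pn)]],
                   numeric(1))
    pick <- near[which.min(vals)]
    tie_broken <- length(unique(round(vals, 8))) > 1L
  } else {
    pick <- near[which.min(obj[near])]
  }
  fit <- runs[[pick]]
  lpar <- stats::setNames(as.numeric(fit$par), pn)
  est <- exp(lpar)
  # with sem-weighted residuals the covariance of the log-params is (J'J)^-1;
  # for unweighted residuals the noise variance is estimated from RSS/dof
  cov_log <- tryCatch(solve(fit$hessian), error = function(e) {
    matrix(NA_real_, length(pn), length(pn))
  })
  dof <- length(fit$fvec) - length(pn)
  if (cov_scale == "estimate" && dof > 0) {
    cov_log <- cov_log * sum(fit$fvec^2) / dof
  }
  se_log <- suppressWarnings(sqrt(diag(cov_log)))
  at_bound <- (lpar - llo < 1e-8) | (lhi - lpar < 1e-8)
  list(estimates = est, se = est * se_log, cov_log = cov_log,
       objective = sum(fit$fvec^2), dof = dof,
       converged = fit$info %in% 1:4, info = fit$info,
       at_bound = stats::setNames(at_bound, pn), tie_broken = tie_broken)
}

.new_fit_result <- function(core, fixed = list(), derived = list(),
                            seed = NA_integer_, n_starts = NA_integer_,
                            method = "") {
  structure(c(core, list(fixed = fixed, derived = derived, seed = seed,
                         n_starts = n_starts, method = method)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$method, "\n")
  est <- data.frame(estimate = x$estimates, se = x$se)
  print(est)
  if (length(x$derived)) {
    cat("derived:\n")
    for (nm in names(x$derived)) cat("  ", nm, "=",
                                     format(x$derived[[nm]]), "\n")
  }
  if (length(x$fixed)) cat("fixed:", paste(names(x$fixed), "=",
                                           vapply(x$fixed, format, ""),
                                           collapse = ", "), "\n")
  cat("objective:", format(x$objective), " (dof ", x$dof, "), converged: ",
      x$converged, "\n", sep = "")
  invisible(x)
}

# Shared barrier-curve fitter: f(P) = A (P/Pstar) exp(-Pstar/P).
# Used for low-pressure jamming fits (A = k, Pstar = P_c) and for
# suction-model DNA fits (A = f_suc, Pstar = P_suc).
.fit_barrier <- function(pressure, frequency, sem, n_starts, seed) {
  model <- function(par) par[["A"]] * (pressure / par[["Pstar"]]) *
    exp(-par[["Pstar"]] / pressure)
  resid <- function(par) (frequency - model(par)) / sem
  fscale <- stats::median(frequency[frequency > 0])
  lower <- c(A = 1e-8 * fscale, Pstar = 1e-5 * min(pressure))
  upper <- c(A = 1e8 * fscale, Pstar = 50 * max(pressure))
  .ms_fit(resid, lower, upper, n_starts = n_starts, seed = seed)
}

#' Low-pressure fit: critical pressure and prefactor from one curve
#'
#' Below the frequency plateau the entry time is negligible compared to the
#' transit time and the curve follows f = 1/tau_2 = k (P/P_c) exp(-P_c/P).
#' This fits (k, P_c) by weighted least squares on the pre-plateau window and
#' derives the wall on-rate via [kon_from_critical_pressure()].
#'
#' The default window keeps points whose frequency is below 50% of the
#' running plateau estimate (the mean frequency of the three highest
#' pressures); `window = "all"` uses every point (appropriate for wall-only
#' particles with no plateau).
#'
#' @param curve A [frequency_curve()] (single concentration recommended).
#' @param geom A [pore_geometry()].
#' @param fluid A [fluid_env()].
#' @param window `"auto"` or `"all"`.
#' @param n_starts Number of multistart draws.
#' @param seed Integer seed for the multistart.
#' @return A `fit_result` with estimates `k`, `critical_pressure` and
#'   derived `kon_pore`.
#' @export
fit_low_pressure <- function(curve, geom, fluid, window = c("auto", "all"),
                             n_starts = 8L, seed = 1L) {
  window <- match.arg(window)
  d <- .as_curve_df(curve)
  if (window == "auto") {
    top <- utils::tail(order(d$pressure), 3L)
    plateau <- mean(d$frequency[top])
    d <- d[d$frequency < 0.5 * plateau, , drop = FALSE]
  }
  d <- d[d$frequency > 0, , drop = FALSE]
  if (nrow(d) < 4L) {
    stop("fewer than 4 usable points in the low-pressure window", call. = FALSE)
  }
  core <- .fit_barrier(d$pressure, d$frequency, d$sem, n_starts, seed)
  names(core$estimates) <- names(core$se) <-
    c("k", "critical_pressure")
  if (!core$converged) warning("low-pressure fit did not converge", call. = FALSE)
  kon <- kon_from_critical_pressure(core$estimates[["critical_pressure"]],
                                    geom, fluid)
  .new_fit_result(core,
                  derived = list(kon_pore = kon, n_points = nrow(d)),
                  seed = seed, n_starts = n_starts,
                  method = "low-pressure barrier fit (f = 1/tau_2)")
}

# Model frequency for a parameter vector with possible fixed components.
.jamming_model_fn <- function(free_names, fixed, pressure, concentration,
                              geom, fluid) {
  function(par) {
    full <- c(as.list(par[free_names]), fixed)
    p <- jamming_params(full$kon_pore, full$koff_clog, full$kd_clog)
    translocation_frequency(p, pressure, concentration, geom, fluid)
  }
}

#' Global pressure-sweep fit of the jamming model
#'
#' Fits the full model f(C,P) = 1/(tau_1 + tau_2) to frequency-pressure
#' curves at several concentrations simultaneously, with one shared
#' (kon_pore, koff_clog, kd_clog) triple. Any subset of parameters can be
#' frozen via `fixed` (used e.g. to check the independence of the entry and
#' transit branches).
#'
#' Ties between equally good minima are broken towards the smallest
#' `kd_clog`.
#'
#' @param curve A [frequency_curve()] containing at least 2 distinct
#'   concentrations with at least 4 pressures each.
#' @inheritParams fit_low_pressure
#' @param fixed Named list freezing any of `kon_pore`, `koff_clog`,
#'   `kd_clog` at given values.
#' @return A `fit_result` with the free parameters and derived
#'   `critical_pressure`.
#' @export
fit_pressure_sweep <- function(curve, geom, fluid, fixed = list(),
                               n_starts = 8L, seed = 1L) {
  d <- .as_curve_df(curve)
  d <- d[d$frequency > 0, , drop = FALSE]
  tab <- table(d$concentration)
  if (length(tab) < 2L || any(tab < 4L)) {
    stop("need >= 2 concentrations with >= 4 usable pressures each", call. = FALSE)
  }
  all_names <- c("kon_pore", "koff_clog", "kd_clog")
  stopifnot(all(names(fixed) %in% all_names))
  if (!length(setdiff(all_names, names(fixed)))) {
    stop("no free parameters", call. = FALSE)
  }
  res <- fit_pressure_sweep_engine(d, geom, fluid, fixed, n_starts, seed)
  if (!res$converged) warning("global fit did not converge", call. = FALSE)
  if (any(res$at_bound)) {
    warning("parameter(s) at the search-box boundary: ",
            paste(names(res$at_bound)[res$at_bound], collapse = ", "),
            call. = FALSE)
  }
  res$method <- "global jamming-model fit (shared parameters)"
  res
}

#' Concentration-sweep fit at fixed pressure
#'
#' At a fixed pressure, the frequency-versus-concentration curve rises and
#' saturates towards k_off; this extracts (koff_clog, kd_clog) with the wall
#' on-rate supplied (from a low-pressure fit) or co-fitted when `kon = NULL`.
#'
#' Identifiability guard: if the whole concentration grid lies below a tenth
#' of the fitted K_d, the saturation regime was never reached and k_off and
#' K_d are only jointly constrained; the fit is rejected with an error.
#'
#' @param curve A [frequency_curve()] at a single pressure with >= 5
#'   concentrations.
#' @inheritParams fit_low_pressure
#' @param kon Wall on-rate in 1/s, or `NULL` to co-fit it.
#' @return A `fit_result`.
#' @export
fit_concentration_sweep <- function(curve, geom, fluid, kon = NULL,
                                    n_starts = 8L, seed = 1L) {
  d <- .as_curve_df(curve)
  d <- d[d$frequency > 0, , drop = FALSE]
  if (length(unique(d$pressure)) != 1L) {
    stop("curve must be at a single fixed pressure", call. = FALSE)
  }
  if (length(unique(d$concentration)) < 5L) {
    stop("need >= 5 distinct concentrations", call. = FALSE)
  }
  fixed <- if (is.null(kon)) list() else list(kon_pore = kon)
  res <- fit_pressure_sweep_engine(d, geom, fluid, fixed, n_starts, seed)
  kd_hat <- res$estimates[["kd_clog"]]
  if (max(d$concentration) < kd_hat / 10) {
    stop("concentration grid lies entirely below K_d/10: saturation never ",
         "reached, k_off and K_d are not separately identifiable", call. = FALSE)
  }
  res$method <- "concentration-sweep fit at fixed pressure"
  res
}

# shared core between concentration sweep and pressure sweep (no >=2-C check)
fit_pressure_sweep_engine <- function(d, geom, fluid, fixed, n_starts, seed) {
  all_names <- c("kon_pore", "koff_clog", "kd_clog")
  free_names <- setdiff(all_names, names(fixed))
  model <- .jamming_model_fn(free_names, fixed, d$pressure, d$concentration,
                             geom, fluid)
  resid <- function(par) (d$frequency - model(par)) / d$sem
  fmax <- max(d$frequency)
  boxes <- list(
    kon_pore = kon_from_critical_pressure(
      c(0.02 * min(d$pressure), 20 * max(d$pressure)), geom, fluid),
    koff_clog = c(1e-4 * fmax, 1e3 * fmax),
    kd_clog = stats::median(d$concentration) * c(1e-4, 1e4))
  lower <- vapply(boxes[free_names], `[`, numeric(1), 1L)
  upper <- vapply(boxes[free_names], `[`, numeric(1), 2L)
  names(lower) <- names(upper) <- free_names
  core <- .ms_fit(resid, lower, upper, n_starts = n_starts, seed = seed,
                  prefer_small = if ("kd_clog" %in% free_names) "kd_clog")
  kon <- if ("kon_pore" %in% free_names) core$estimates[["kon_pore"]] else
    fixed$kon_pore
  .new_fit_result(core, fixed = fixed,
                  derived = list(critical_pressure =
                                   critical_pressure(kon, geom, fluid)),
                  seed = seed, n_starts = n_starts, method = "jamming-model fit")
}

#' Fit the clog-formation time constant
#'
#' Least-squares fit of exp(-t/t_clog) to a frequency-contrast trace.
#' Requires at least 6 time points with contrasts within \[-0.2, 1.2\]
#' (tolerating noise excursions); traces with a non-decreasing trend are
#' rejected.
#'
#' @param trace A [clog_trace()].
#' @param n_starts,seed Multistart controls.
#' @return A `fit_result` with estimate `t_clog`.
#' @export
fit_clog_dynamics <- function(trace, n_starts = 4L, seed = 1L) {
  stopifnot(inherits(trace, "clog_trace"))
  t <- trace$times; y <- trace$contrast
  if (length(t) < 6L) stop("need >= 6 time points", call. = FALSE)
  if (any(y < -0.2) || any(y > 1.2)) {
    stop("contrast values outside [-0.2, 1.2]; not a normalized trace",
         call. = FALSE)
  }
  slope <- stats::coef(stats::lm(y ~ t))[[2L]]
  if (slope >= 0) {
    stop("trace is non-decreasing: no clog-formation decay to fit", call. = FALSE)
  }
  resid <- function(par) y - exp(-t / par[["t_clog"]])
  dt <- diff(t)
  lower <- c(t_clog = min(dt) / 10)
  upper <- c(t_clog = 100 * max(t))
  core <- .ms_fit(resid, lower, upper, n_starts = n_starts, seed = seed,
                  cov_scale = "estimate")
  if (!core$converged) warning("clog-dynamics fit did not converge", call. = FALSE)
  .new_fit_result(core, seed = seed, n_starts = n_starts,
                  method = "exponential clog-formation fit")
}

#' Fit the suction model to a DNA translocation curve
#'
#' Weighted fit of f_DNA(P) = f_suc (P/P_suc) exp(-P_suc/P); paired fits on
#' naked and clogged pores feed [clog_thickness()].
#'
#' @param curve A [frequency_curve()] with >= 5 pressures bracketing P_suc.
#' @param n_starts,seed Multistart controls.
#' @return A `fit_result` with estimates `f_suc` and `p_suc`.
#' @export
fit_suction <- function(curve, n_starts = 8L, seed = 1L) {
  d <- .as_curve_df(curve)
  d <- d[d$frequency > 0, , drop = FALSE]
  if (nrow(d) < 5L) stop("need >= 5 usable pressures", call. = FALSE)
  core <- .fit_barrier(d$pressure, d$frequency, d$sem, n_starts, seed)
  names(core$estimates) <- names(core$se) <- c("f_suc", "p_suc")
  if (!core$converged) warning("suction fit did not converge", call. = FALSE)
  .new_fit_result(core, seed = seed, n_starts = n_starts,
                  method = "suction-model fit")
}

#' Master-curve collapse metric
#'
#' Root-mean-square deviation of master-curve points from the identity line
#' y = x. Zero (to numerical precision) for noiseless model data under the
#' generating parameters.
#'
#' @param points A data.frame from [master_curve_points()] (columns `x`, `y`).
#' @return RMS of (y - x).
#' @export
collapse_metric <- function(points) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (nrow(points) < 3L && nrow(points) != 1L) {
    stop("need >= 3 points (or a single point) for the collapse metric",
         call. = FALSE)
  }
  sqrt(mean((points$y - points$x)^2))
}
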
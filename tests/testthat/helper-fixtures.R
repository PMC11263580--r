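# Shared fixtures and independent brute-force oracles for the fit tests.

geom200 <- function() pore_geometry(100e-9, 10e-6)
water <- function() fluid_env()
hiv_params <- function() jamming_params(0.625, 1.2e-4, molar_to_per_m3(1.5e-13))

logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

with_seed <- utils::getFromNamespace("with_seed", "porejam")

# Independent oracle: dense grid minimisation of a chi-square function over
# log-spaced parameter grids, optionally zooming around the incumbent best
# (span +-2 cells per pass). Never calls the optimizer path.
grid_oracle <- function(chisq_fn, grids, refine = 0L) {
  steps <- vapply(grids, function(gr) diff(log(gr[1:2])), numeric(1))
  for (pass in seq_len(refine + 1L)) {
    g <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
    vals <- vapply(seq_len(nrow(g)),
                   function(i) chisq_fn(as.numeric(g[i, ])), numeric(1))
    best <- as.numeric(g[which.min(vals), ])
    if (pass <= refine) {
      grids <- Map(function(b, s, gr) {
        exp(seq(log(b) - 2 * s, log(b) + 2 * s, length.out = length(gr)))
      }, best, steps, grids)
      steps <- vapply(grids, function(gr) diff(log(gr[1:2])), numeric(1))
    }
  }
  list(par = best, objective = min(vals), log_step = steps)
}

# Exact brute-force oracle for the barrier law f = A (P/Pstar) exp(-Pstar/P):
# A enters linearly, so for each candidate Pstar the weighted-least-squares
# amplitude is closed form; only Pstar needs a grid.
barrier_profile_oracle <- function(d, pstar_grid) {
  w <- 1 / d$sem^2
  best <- list(objective = Inf)
  for (ps in pstar_grid) {
    m <- (d$pressure / ps) * exp(-ps / d$pressure)
    A <- sum(w * d$frequency * m) / sum(w * m^2)
    obj <- sum(w * (d$frequency - A * m)^2)
    if (obj < best$objective) best <- list(objective = obj, A = A, Pstar = ps)
  }
  best$log_step <- diff(log(pstar_grid[1:2]))
  best
}

expect_within_one_cell <- function(est, oracle) {
  expect_true(all(abs(log(est) - log(oracle$par)) <= oracle$log_step + 1e-9))
}

chisq_of <- function(d, model_fn) {
  function(par) sum(((d$frequency - model_fn(par)) / d$sem)^2)
}

# Noiseless multi-virus multi-pore master-curve set: operating points at
# P >= P_c (where translocations are observable) and C spanning K_d.
master_curve_set <- function() {
  fl <- water()
  mk <- function(kon, koff, kd_M, geom) {
    p <- jamming_params(kon, koff, molar_to_per_m3(kd_M))
    pc <- critical_pressure(kon, geom, fl)
    g <- expand.grid(pressure = logspace(pc, 20 * pc, 8),
                     concentration = molar_to_per_m3(kd_M) * c(0.1, 1, 10))
    g$frequency <- translocation_frequency(p, g$pressure, g$concentration,
                                           geom, fl)
    list(d = g, params = p, geom = geom)
  }
  list(mk(0.625, 1.2e-4, 1.5e-13, pore_geometry(100e-9, 10e-6)),   # HIV-like
       mk(0.3, 0.8e-4, 3e-14, pore_geometry(50e-9, 6e-6)),         # AAV-like
       mk(0.8, 1.7e-4, 3e-13, pore_geometry(200e-9, 10e-6)),       # MLV-like
       mk(0.45, 1.0e-4, 8e-14, pore_geometry(40e-9, 6e-6)))        # HBV-like
}
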
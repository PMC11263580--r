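#!/usr/bin/env Rscript
# Step 4 — master-curve collapse across viruses and pore sizes.
#
# Builds jamming datasets for four particle types in four pore geometries,
# transforms them into the dimensionless master-curve coordinates
# x = C/(C + K_d), y = (k_off/k)(k tau - alpha), and quantifies the collapse
# onto the identity line, noiseless and at 5% measurement noise. Writes
# results/master_curve.csv and results/collapse_metrics.csv.

suppressMessages(library(porejam))
dir.create("results", showWarnings = FALSE)
fl <- fluid_env()

systems <- list(
  list(name = "HIV_200nm", kon = 0.625, koff = 1.2e-4, kd_M = 1.5e-13,
       geom = pore_geometry(100e-9, 10e-6)),
  list(name = "AAV_100nm", kon = 0.3, koff = 0.8e-4, kd_M = 3e-14,
       geom = pore_geometry(50e-9, 6e-6)),
  list(name = "MLV_400nm", kon = 0.8, koff = 1.7e-4, kd_M = 3e-13,
       geom = pore_geometry(200e-9, 10e-6)),
  list(name = "HBV_80nm", kon = 0.45, koff = 1.0e-4, kd_M = 8e-14,
       geom = pore_geometry(40e-9, 6e-6)))

# Operating points are taken in the regime where jamming is visible -- the
# pressures at which the transit time is a chosen multiple of the entry time
# (the experimentally informative window; far below it the entry branch, and
# hence the y-coordinate, is swamped by transit-time noise).
pressure_for_ratio <- function(p, conc, geom, r) {
  t1 <- entry_time(p, conc)
  f <- function(lp) transit_time(p, exp(lp), conc, geom, fl) - r * t1
  exp(stats::uniroot(f, c(log(1e-3), log(1e9)))$root)
}

build <- function(sys, sigma, seed) {
  p <- jamming_params(sys$kon, sys$koff, molar_to_per_m3(sys$kd_M))
  g <- do.call(rbind, lapply(molar_to_per_m3(sys$kd_M) * c(0.1, 1, 10),
    function(conc) data.frame(
      pressure = vapply(c(4, 2, 1, 0.5, 0.25, 0.125), function(r)
        pressure_for_ratio(p, conc, sys$geom, r), numeric(1)),
      concentration = conc)))
  f <- translocation_frequency(p, g$pressure, g$concentration, sys$geom, fl)
  if (sigma > 0) {
    set.seed(seed)
    f <- f * (1 + sigma * rnorm(length(f)))
  }
  g$frequency <- f
  mp <- master_curve_points(g, p, sys$geom, fl)
  mp$system <- sys$name
  mp
}

noiseless <- do.call(rbind, lapply(systems, build, sigma = 0, seed = 0))
noisy <- do.call(rbind, lapply(seq_along(systems), function(i)
  build(systems[[i]], sigma = 0.05, seed = 400 + i)))

m0 <- collapse_metric(noiseless)
m5 <- collapse_metric(noisy)
message(sprintf("collapse RMS(y - x): %.2e noiseless, %.3f at 5%% noise (%d points, 4 systems)",
                m0, m5, nrow(noiseless)))

write.csv(noisy, "results/master_curve.csv", row.names = FALSE)
write.csv(data.frame(condition = c("noiseless", "noise_5pct"),
                     collapse_rms = c(m0, m5), n_points = nrow(noiseless)),
          "results/collapse_metrics.csv", row.names = FALSE)
message("wrote results/master_curve.csv and results/collapse_metrics.csv")
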
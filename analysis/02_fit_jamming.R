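#!/usr/bin/env Rscript
# Step 2 — fit the soft-jamming model to the synthetic sweeps.
#
# Recovers the interaction parameters: the wall on-rate (and hence the
# critical pressure) from a low-pressure fit of f = 1/tau_2, then all three
# parameters from a global fit across concentrations, and the clog
# parameters (k_off, K_d) from the fixed-pressure concentration sweep.
# Writes results/fit_jamming.csv and a structured report.

suppressMessages(library(porejam))
dir.create("results", showWarnings = FALSE)

geom <- pore_geometry(100e-9, 10e-6)
fl <- fluid_env()
truth <- jamming_params(0.625, 1.2e-4, molar_to_per_m3(1.5e-13))

exit <- read_frequency_csv("results/data/hiv_exit_200nm.csv")

low <- exit[exit$concentration == min(exit$concentration), ]
lp <- fit_low_pressure(low, geom, fl, seed = 201)
message(sprintf("low-pressure fit:   P_c = %.1f Pa (true 50), kon = %.3f 1/s",
                lp$estimates[["critical_pressure"]], lp$derived$kon_pore))

gl <- suppressWarnings(fit_pressure_sweep(exit, geom, fl, seed = 202))
message(sprintf("global fit:         P_c = %.1f Pa, koff = %.2e 1/s, K_d = %.2e M",
                gl$derived$critical_pressure, gl$estimates[["koff_clog"]],
                per_m3_to_molar(gl$estimates[["kd_clog"]])))

cs <- read_frequency_csv("results/data/hiv_concentration_sweep.csv")
cf <- fit_concentration_sweep(cs, geom, fl, kon = lp$derived$kon_pore,
                              seed = 203)
message(sprintf("concentration fit:  koff = %.2e 1/s (true 1.2e-4), K_d = %.2e M (true 1.5e-13)",
                cf$estimates[["koff_clog"]],
                per_m3_to_molar(cf$estimates[["kd_clog"]])))

entry <- read_frequency_csv("results/data/hiv_entry_200nm.csv")
ent1 <- entry[entry$concentration == max(entry$concentration), ]
ep <- fit_low_pressure(ent1, geom, fl, seed = 204)
message(sprintf("entry side:         P_c = %.2g Pa (no critical pressure at entry)",
                ep$estimates[["critical_pressure"]]))

amino <- read_frequency_csv("results/data/amino_beads_400nm.csv")
am1 <- amino[amino$concentration == min(amino$concentration), ]
ab <- fit_low_pressure(am1, pore_geometry(200e-9, 10e-6), fl,
                       window = "all", seed = 205)
message(sprintf("amino beads:        P_c = %.0f Pa (wall adhesion only, no plateau)",
                ab$estimates[["critical_pressure"]]))

tab <- data.frame(
  analysis = c("low_pressure", "global", "concentration_sweep", "entry",
               "amino_beads"),
  critical_pressure_Pa = c(lp$estimates[["critical_pressure"]],
                           gl$derived$critical_pressure, NA,
                           ep$estimates[["critical_pressure"]],
                           ab$estimates[["critical_pressure"]]),
  kon_pore_per_s = c(lp$derived$kon_pore, gl$estimates[["kon_pore"]], NA,
                     NA, NA),
  koff_clog_per_s = c(NA, gl$estimates[["koff_clog"]],
                      cf$estimates[["koff_clog"]], NA, NA),
  kd_clog_M = c(NA, per_m3_to_molar(gl$estimates[["kd_clog"]]),
                per_m3_to_molar(cf$estimates[["kd_clog"]]), NA, NA))
write.csv(tab, "results/fit_jamming.csv", row.names = FALSE)
write_fit_report(gl, "results/fit_jamming_global.txt")
message("wrote results/fit_jamming.csv and results/fit_jamming_global.txt")
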
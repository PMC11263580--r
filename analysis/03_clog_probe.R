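#!/usr/bin/env Rscript
# Step 3 — characterise the clog: formation kinetics and geometry.
#
# Fits the exponential clog-formation transient (time constant t_clog,
# compared with the diffusive timescale), fits the suction model to the
# naked and clogged DNA curves to extract the particle layer thickness, and
# derives the effective in-pore concentration, the corrected dissociation
# constant and the adhesion energy barrier. Writes results/clog_probe.csv.

suppressMessages(library(porejam))
dir.create("results", showWarnings = FALSE)

geom <- pore_geometry(100e-9, 10e-6)
fl <- fluid_env()
hiv <- virus_params(83e-9, "HIV VLP")

tr_tab <- read.csv("results/data/clog_trace.csv")
tr <- clog_trace(tr_tab$time_s, tr_tab$contrast)
ck <- fit_clog_dynamics(tr, seed = 301)
message(sprintf("clog formation:  t_clog = %.1f +- %.1f s; diffusive scale t_diff = %.1f s",
                ck$estimates[["t_clog"]], ck$se[["t_clog"]],
                diffusion_time(geom, hiv, fl)))

naked <- read_frequency_csv("results/data/dna_naked.csv")
clogged <- read_frequency_csv("results/data/dna_clogged.csv")
fn <- fit_suction(naked, seed = 302)
fc <- fit_suction(clogged, seed = 303)
cs <- clog_thickness(fn$estimates[["p_suc"]], fc$estimates[["p_suc"]], geom)
re_r <- cs$layer_thickness / cs$pore_radius
message(sprintf("suction probe:   P_suc = %.0f Pa (naked), %.0f Pa (clogged) -> R_e/R = %.3f",
                fn$estimates[["p_suc"]], fc$estimates[["p_suc"]], re_r))

cn <- effective_pore_concentration(cs, hiv)
kd_corr <- corrected_kd(1.5e-13, per_ml_to_per_m3(1e8), cn)
barrier <- adhesion_energy_barrier(0.625, attempt_rate = 1e3)
message(sprintf("in-pore concentration C_n = %.2g /mL; corrected K_d = %.2g M; dF* = %.1f kBT",
                per_m3_to_per_ml(cn), kd_corr, as.numeric(barrier)))

write.csv(data.frame(
  quantity = c("t_clog_s", "t_diff_s", "p_suc_naked_Pa", "p_suc_clogged_Pa",
               "re_over_r", "pore_concentration_per_mL", "corrected_kd_M",
               "adhesion_barrier_kBT", "attempt_rate_per_s"),
  value = c(ck$estimates[["t_clog"]], diffusion_time(geom, hiv, fl),
            fn$estimates[["p_suc"]], fc$estimates[["p_suc"]], re_r,
            per_m3_to_per_ml(cn), kd_corr, as.numeric(barrier),
            attr(barrier, "attempt_rate"))),
  "results/clog_probe.csv", row.names = FALSE)
message("wrote results/clog_probe.csv")
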
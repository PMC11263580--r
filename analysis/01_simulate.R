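#!/usr/bin/env Rscript
# Step 1 — generate the synthetic experiment suite.
#
# Emulates the four experiment types of the translocation study: exit-side
# and entry-side frequency-pressure sweeps for HIV-like particles, the two
# nanobead controls, a fixed-pressure concentration sweep, a clog-formation
# contrast trace, and the paired naked/clogged DNA suction probe. Writes the
# tables under results/data/.

suppressMessages(library(porejam))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

geom <- pore_geometry(100e-9, 10e-6)
fl <- fluid_env()

message("Poiseuille sanity: v(800 Pa) = ",
        signif(flow_speed(800, geom, fl), 3), " m/s, t_adv = ",
        signif(advection_time(800, geom, fl), 3), " s, t_diff(83 nm) = ",
        signif(diffusion_time(geom, virus_params(83e-9), fl), 3), " s")

write_frequency_csv(
  generate_frequency_curves(preset_scenario("hiv_exit_200nm", seed = 101)),
  "results/data/hiv_exit_200nm.csv")
write_frequency_csv(
  generate_entry_curves(preset_scenario("hiv_entry_200nm", seed = 102)),
  "results/data/hiv_entry_200nm.csv")
write_frequency_csv(
  generate_bead_curves(preset_scenario("carboxyl_beads_200nm", seed = 103),
                       "carboxyl"),
  "results/data/carboxyl_beads_200nm.csv")
write_frequency_csv(
  generate_bead_curves(preset_scenario("amino_beads_400nm", seed = 104),
                       "amino"),
  "results/data/amino_beads_400nm.csv")

# concentration sweep at the 800 Pa saturation-regime pressure
conc_scenario <- preset_scenario("hiv_exit_200nm", seed = 105,
                                 pressures = 800, replicates = 18L,
                                 concentrations = per_ml_to_per_m3(10^seq(6.5, 9.5, 0.5)))
write_frequency_csv(generate_frequency_curves(conc_scenario),
                    "results/data/hiv_concentration_sweep.csv")

# clog-formation transient (contrast vs time)
tr <- generate_clog_trace(t_clog = 38, times = seq(0, 300, length.out = 30),
                          sigma = 0.05, seed = 106)
write.csv(data.frame(time_s = tr$times, contrast = tr$contrast),
          "results/data/clog_trace.csv", row.names = FALSE)

# DNA suction probe of the clogged pore: naked vs clogged pair
pair <- generate_dna_curves(suction_critical_pressure(geom, fl),
                            resistance_ratio = 16, f_suc = 5,
                            sigma = 0.05, seed = 107)
write_frequency_csv(pair$naked, "results/data/dna_naked.csv")
write_frequency_csv(pair$clogged, "results/data/dna_clogged.csv")

message("wrote 7 synthetic tables under results/data/")
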
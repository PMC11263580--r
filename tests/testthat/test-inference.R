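# Fitters: exact recovery on noiseless data, agreement with brute-force grid
# oracles, identifiability guards, separability, unit invariance.

test_that("noiseless recovery is exact (optimizer tolerance) for every fitter", {
  g <- geom200(); fl <- water(); truth <- hiv_params()
  # global pressure sweep
  s <- preset_scenario("hiv_exit_200nm", noise = "gaussian_relative",
                       noise_sigma = 0, replicates = 1L)
  cur <- generate_frequency_curves(s)
  gf <- fit_pressure_sweep(cur, g, fl)
  expect_equal(gf$estimates[["kon_pore"]], truth$kon_pore, tolerance = 1e-6)
  expect_equal(gf$estimates[["koff_clog"]], truth$koff_clog, tolerance = 1e-6)
  expect_equal(gf$estimates[["kd_clog"]], truth$kd_clog, tolerance = 1e-6)
  # low-pressure fit on a noiseless amino curve (f = 1/tau2 exactly)
  sa <- preset_scenario("amino_beads_400nm", noise = "gaussian_relative",
                        noise_sigma = 0, replicates = 1L)
  am <- generate_bead_curves(sa, "amino")
  am1 <- am[am$concentration == min(am$concentration), ]
  lp <- fit_low_pressure(am1, sa$geometry, fl)
  pc_true <- critical_pressure(sa$params$kon_pore, sa$geometry, fl)
  expect_equal(lp$estimates[["critical_pressure"]], pc_true, tolerance = 1e-6)
  expect_equal(lp$derived$kon_pore, sa$params$kon_pore, tolerance = 1e-6)
  # concentration sweep at fixed pressure
  sc <- preset_scenario("hiv_exit_200nm", noise = "gaussian_relative",
                        noise_sigma = 0, replicates = 1L, pressures = 800,
                        concentrations = per_ml_to_per_m3(10^seq(6.5, 9.5, 0.5)))
  cc <- generate_frequency_curves(sc)
  fc <- fit_concentration_sweep(cc, g, fl, kon = truth$kon_pore)
  expect_equal(fc$estimates[["koff_clog"]], truth$koff_clog, tolerance = 1e-6)
  expect_equal(fc$estimates[["kd_clog"]], truth$kd_clog, tolerance = 1e-6)
  # clog dynamics
  tr <- generate_clog_trace(t_clog = 38, sigma = 0, times = seq(0, 300, length.out = 10))
  expect_equal(fit_clog_dynamics(tr)$estimates[["t_clog"]], 38, tolerance = 1e-6)
  # suction
  dn <- generate_dna_curves(1037, 16, 5, sigma = 0)
  fs <- fit_suction(dn$naked)
  expect_equal(fs$estimates[["f_suc"]], 5, tolerance = 1e-6)
  expect_equal(fs$estimates[["p_suc"]], 1037, tolerance = 1e-6)
})

test_that("optimizer agrees with the dense grid-search oracle (barrier fits)", {
  fl <- water()
  sa <- preset_scenario("amino_beads_400nm", seed = 13,
                        noise = "gaussian_relative", noise_sigma = 0.05,
                        replicates = 1L)
  am <- generate_bead_curves(sa, "amino")
  d <- am[am$concentration == min(am$concentration), ]
  fit <- fit_low_pressure(d, sa$geometry, fl, window = "all")
  orc <- barrier_profile_oracle(d, logspace(min(d$pressure) / 20,
                                            2 * max(d$pressure), 2000))
  expect_lte(abs(log(fit$estimates[["critical_pressure"]]) - log(orc$Pstar)),
             orc$log_step + 1e-9)
  expect_equal(fit$estimates[["k"]], orc$A, tolerance = 0.02)
  expect_lte(fit$objective, orc$objective * (1 + 1e-8))
  # suction curve, same functional form, independent data
  dn <- generate_dna_curves(1037, 16, 5, sigma = 0.05, seed = 17)
  dd <- as.data.frame(dn$clogged)
  fits <- fit_suction(dn$clogged)
  orc2 <- barrier_profile_oracle(dd, logspace(min(dd$pressure) / 20,
                                              5 * max(dd$pressure), 2000))
  expect_lte(abs(log(fits$estimates[["p_suc"]]) - log(orc2$Pstar)),
             orc2$log_step + 1e-9)
  expect_equal(fits$estimates[["f_suc"]], orc2$A, tolerance = 0.02)
  expect_lte(fits$objective, orc2$objective * (1 + 1e-8))
})

test_that("optimizer agrees with the grid oracle (clog dynamics, 1-D)", {
  tr <- generate_clog_trace(t_clog = 38, sigma = 0.05, seed = 19)
  fit <- fit_clog_dynamics(tr)
  chisq <- function(par) sum((tr$contrast - exp(-tr$times / par[1]))^2)
  orc <- grid_oracle(chisq, list(t_clog = logspace(1, 1000, 2000)))
  expect_within_one_cell(fit$estimates[["t_clog"]], orc)
  # low-noise cross-check against the linearised log-contrast regression
  tr2 <- generate_clog_trace(t_clog = 38, sigma = 0.005, seed = 23,
                             times = seq(0, 80, length.out = 20))
  fit2 <- fit_clog_dynamics(tr2)
  lin <- -1 / stats::coef(stats::lm(log(tr2$contrast) ~ tr2$times))[[2]]
  expect_equal(fit2$estimates[["t_clog"]], lin, tolerance = 0.02)
})

test_that("optimizer agrees with a coarse 3-D grid oracle (global jamming fit)", {
  g <- geom200(); fl <- water()
  s <- preset_scenario("hiv_exit_200nm", seed = 29, noise = "gaussian_relative",
                       noise_sigma = 0.05, replicates = 1L,
                       pressures = logspace(20, 2000, 8),
                       concentrations = per_ml_to_per_m3(c(1e7, 1e8, 1e9)))
  cur <- generate_frequency_curves(s)
  fit <- fit_pressure_sweep(cur, g, fl, seed = 29)
  d <- as.data.frame(cur)
  model <- function(par) {
    translocation_frequency(jamming_params(par[1], par[2], par[3]),
                            d$pressure, d$concentration, g, fl)
  }
  orc <- grid_oracle(chisq_of(d, model),
                     list(kon = logspace(0.05, 5, 25),
                          koff = logspace(1e-5, 1e-2, 25),
                          kd = logspace(1e12, 1e16, 25)), refine = 3L)
  expect_lte(fit$objective, orc$objective * (1 + 1e-8))
  expect_within_one_cell(
    fit$estimates[c("kon_pore", "koff_clog", "kd_clog")], orc)
})

test_that("noisy recovery: critical pressure and the softer K_d direction", {
  g <- geom200(); fl <- water(); truth <- hiv_params()
  # low-pressure fits across seeded replicates recover Pc within the +-10 Pa band
  pcs <- vapply(1:30, function(i) {
    s <- preset_scenario("hiv_exit_200nm", seed = i, noise = "gaussian_relative",
                         noise_sigma = 0.05, replicates = 1L)
    cur <- generate_frequency_curves(s)
    one <- cur[cur$concentration == min(cur$concentration), ]
    fit_low_pressure(one, g, fl)$estimates[["critical_pressure"]]
  }, numeric(1))
  expect_gt(mean(pcs), 40); expect_lt(mean(pcs), 60)
  # K_d is the softest direction: median relative error < 30% at 5% noise
  kd_err <- vapply(1:20, function(i) {
    s <- preset_scenario("hiv_exit_200nm", seed = 100 + i,
                         noise = "gaussian_relative", noise_sigma = 0.05,
                         replicates = 1L,
                         concentrations = per_ml_to_per_m3(c(1e7, 1e8, 1e9)))
    cur <- generate_frequency_curves(s)
    fit <- suppressWarnings(fit_pressure_sweep(cur, g, fl, seed = i))
    abs(fit$estimates[["kd_clog"]] / truth$kd_clog - 1)
  }, numeric(1))
  expect_lt(median(kd_err), 0.30)
})

test_that("recovered off-rate stays inside the experimentally reported decade", {
  g <- geom200(); fl <- water()
  s <- preset_scenario("hiv_exit_200nm", seed = 37, noise = "gaussian_relative",
                       noise_sigma = 0.05, replicates = 1L, pressures = 800,
                       concentrations = per_ml_to_per_m3(10^seq(6.5, 9.5, 0.5)))
  cc <- generate_frequency_curves(s)
  fit <- fit_concentration_sweep(cc, g, fl, kon = 0.625, seed = 37)
  expect_gte(fit$estimates[["koff_clog"]], 0.8e-4)
  expect_lte(fit$estimates[["koff_clog"]], 1.7e-4)
})

test_that("identifiability guard: all concentrations far below K_d is rejected", {
  g <- geom200(); fl <- water()
  s <- preset_scenario("hiv_exit_200nm", seed = 43, noise = "gaussian_relative",
                       noise_sigma = 0.02, replicates = 1L, pressures = 800,
                       concentrations = per_ml_to_per_m3(10^seq(2, 4, 0.5)))
  cc <- generate_frequency_curves(s)
  expect_error(fit_concentration_sweep(cc, g, fl, kon = 0.625),
               "not separately identifiable")
})

test_that("entry and transit branches are separable in the global fit", {
  g <- geom200(); fl <- water(); truth <- hiv_params()
  s <- preset_scenario("hiv_exit_200nm", seed = 47, noise = "gaussian_relative",
                       noise_sigma = 0.01, replicates = 1L,
                       concentrations = per_ml_to_per_m3(c(1e7, 1e8, 1e9)))
  cur <- generate_frequency_curves(s)
  free <- fit_pressure_sweep(cur, g, fl, seed = 47)
  tau1_frozen <- fit_pressure_sweep(cur, g, fl, seed = 47,
                                    fixed = list(koff_clog = truth$koff_clog,
                                                 kd_clog = truth$kd_clog))
  tau2_frozen <- fit_pressure_sweep(cur, g, fl, seed = 47,
                                    fixed = list(kon_pore = truth$kon_pore))
  expect_equal(tau1_frozen$estimates[["kon_pore"]],
               free$estimates[["kon_pore"]], tolerance = 0.02)
  expect_equal(tau2_frozen$estimates[["koff_clog"]],
               free$estimates[["koff_clog"]], tolerance = 0.05)
  expect_equal(tau2_frozen$estimates[["kd_clog"]],
               free$estimates[["kd_clog"]], tolerance = 0.15)
})

test_that("fits are invariant under the CSV unit round-trip (mL <-> m^3)", {
  g <- geom200(); fl <- water()
  s <- preset_scenario("hiv_exit_200nm", seed = 53, noise = "gaussian_relative",
                       noise_sigma = 0.05, replicates = 1L)
  cur <- generate_frequency_curves(s)
  path <- withr::local_tempfile(fileext = ".csv")
  write_frequency_csv(cur, path)
  back <- read_frequency_csv(path)
  f1 <- fit_pressure_sweep(cur, g, fl, seed = 53)
  f2 <- fit_pressure_sweep(back, g, fl, seed = 53)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected with informative errors", {
  g <- geom200(); fl <- water()
  tiny <- data.frame(pressure = c(100, 200, 400), concentration = rep(1e14, 3),
                     frequency = c(1e-5, 2e-5, 3e-5), sem = rep(1e-6, 3))
  expect_error(fit_low_pressure(tiny, g, fl, window = "all"),
               "fewer than 4")
  one_c <- data.frame(pressure = logspace(10, 1000, 8),
                      concentration = rep(1e14, 8),
                      frequency = seq(1e-5, 8e-5, length.out = 8),
                      sem = rep(1e-6, 8))
  expect_error(fit_pressure_sweep(one_c, g, fl), ">= 2 concentrations")
  up <- suppressWarnings(clog_trace(seq(0, 100, 20), seq(0.1, 0.9, length.out = 6)))
  expect_error(fit_clog_dynamics(up), "non-decreasing")
  short <- generate_clog_trace(times = seq(0, 40, 10), sigma = 0)
  expect_error(fit_clog_dynamics(short), ">= 6")
})

test_that("the collapse metric measures deviation from identity and shrinks with noise", {
  set <- master_curve_set()[[1]]
  mp <- master_curve_points(set$d, set$params, set$geom, water())
  expect_lte(collapse_metric(mp), 1e-12)
  expect_equal(collapse_metric(data.frame(x = 0.4, y = 0.4)), 0)
  expect_error(collapse_metric(data.frame(x = c(1, 2), y = c(1, 2))), ">= 3")
  # monotone in noise level on average
  noisy_rms <- vapply(c(0.02, 0.10), function(sig) {
    mean(vapply(1:10, function(i) {
      d <- set$d
      d$frequency <- d$frequency * (1 + sig * with_seed(i, rnorm(nrow(d))))
      collapse_metric(master_curve_points(d, set$params, set$geom, water()))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(noisy_rms[1], 0)
  expect_gt(noisy_rms[2], noisy_rms[1])
})
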
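test_that("Arrhenius factor and adjustment round-trip at T_opt", {
  cases <- expand.grid(v = c(0.5, 100), ea = c(0, 30000, 80000),
                       t = c(298.15, 303.15))
  for (i in seq_len(nrow(cases))) {
    v <- cases$v[i]; ea <- cases$ea[i]; t <- cases$t[i]
    C <- arrhenius_factor(v, ea, t)
    expect_equal(adjust_vmax(C, ea, t), v, tolerance = 1e-12)
  }
  # ea = 0: C equals the measured activity, flat in temperature
  expect_equal(arrhenius_factor(7, 0, 303.15), 7)
  expect_equal(adjust_vmax(7, 0, 400), 7)
})

test_that("Arrhenius factor matches high-precision evaluation", {
  # frozen from a 30-digit arbitrary-precision evaluation of
  # exp(50000 / (8.314 * 303.15))
  C <- arrhenius_factor(100, 50000, 303.15)
  expect_equal(C / 100, 412689778.769426, tolerance = 1e-12)
  # closed-form ratio between two temperatures
  C2 <- arrhenius_factor(1, 60000, 303.15)
  ratio <- adjust_vmax(C2, 60000, 295.15) / adjust_vmax(C2, 60000, 307.15)
  expect_equal(ratio,
               exp(-60000 / 8.314 * (1 / 295.15 - 1 / 307.15)),
               tolerance = 1e-12)
  # monotone increasing in temperature for ea > 0
  temps <- seq(280, 320, by = 5)
  expect_true(all(diff(adjust_vmax(C2, 60000, temps)) > 0))
})

test_that("temperature unit guard rejects Celsius-looking input", {
  expect_error(adjust_vmax(10, 50000, 22), "Kelvin")
  expect_equal(celsius_to_kelvin(22), 295.15)
  expect_equal(celsius_to_kelvin(34), 307.15)
})

test_that("activity normalization to cell volume", {
  expect_equal(normalize_activity_to_volume(10.93, 10.93), 1)
  expect_equal(normalize_activity_to_volume(0, 8.26), 0)
  expect_error(normalize_activity_to_volume(1, 0), "positive")
})

test_that("mixed-inhibition rate law hits its closed-form anchors", {
  p <- kinetic_parameters(v_max = 6, k_m = 10, k_i_frc = 5, k_i_glc = 4)
  # half-saturation without inhibitors
  expect_equal(mixed_inhibition_rate(10, 0, 0, p), 3, tolerance = 1e-12)
  expect_equal(mixed_inhibition_rate(0, 3, 3, p), 0)
  # s=Km, f=Ki_frc, g=Ki_glc -> Vmax/6
  expect_equal(mixed_inhibition_rate(10, 5, 4, p), 1, tolerance = 1e-12)
  expect_error(mixed_inhibition_rate(-1, 0, 0, p), "non-negative")
})

test_that("rate law bounds and monotonicity hold", {
  p <- kinetic_parameters(v_max = 2, k_m = 8, k_i_frc = 6, k_i_glc = 3)
  s <- seq(0, 500, by = 10)
  v <- mixed_inhibition_rate(s, 2, 2, p)
  expect_true(all(v >= 0 & v < p$v_max))
  expect_true(all(diff(v) > 0))
  # decreasing in each inhibitor
  expect_gt(mixed_inhibition_rate(20, 1, 2, p),
            mixed_inhibition_rate(20, 5, 2, p))
  expect_gt(mixed_inhibition_rate(20, 2, 1, p),
            mixed_inhibition_rate(20, 2, 5, p))
})

test_that("infinite inhibition constants recover Michaelis-Menten", {
  scale <- 10
  p_inf <- kinetic_parameters(v_max = 2, k_m = 8, k_i_frc = 1e9 * scale,
                              k_i_glc = 1e9 * scale)
  p_mm <- kinetic_parameters(v_max = 2, k_m = 8, k_i_frc = 1,
                             k_i_glc = 1)
  s <- c(1, 8, 50)
  mm <- mixed_inhibition_rate(s, 0, 0, p_mm)
  expect_equal(mixed_inhibition_rate(s, 10, 10, p_inf), mm,
               tolerance = 1e-6)
})

test_that("rate curves order correctly and reach the right asymptote", {
  p <- kinetic_parameters(v_max = 4, k_m = 10, k_i_frc = 5, k_i_glc = 5)
  cur <- simulate_rate_curve(seq(0, 50, by = 5), f = 3, g = 2, p,
                             in_vivo_range = c(10, 30))
  expect_true(all(cur$rate_inhibited <= cur$rate_uninhibited))
  expect_true(all(cur$rate_inhibited[cur$s_mM > 0] <
                    cur$rate_uninhibited[cur$s_mM > 0]))
  expect_identical(cur$in_vivo, cur$s_mM >= 10 & cur$s_mM <= 30)
  # f = g = 0: curves coincide
  cur0 <- simulate_rate_curve(c(0, 5, 10), 0, 0, p)
  expect_equal(cur0$rate_inhibited, cur0$rate_uninhibited)
  # s -> infinity approaches Vmax / (1 + g/Ki_glc)
  far <- simulate_rate_curve(1e7, f = 3, g = 5, p)
  expect_equal(far$rate_inhibited, 4 / (1 + 5 / 5), tolerance = 1e-4)
  expect_error(simulate_rate_curve(numeric(0), 0, 0, p), "empty")
})

test_that("in vivo flux wires compartments to their invertases", {
  concs <- data.frame(
    metabolite = rep(c("sucrose", "glucose", "fructose"), 2),
    compartment = rep(c("cytosol", "vacuole"), each = 3),
    concentration_mM = c(40, 10, 8, 25, 4, 3))
  assays <- data.frame(enzyme = c("nInv", "aInv"),
                       vmax = c(1.5, 3),
                       t_opt_K = 303.15, ea_J_per_mol = 50000)
  params <- list(nInv = kinetic_parameters(k_m = 12, k_i_frc = 4,
                                           k_i_glc = 4),
                 aInv = kinetic_parameters(k_m = 10, k_i_frc = 6,
                                           k_i_glc = 6))
  fl <- in_vivo_flux(concs, assays, params, celsius_to_kelvin(22), 10.93)
  expect_equal(fl$compartment, c("cytosol", "vacuole"))
  # hand-computed expectation for nInv
  C <- arrhenius_factor(1.5, 50000, 303.15)
  vadj <- adjust_vmax(C, 50000, 295.15) / 10.93
  p <- params$nInv; p$v_max <- vadj
  expect_equal(fl$rate[1], mixed_inhibition_rate(40, 8, 10, p),
               tolerance = 1e-12)
  # zero hexoses: rate equals the uninhibited Michaelis-Menten value
  concs0 <- concs
  concs0$concentration_mM[concs0$metabolite != "sucrose"] <- 0
  fl0 <- in_vivo_flux(concs0, assays, params, celsius_to_kelvin(22),
                      10.93)
  expect_equal(fl0$rate, fl0$rate_uninhibited, tolerance = 1e-12)
  # homogeneity: doubling Vmax doubles the rate
  assays2 <- assays; assays2$vmax <- assays2$vmax * 2
  fl2 <- in_vivo_flux(concs, assays2, params, celsius_to_kelvin(22),
                      10.93)
  expect_equal(fl2$rate, 2 * fl$rate, tolerance = 1e-12)
  # hexose-loaded cytosol quenches nInv while vacuolar flux persists
  expect_lt(fl$rate[1] / fl$rate_uninhibited[1],
            fl$rate[2] / fl$rate_uninhibited[2])
  expect_error(in_vivo_flux(concs[-1, ], assays, params, 295.15, 10.93),
               "missing")
})
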
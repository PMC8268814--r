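test_that("counterion-corrected constant reduces correctly in limiting cases", {
  expect_equal(k_mic(123.4, sodium = 0.5, beta = 0, n = 10), 123.4)
  expect_equal(k_mic(123.4, sodium = 1, beta = 0.7, n = 10), 123.4)
  expect_equal(k_mic(1e10, sodium = 0.0765, beta = 0.5, n = 10),
               1e10 * 0.0765^5, tolerance = 1e-12)
})

test_that("free energy of demicellization follows (RT/n) ln K_mic", {
  expect_equal(delta_g_demic(1, 298.15, 10), 0)
  expect_equal(delta_g_demic(2.62e4, 298.15, 10),
               8.314 * 298.15 / 10 * log(2.62e4) / 1000, tolerance = 1e-12)
  expect_equal(delta_g_demic(2.62e4, 298.15, 10), 2.52, tolerance = 0.005)
  # doubling n halves the value
  expect_equal(delta_g_demic(50, 300, 20), delta_g_demic(50, 300, 10) / 2)
})

test_that("entropies recomputed from printed free energies and enthalpies match the table", {
  # NaAdC at 298.15 K and 283.15 K; the table rounds to 1 J/(mol K)
  expect_lt(abs(delta_s_demic(27.3, -2.9, 298.15) - (-101)), 0.5)
  expect_lt(abs(delta_s_demic(25.1, -8.2, 283.15) - (-118)), 0.5)
  expect_equal(delta_s_demic(5, 5, 300), 0)
})

test_that("heat capacity is the OLS slope of enthalpy against temperature", {
  tt <- c(288.15, 293.15, 298.15, 303.15, 313.15, 318.15)
  hh <- c(-6.4, -5.3, -3.2, -1.5, 1.5, 2.1)
  cp <- heat_capacity_demic(tt, hh)
  expect_equal(cp$dCp, ols_slope(tt, hh) * 1000, tolerance = 1e-9)
  expect_lt(abs(cp$dCp - 300) / 300, 0.02)
  expect_gt(cp$stderr, 0)
  expect_equal(heat_capacity_demic(c(280, 290, 300), rep(2.5, 3))$dCp, 0)
  expect_error(heat_capacity_demic(c(280, 290), c(1, 2)), ">= 3")
})

test_that("mole-fraction cmc uses the 55.5 M water convention", {
  expect_lt(abs(mole_fraction_from_cmc(0.323) - 5.82e-6), 0.01e-6)
  expect_lt(abs(mole_fraction_from_cmc(0.182) - 3.28e-6), 0.01e-6)
  expect_identical(mole_fraction_from_cmc(0), 0)
})

test_that("sodium term contribution is RT beta |ln Na| and vanishes in the limits", {
  v <- sodium_term_contribution(0.49, 10, 0.0765, 298.15)
  expect_equal(v, 8.314 * 298.15 * 0.49 * abs(log(0.0765)) / 1000,
               tolerance = 1e-12)
  expect_lt(abs(v - 3.12), 0.01)
  expect_equal(sodium_term_contribution(0, 10, 0.0765, 298.15), 0)
  expect_equal(sodium_term_contribution(0.5, 10, 1, 298.15), 0)
})

test_that("free-energy decomposition is consistent with the sodium term", {
  K <- 5e8; Na <- 0.0765; beta <- 0.63; n <- 10.8; temp <- 298.15
  dg_with <- delta_g_demic(k_mic(K, Na, beta, n), temp, n)
  dg_unit <- delta_g_demic(k_mic(K, 1, beta, n), temp, n)
  expect_equal(abs(dg_with - dg_unit),
               sodium_term_contribution(beta, n, Na, temp), tolerance = 1e-9)
})

test_that("thermo records satisfy Gibbs-Helmholtz bookkeeping by construction", {
  rec <- thermo_records(temperature = c(288.15, 298.15, 308.15),
                        cmc = c(0.45, 0.40, 0.42), n = c(9, 10, 11),
                        dG_demic = c(27, 28, 29), dH_demic = c(-5, -2, 1),
                        surfactant = "synthetic")
  expect_s3_class(rec, "thermo_records")
  expect_equal(rec$dG_demic, rec$dH_demic - rec$temperature * rec$dS_demic / 1000,
               tolerance = 1e-10)
  expect_equal(rec$x_cmc, rec$cmc / 55500, tolerance = 1e-12)
})

test_that("summaries aggregate aggregation numbers and heat capacity", {
  sm <- summarize_thermo(data.frame(
    temperature = c(283.15, 288.15, 293.15, 298.15),
    n = c(6.16, 6.53, 5.88, 7.38),
    dH_demic = c(-8.2, -6.5, -5.4, -2.9)))
  expect_equal(sm$mean_n, mean(c(6.16, 6.53, 5.88, 7.38)), tolerance = 1e-12)
  expect_lt(abs(sm$mean_n - 6.5), 0.1)
  expect_equal(sm$dCp,
               ols_slope(c(283.15, 288.15, 293.15, 298.15),
                         c(-8.2, -6.5, -5.4, -2.9)) * 1000, tolerance = 1e-9)
  # identical records have zero spread
  sm0 <- summarize_thermo(data.frame(temperature = c(300, 300),
                                     n = c(8, 8), dH_demic = c(1, 1)))
  expect_equal(sm0$sd_n, 0)
  expect_error(summarize_thermo(data.frame(temperature = 1, n = 1,
                                           dH_demic = 1)), ">= 2")
})
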
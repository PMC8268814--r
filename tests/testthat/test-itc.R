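test_that("cumulative concentrations follow the displacement model", {
  ser <- itc_series(10, 200, rep(2, 2), heats = c(0, 0))
  expect_equal(cumulative_concentrations(ser), 10 * (1 - 0.99^(1:2)),
               tolerance = 1e-12)
  ser1 <- itc_series(10, 200, 2, heats = 0)
  expect_equal(cumulative_concentrations(ser1), 0.1, tolerance = 1e-12)
  ser0 <- itc_series(10, 200, numeric(0), heats = numeric(0))
  expect_identical(cumulative_concentrations(ser0), numeric(0))
  bad <- itc_series(10, 200, 250, heats = 0)
  expect_error(cumulative_concentrations(bad), "invalid schedule")
})

test_that("itc_series validates its schedule", {
  expect_error(itc_series(10, 200, c(2, 2), heats = 1), "length")
  expect_error(itc_series(10, 200, c(2, -1), heats = c(1, 1)), "> 0")
  expect_error(itc_series(-1, 200, 2, heats = 1))
})

test_that("linearization of exact model data falls on the theoretical line", {
  # dense sampling so the staggered finite differences are effectively exact
  n <- 10
  p <- params_from_cmc(n, 0.45)
  s_tot <- 0.45 * 10^seq(-1.2, 1.2, length.out = 400)
  x_true <- monomer_derivative(monomer_concentration(s_tot, p), p)
  dH_demic <- -5; dH_dil <- -0.2
  heats <- dH_dil + dH_demic * x_true
  lin <- linearize_demicellization(heats, s_tot, dH_demic, dH_dil)
  fit <- lm(y ~ x, data = lin, weights = lin$weight)
  expect_gte(summary(fit)$r.squared, 0.999999)
  est <- aggregation_number_from_line(coef(fit)[1L], coef(fit)[2L])
  expect_equal(est$n, n, tolerance = 0.005)
  # pointwise: the line evaluated at x = 0.5 gives 0.9 + 8.1/2 = 4.95
  y_mid <- approx(lin$x, lin$y, xout = 0.5)$y
  expect_equal(y_mid, 4.95, tolerance = 1e-3)
})

test_that("a flipped demicellization-enthalpy sign makes every point unusable", {
  ser <- make_clean_series()
  conc <- cumulative_concentrations(ser)
  expect_error(
    linearize_demicellization(ser$heats, conc, dH_demic = +5, dH_dil = -0.2),
    "usable")
})

test_that("aggregation numbers invert the line parameters", {
  # perfectly consistent pair: intercept (n-1)/n, slope (n-1)^2/n at n = 10
  est <- aggregation_number_from_line(0.9, 8.1)
  expect_equal(est$n, 10, tolerance = 1e-4)
  expect_equal(est$n_intercept, 10, tolerance = 1e-10)
  expect_equal(est$n_slope, 10, tolerance = 1e-10)
  expect_true(est$consistent)

  # slope-only inversion: larger root of n^2 - 10.43 n + 1 = 0
  est2 <- aggregation_number_from_line(NA, 8.43)
  expect_equal(est2$n_slope, (10.43 + sqrt(10.43^2 - 4)) / 2,
               tolerance = 1e-12)
  expect_equal(est2$n, 10.33, tolerance = 0.01)

  # intercept-only
  est3 <- aggregation_number_from_line(0.89, -1)
  expect_equal(est3$n, 1 / (1 - 0.89), tolerance = 1e-10)

  # an inconsistent pair is flagged, not fatal
  expect_warning(est4 <- aggregation_number_from_line(0.5, 8.1), "disagree")
  expect_false(est4$consistent)

  expect_error(aggregation_number_from_line(1.4, -2), "usable")
})

test_that("noiseless synthetic titrations are recovered within tight tolerances", {
  ser <- make_clean_series(n = 10, cmc = 0.45, dH_demic = -5, dH_dil = -0.2)
  fit <- fit_demicellization(ser)
  expect_equal(fit$n, 10, tolerance = 0.02)
  expect_equal(fit$dH_demic, -5, tolerance = 0.01)
  expect_equal(fit$cmc, 0.45, tolerance = 0.02)
  expect_gte(fit$r_squared, 0.999999)
  # line self-consistency on clean data
  expect_equal(fit$line_intercept, 0.9, tolerance = 0.05)
  expect_equal(fit$line_slope, 8.1, tolerance = 0.05 * 8.1)

  # a second parameter set, exothermic-to-endothermic sign structure
  ser2 <- make_clean_series(n = 6, cmc = 0.33, dH_demic = 4, dH_dil = 0.5,
                            schedule = default_itc_schedule(syringe_conc = 5))
  fit2 <- fit_demicellization(ser2)
  expect_equal(fit2$n, 6, tolerance = 0.02)
  expect_equal(fit2$dH_demic, 4, tolerance = 0.01)
  expect_equal(fit2$cmc, 0.33, tolerance = 0.02)
})

test_that("fit is invariant to common rescaling of the heats", {
  ser <- make_clean_series()
  f1 <- fit_demicellization(ser)
  ser$heats <- ser$heats * 3.7
  f2 <- fit_demicellization(ser)
  expect_equal(f2$n, f1$n, tolerance = 1e-6)
  expect_equal(f2$cmc, f1$cmc, tolerance = 1e-6)
  expect_equal(f2$dH_demic, 3.7 * f1$dH_demic, tolerance = 1e-6)
  expect_equal(f2$dH_dil, 3.7 * f1$dH_dil, tolerance = 1e-4)
})

test_that("dropping the first injection barely moves the fit on clean data", {
  ser <- make_clean_series()
  f1 <- fit_demicellization(ser)
  f2 <- fit_demicellization(ser, drop_first = TRUE)
  expect_lt(abs(f2$n - f1$n) / f1$n, 0.01)
})

test_that("Monte-Carlo recovery at 2% heat noise keeps the median n error under 10%", {
  errs <- vapply(1:50, function(s) {
    truth <- synthetic_truth(n = 10, cmc = 0.45, dH_demic = -5, dH_dil = -0.2,
                             noise_sd = 0.1, seed = s)
    ser <- gen_itc_experiment(truth, default_itc_schedule())
    fit <- suppressWarnings(fit_demicellization(ser))
    abs(fit$n - 10) / 10
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})

test_that("degenerate titrations raise explicit errors", {
  ser <- make_clean_series()
  ser$heats <- rep(-0.2, length(ser$heats))
  expect_error(fit_demicellization(ser), "no cmc in scanned range")

  short <- itc_series(4, 200, rep(2, 5), heats = seq(-5, -1, length.out = 5))
  expect_error(fit_demicellization(short), "at least 10")
})
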
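test_that("monomer concentration solves the mass balance exactly in known cases", {
  # n = 2, K = 1: closed-form root of 2 s^2 + s - 1 = 0 is 0.5
  p <- mass_action_params(2, 1)
  expect_equal(monomer_concentration(1, p), 0.5, tolerance = 1e-10)
  # empty system
  expect_identical(monomer_concentration(0, p), 0)
  # vanishing K: no micelles, s = s_total
  p0 <- mass_action_params(2, 1e-300)
  expect_equal(monomer_concentration(5, p0), 5, tolerance = 1e-9)
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(mass_action_params(1.5, 1), "n")
  expect_error(mass_action_params(10, -1), "K")
  expect_error(monomer_concentration(-1, mass_action_params(2, 1)))
})

test_that("mass-balance residual stays below 1e-10 across extreme parameter ranges", {
  set.seed(42)
  for (i in 1:100) {
    n <- runif(1, 2, 60)
    K <- 10^runif(1, -3, 30)
    p <- mass_action_params(n, K)
    s_tot <- 10^runif(3, -3, 3)
    s <- monomer_concentration(s_tot, p)
    resid <- abs(s + n * K * exp(n * log(s)) - s_tot) / s_tot
    expect_true(all(resid <= 1e-10))
    # monotone nondecreasing in s_total
    o <- order(s_tot)
    expect_true(all(diff(s[o]) >= -1e-12))
  }
})

test_that("monomer solver agrees with a plain bisection oracle", {
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    n <- runif(1, 2, 20)
    K <- 10^runif(1, -3, 6)
    s_tot <- 10^runif(1, -2, 2)
    s_pkg <- monomer_concentration(s_tot, mass_action_params(n, K))
    s_ora <- bisect_monomer(s_tot, n, K)
    worst <- max(worst, abs(s_pkg - s_ora) / s_ora)
  }
  expect_lt(worst, 1e-9)
})

test_that("analytic monomer derivative matches known values and finite differences", {
  p <- mass_action_params(2, 1)
  expect_equal(monomer_derivative(0.5, p), 1 / 3, tolerance = 1e-12)
  # K -> 0 limit: monomers only
  expect_equal(monomer_derivative(3, mass_action_params(5, 1e-300)), 1,
               tolerance = 1e-12)
  # n = 10 with n^2 K s^(n-1) = 9 gives 1/10
  expect_equal(monomer_derivative(1, mass_action_params(10, 9 / 100)), 0.1,
               tolerance = 1e-12)

  # agreement with a central finite difference of the solver
  set.seed(11)
  for (i in 1:10) {
    p <- mass_action_params(runif(1, 2.5, 15), 10^runif(1, -2, 4))
    c0 <- 10^runif(1, -1, 1)
    h <- 1e-5 * c0
    fd <- (monomer_concentration(c0 + h, p) -
             monomer_concentration(c0 - h, p)) / (2 * h)
    an <- monomer_derivative(monomer_concentration(c0, p), p)
    expect_equal(an, fd, tolerance = 1e-6)
  }
})

test_that("equilibrium state respects its bounds", {
  p <- mass_action_params(10, 100)
  st <- equilibrium_state(10^seq(-3, 2, length.out = 40), p)
  expect_true(all(st$s_monomer >= 0 & st$s_monomer <= st$s_total))
  expect_true(all(st$micellar_fraction >= 0 & st$micellar_fraction < 1))
  expect_true(all(st$ds_dstot > 0 & st$ds_dstot <= 1))
})

test_that("the demicellization linearization identity holds with analytic derivatives", {
  # d ln{(ds/dStot)^-1 - 1} / d ln Stot == (n-1)/n + ((n-1)^2/n) ds/dStot,
  # with the left side evaluated through the chain rule on solver outputs:
  # t = n^2 K s^(n-1) gives d ln t/d ln Stot = (n-1) x Stot / s.
  set.seed(3)
  for (i in 1:20) {
    n <- runif(1, 2.2, 40)
    p <- params_from_cmc(max(n, 2.2), cmc = 10^runif(1, -1, 1))
    cmc <- cmc_from_params(p)
    s_tot <- cmc * 10^seq(-1.5, 1.5, length.out = 25)
    s <- monomer_concentration(s_tot, p)
    x <- monomer_derivative(s, p)
    lhs <- (p$n - 1) * x * s_tot / s
    rhs <- (p$n - 1) / p$n + (p$n - 1)^2 / p$n * x
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("cmc round trips are exact and ordered", {
  p <- params_from_cmc(10, 0.44)
  expect_equal(cmc_from_params(p), 0.44, tolerance = 1e-6)
  p2 <- params_from_cmc(10, 0.182)
  expect_equal(cmc_from_params(p2), 0.182, tolerance = 1e-6)
  # larger K at fixed n -> smaller cmc
  expect_lt(cmc_from_params(mass_action_params(10, 10 * p$K)),
            cmc_from_params(p))
  # mole-fraction convention round trip
  pm <- params_from_cmc(8, 0.5, convention = "mole_fraction")
  expect_equal(cmc_from_params(pm, convention = "mole_fraction"), 0.5,
               tolerance = 1e-6)
  # degenerate criterion at n = 2 is an explicit error
  expect_error(cmc_from_params(mass_action_params(2, 5)), "flat")
  expect_error(params_from_cmc(2, 0.5), "flat")
})

test_that("closed-form inflection cmc matches a numeric grid-and-refine oracle", {
  for (case in list(c(10, 0.45), c(6, 1.2), c(25, 0.08))) {
    p <- params_from_cmc(case[1L], case[2L])
    expect_equal(grid_cmc(p), case[2L], tolerance = 1e-3)
  }
})
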
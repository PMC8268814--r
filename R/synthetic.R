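# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Ground truth for a simulated demicellization experiment
#'
#' Bundles every parameter the simulators need, with the instrument-free
#' quantities a real study would report: the mass-action pair is derived
#' from \code{(n, cmc)} via [params_from_cmc()], so generator and fitter
#' share one cmc convention.
#'
#' @param n True aggregation number (> 2).
#' @param cmc True cmc in mM.
#' @param dH_demic Demicellization enthalpy (kJ/mol).
#' @param dH_dil Dilution enthalpy (kJ/mol).
#' @param beta Degree of counterion binding (for Corrin-Harkins series).
#' @param sodium Sodium concentration in M.
#' @param noise_sd Standard deviation of the Gaussian heat noise (kJ/mol);
#'   defaults to 1\% of \eqn{|\Delta H_{demic}|}.
#' @param seed Integer seed making every generated dataset reproducible.
#' @return An object of class \code{"synthetic_truth"} (also carrying the
#'   derived \code{params}).
#' @export
synthetic_truth <- function(n, cmc, dH_demic, dH_dil = 0, beta = 0.5,
                            sodium = 0.0765, noise_sd = 0.01 * abs(dH_demic),
                            seed = 1L) {
  params <- params_from_cmc(n, cmc)
  structure(list(n = n, cmc = cmc, params = params,
                 dH_demic = dH_demic, dH_dil = dH_dil,
                 beta = beta, sodium = sodium,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Default ITC injection schedule
#'
#' Mirrors the usual demicellization protocol on a 200 uL perfusion cell:
#' equal 2 uL injections of a 4 mM titrant, 38 injections, reaching roughly
#' three times a sub-millimolar cmc.
#'
#' @param n_injections Number of injections.
#' @param injection_volume Volume per injection (uL).
#' @param cell_volume Cell volume (uL).
#' @param syringe_conc Syringe concentration (mM).
#' @return A list with the four schedule fields, for [gen_itc_experiment()].
#' @export
default_itc_schedule <- function(n_injections = 38L, injection_volume = 2,
                                 cell_volume = 200, syringe_conc = 4) {
  list(n_injections = as.integer(n_injections),
       injection_volume = injection_volume,
       cell_volume = cell_volume,
       syringe_conc = syringe_conc)
}

#' Simulate a demicellization ITC titration
#'
#' Forward model of the enthalpogram: with cumulative cell concentrations
#' \eqn{c_i} (displacement bookkeeping, [cumulative_concentrations()]) and
#' monomer concentrations \eqn{s_i} from the mass-action model, the heat of
#' injection \eqn{i}, normalized per mole of injectant, is
#' \deqn{\Delta H_i = \Delta H_{dil} + \Delta H_{demic}
#'   \frac{s_i - s_{i-1}}{c_i - c_{i-1}} + \varepsilon_i,}
#' i.e. the dilution background plus the demicellization enthalpy weighted
#' by the fraction of injected surfactant that ends up as free monomer,
#' with additive Gaussian noise. Well below the cmc the heats plateau at
#' \eqn{\Delta H_{dil} + \Delta H_{demic}} (all injected micelles
#' dissolve), far above at \eqn{\Delta H_{dil}}.
#'
#' @param truth A [synthetic_truth()].
#' @param schedule A [default_itc_schedule()]-style list.
#' @param temperature Cell temperature (K), recorded in the series.
#' @param buffer_total_conc,pH Buffer metadata recorded in the series.
#' @return An [itc_series()]. Warns when the schedule never crosses the
#'   true cmc.
#' @export
gen_itc_experiment <- function(truth, schedule = default_itc_schedule(),
                               temperature = 298.15,
                               buffer_total_conc = 50.60, pH = 10.35) {
  stopifnot(inherits(truth, "synthetic_truth"))
  vols <- rep(schedule$injection_volume, schedule$n_injections)
  ser <- itc_series(schedule$syringe_conc, schedule$cell_volume, vols,
                    heats = numeric(schedule$n_injections),
                    temperature = temperature,
                    buffer_total_conc = buffer_total_conc, pH = pH,
                    label = sprintf("synthetic n=%.3g cmc=%.3g seed=%d",
                                    truth$n, truth$cmc, truth$seed))
  conc <- cumulative_concentrations(ser)
  if (max(conc) < truth$cmc)
    warning("injection schedule never crosses the cmc; no transition will be visible",
            call. = FALSE)
  s <- monomer_concentration(conc, truth$params)
  dmono <- diff(c(0, s)) / diff(c(0, conc))
  noise <- with_seed(truth$seed,
                     stats::rnorm(length(conc), 0, max(truth$noise_sd, 0)))
  ser$heats <- truth$dH_dil + truth$dH_demic * dmono + noise
  ser
}

#' Simulate a two-segment surface-tension curve
#'
#' Piecewise-linear in \eqn{(\ln c, \gamma)}, continuous at the break:
#' \eqn{\gamma = plateau + pre\_slope\,(\ln c - \ln cmc)} below the cmc and
#' \eqn{plateau + post\_slope\,(\ln c - \ln cmc)} above, plus Gaussian
#' noise.
#'
#' @param cmc True breakpoint concentration (mM).
#' @param pre_slope Slope below the cmc (mN/m per ln unit; negative for a
#'   surfactant).
#' @param plateau Surface tension at and above the cmc (mN/m).
#' @param noise_sd Gaussian noise on gamma (mN/m).
#' @param seed Integer seed (NULL uses the current RNG stream).
#' @param post_slope Slope above the cmc (default 0, a flat plateau).
#' @param n_points Number of log-spaced concentrations.
#' @param span Concentration range as multiples of the cmc.
#' @param temperature,label Passed to [surface_tension_curve()].
#' @return A [surface_tension_curve()].
#' @export
gen_surface_tension_curve <- function(cmc, pre_slope, plateau, noise_sd = 0,
                                      seed = 1L, post_slope = 0,
                                      n_points = 18L, span = c(1 / 8, 8),
                                      temperature = 298.15,
                                      label = "synthetic tensiometry") {
  stopifnot(cmc > 0, length(span) == 2L, all(span > 0))
  conc <- exp(seq(log(cmc * span[1L]), log(cmc * span[2L]),
                  length.out = n_points))
  dt <- log(conc) - log(cmc)
  g <- plateau + ifelse(dt <= 0, pre_slope * dt, post_slope * dt)
  g <- g + with_seed(seed, stats::rnorm(n_points, 0, max(noise_sd, 0)))
  surface_tension_curve(conc, g, temperature = temperature, label = label)
}

#' Simulate a Corrin-Harkins cmc / sodium series
#'
#' cmc values drawn from \eqn{cmc = 10^{A - \beta \log_{10}[\mathrm{Na^+}]}}
#' with multiplicative lognormal noise (keeping concentrations positive).
#'
#' @param A Intercept (log10 mM).
#' @param beta True degree of counterion binding, in \eqn{[0, 1]}.
#' @param sodium Sodium concentrations in M.
#' @param noise_sd Standard deviation of the log-scale noise (0.02 is 2\%
#'   relative noise on the cmc).
#' @param seed Integer seed (NULL uses the current RNG stream).
#' @return A data frame with columns \code{sodium} (M) and \code{cmc} (mM).
#' @export
gen_corrin_harkins_series <- function(A, beta, sodium = c(0.05, 0.15, 0.70),
                                      noise_sd = 0, seed = 1L) {
  stopifnot(beta >= 0, beta <= 1, all(sodium > 0))
  cmc <- 10^(A - beta * log10(sodium)) *
    exp(with_seed(seed, stats::rnorm(length(sodium), 0, max(noise_sd, 0))))
  data.frame(sodium = sodium, cmc = cmc)
}

#' Simulate a log P / cmc calibration dataset
#'
#' cmc values log-uniform over the span typical of bile-salt derivatives
#' (0.1--15 mM); log P from the linear calibration plus Gaussian noise.
#'
#' @param slope,intercept True calibration line (log10 units).
#' @param n Number of compounds (>= 3).
#' @param noise_sd Gaussian noise on log P.
#' @param seed Integer seed (NULL uses the current RNG stream).
#' @param cmc_range Span of the log-uniform cmc draw (mM).
#' @return A data frame with columns \code{cmc} (mM) and \code{logp}.
#' @export
gen_logp_cmc_dataset <- function(slope = -1.00, intercept = 2.79, n = 12L,
                                 noise_sd = 0, seed = 1L,
                                 cmc_range = c(0.1, 15)) {
  stopifnot(n >= 3L, all(cmc_range > 0))
  with_seed(seed, {
    cmc <- exp(stats::runif(n, log(cmc_range[1L]), log(cmc_range[2L])))
    logp <- intercept + slope * log10(cmc) +
      stats::rnorm(n, 0, max(noise_sd, 0))
    data.frame(cmc = cmc, logp = logp)
  })
}
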
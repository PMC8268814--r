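#' Gas constant used throughout (J mol-1 K-1)
#' @keywords internal
R_GAS <- 8.314

#' Counterion-corrected micellization constant
#'
#' For an ionic surfactant a fraction \eqn{\beta} of the counterions binds
#' to the micelle, and the mass-action constant must be corrected as
#' \deqn{K_{mic} = K\,[\mathrm{Na^+}]^{\beta n}.}
#' Computed in log space so large \eqn{K} and \eqn{\beta n} do not overflow.
#'
#' @param K Mass-action equilibrium constant (mM^(1-n)).
#' @param sodium Sodium concentration in M.
#' @param beta Degree of counterion binding, in \eqn{[0, 1]}.
#' @param n Aggregation number.
#' @return The corrected constant \eqn{K_{mic}}.
#' @export
k_mic <- function(K, sodium, beta, n) {
  stopifnot(all(K > 0), all(sodium > 0), all(beta >= 0), all(beta <= 1))
  exp(log(K) + beta * n * log(sodium))
}

#' Gibbs free energy of demicellization
#'
#' \deqn{\Delta G_{demic} = (RT/n)\,\ln K_{mic}} with
#' \eqn{R = 8.314} J mol-1 K-1. Per mole of monomer; positive for a stable
#' micelle (demicellization costs free energy).
#'
#' @param k_mic_value Counterion-corrected constant from [k_mic()].
#' @param temperature Temperature in K.
#' @param n Aggregation number (\eqn{\ge 2}).
#' @return \eqn{\Delta G_{demic}} in kJ/mol.
#' @export
delta_g_demic <- function(k_mic_value, temperature, n) {
  stopifnot(all(k_mic_value > 0), all(temperature > 0), all(n >= 2))
  (R_GAS * temperature / n) * log(k_mic_value) / 1000
}

#' Entropy of demicellization from the Gibbs-Helmholtz bookkeeping
#'
#' \deqn{\Delta S_{demic} = 1000\,(\Delta H - \Delta G)/T} (J mol-1 K-1,
#' with \eqn{\Delta G}, \eqn{\Delta H} in kJ/mol).
#'
#' @param dG Gibbs free energy of demicellization (kJ/mol).
#' @param dH Enthalpy of demicellization (kJ/mol).
#' @param temperature Temperature in K.
#' @return \eqn{\Delta S_{demic}} in J mol-1 K-1 (vectorized).
#' @export
delta_s_demic <- function(dG, dH, temperature) {
  stopifnot(all(temperature > 0))
  1000 * (dH - dG) / temperature
}

#' Heat capacity of demicellization
#'
#' \eqn{\Delta C_{P,demic}} is the slope of the demicellization enthalpy
#' versus temperature, obtained by ordinary least squares; it is positive
#' when hydrophobic surface becomes water-exposed on micelle dissociation.
#'
#' @param temperature Temperatures in K (at least 3 distinct values).
#' @param dH Demicellization enthalpies in kJ/mol, same length.
#' @return A list with \code{dCp} (J mol-1 K-1), its standard error
#'   \code{stderr}, and \code{n_points}.
#' @export
heat_capacity_demic <- function(temperature, dH) {
  stopifnot(length(temperature) == length(dH))
  if (length(unique(temperature)) < 3L)
    stop("heat_capacity_demic: need >= 3 distinct temperatures", call. = FALSE)
  fit <- stats::lm(dH ~ temperature)
  # a perfectly linear (e.g. constant) input is legitimate here
  sm <- suppressWarnings(summary(fit))$coefficients
  list(dCp = unname(stats::coef(fit)[2L]) * 1000,
       stderr = unname(sm["temperature", "Std. Error"]) * 1000,
       n_points = length(dH))
}

#' Mole-fraction cmc
#'
#' Converts a molar cmc to the mole-fraction scale by dividing by the
#' molarity of water (55.5 M by default, i.e. 55500 mM).
#'
#' @param cmc cmc in mM (vectorized).
#' @param water_molarity Molarity of water in M.
#' @return The cmc as a mole fraction.
#' @export
mole_fraction_from_cmc <- function(cmc, water_molarity = 55.5) {
  stopifnot(all(cmc >= 0), water_molarity > 0)
  cmc / (1000 * water_molarity)
}

#' Magnitude of the counterion term in the demicellization free energy
#'
#' The \eqn{[\mathrm{Na^+}]^{\beta n}} factor of \eqn{K_{mic}} contributes
#' \eqn{(RT/n)\ln [\mathrm{Na^+}]^{\beta n} = RT\beta\ln[\mathrm{Na^+}]}
#' to \eqn{\Delta G_{demic}}; the aggregation number cancels. Reported as a
#' magnitude (for sub-molar sodium the literal term is negative).
#'
#' @inheritParams k_mic
#' @param temperature Temperature in K.
#' @return \eqn{RT\beta\,|\ln[\mathrm{Na^+}]|} in kJ/mol.
#' @export
sodium_term_contribution <- function(beta, n, sodium, temperature) {
  stopifnot(all(sodium > 0), all(beta >= 0), all(beta <= 1),
            all(temperature > 0))
  R_GAS * temperature * beta * abs(log(sodium)) / 1000
}

#' Assemble a per-temperature demicellization record table
#'
#' Builds the standard per-temperature table of demicellization state
#' functions from cmc, aggregation number, \eqn{\Delta G} and
#' \eqn{\Delta H}: the entropy follows from [delta_s_demic()] and the
#' mole-fraction cmc from [mole_fraction_from_cmc()], so the Gibbs--Helmholtz
#' relation holds exactly by construction.
#'
#' @param temperature Temperatures in K.
#' @param cmc cmc values in mM.
#' @param n Aggregation numbers.
#' @param dG_demic Gibbs free energies of demicellization (kJ/mol).
#' @param dH_demic Demicellization enthalpies (kJ/mol).
#' @param surfactant Optional surfactant labels (recycled).
#' @param water_molarity Molarity of water (M) for the mole-fraction column.
#' @return A data frame of class \code{"thermo_records"} with columns
#'   \code{surfactant}, \code{cmc}, \code{x_cmc}, \code{temperature},
#'   \code{n}, \code{dG_demic}, \code{dH_demic}, \code{dS_demic}.
#' @export
thermo_records <- function(temperature, cmc, n, dG_demic, dH_demic,
                           surfactant = "", water_molarity = 55.5) {
  m <- length(temperature)
  stopifnot(length(cmc) == m, length(n) == m, length(dG_demic) == m,
            length(dH_demic) == m, all(temperature > 0), all(cmc >= 0))
  out <- data.frame(
    surfactant = rep_len(as.character(surfactant), m),
    cmc = cmc,
    x_cmc = mole_fraction_from_cmc(cmc, water_molarity),
    temperature = temperature,
    n = n,
    dG_demic = dG_demic,
    dH_demic = dH_demic,
    dS_demic = delta_s_demic(dG_demic, dH_demic, temperature)
  )
  class(out) <- c("thermo_records", "data.frame")
  out
}

#' Cross-temperature summary of demicellization records
#'
#' Mean and sample standard deviation of the aggregation number across
#' temperatures, plus the demicellization heat capacity from
#' [heat_capacity_demic()].
#'
#' @param records A data frame with columns \code{temperature}, \code{n}
#'   and \code{dH_demic} (e.g. from [thermo_records()]); at least 2 rows.
#' @return A list of class \code{"thermo_summary"} with \code{mean_n},
#'   \code{sd_n}, \code{dCp} (J mol-1 K-1), \code{dCp_stderr},
#'   \code{n_records} and the input \code{records}.
#' @export
summarize_thermo <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("temperature", "n", "dH_demic") %in% names(records)))
  if (nrow(records) < 2L)
    stop("summarize_thermo: need >= 2 records", call. = FALSE)
  cp <- if (length(unique(records$temperature)) >= 3L)
    heat_capacity_demic(records$temperature, records$dH_demic)
  else list(dCp = NA_real_, stderr = NA_real_)
  structure(list(
    mean_n = mean(records$n),
    sd_n = stats::sd(records$n),
    dCp = cp$dCp,
    dCp_stderr = cp$stderr,
    n_records = nrow(records),
    records = records
  ), class = "thermo_summary")
}

#' @export
print.thermo_summary <- function(x, ...) {
  cat(sprintf("Demicellization summary over %d temperatures\n", x$n_records))
  cat(sprintf("  mean n = %.1f +/- %.1f\n", x$mean_n, x$sd_n))
  if (is.finite(x$dCp))
    cat(sprintf("  dCp_demic = %.0f +/- %.0f J mol-1 K-1\n", x$dCp, x$dCp_stderr))
  invisible(x)
}
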
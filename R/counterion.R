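#' Corrin-Harkins analysis of the cmc / counterion dependence
#'
#' For ionic surfactants the cmc falls with the counterion concentration
#' following \deqn{\log_{10} cmc = A - \beta \log_{10}[\mathrm{Na^+}],}
#' where \eqn{\beta} is the degree of counterion binding. This fits the
#' line by ordinary least squares and returns \eqn{\beta} as the negative
#' slope. A \eqn{\beta} outside \eqn{[0, 1]} is physically meaningless and
#' is flagged with a warning, never clamped.
#'
#' @param cmc cmc values in mM (> 0).
#' @param sodium Sodium concentrations in M (> 0); at least 2 distinct values.
#' @return A list of class \code{"corrin_harkins_fit"} with \code{A}
#'   (intercept, log10 mM), \code{beta}, \code{r_squared}, \code{n_points}
#'   and logical \code{physical}.
#' @examples
#' corrin_harkins_fit(cmc = c(1, 0.5), sodium = c(0.1, 0.4))  # beta = 0.5
#' @export
corrin_harkins_fit <- function(cmc, sodium) {
  stopifnot(is.numeric(cmc), is.numeric(sodium), length(cmc) == length(sodium),
            all(cmc > 0), all(sodium > 0))
  if (length(unique(sodium)) < 2L)
    stop("corrin_harkins_fit: need >= 2 distinct sodium concentrations",
         call. = FALSE)
  line <- weighted_line_fit(log10(sodium), log10(cmc))
  beta <- -line$slope
  physical <- beta >= 0 && beta <= 1
  if (!physical)
    warning(sprintf("degree of counterion binding beta = %.3f is outside [0, 1]",
                    beta), call. = FALSE)
  structure(list(A = line$intercept, beta = beta,
                 r_squared = line$r_squared, n_points = length(cmc),
                 physical = physical),
            class = "corrin_harkins_fit")
}

#' @export
print.corrin_harkins_fit <- function(x, ...) {
  cat(sprintf(
    "Corrin-Harkins fit (%d points): log10 cmc = %.4f - %.4f log10[Na+], r^2 = %.4f\n",
    x$n_points, x$A, x$beta, x$r_squared))
  if (!x$physical) cat("  note: beta outside [0, 1]\n")
  invisible(x)
}

#' Sodium concentration of a carbonate/bicarbonate buffer
#'
#' Both buffer species carry sodium: NaHCO3 one ion, Na2CO3 two. With the
#' carbonate fraction \eqn{f = 1/(1 + 10^{pK_{a2} - pH})}
#' (Henderson--Hasselbalch for the second dissociation), the total sodium is
#' \eqn{[\mathrm{Na^+}] = c_{buffer}(1 + f)}.
#'
#' @param total_mM Total buffer concentration in mM.
#' @param pH Buffer pH.
#' @param pKa2 Second dissociation constant of carbonic acid (default
#'   10.33, the thermodynamic value at 25 C).
#' @return Sodium concentration in M (vectorized).
#' @examples
#' sodium_from_carbonate_buffer(50.60, pH = 10.35)  # 0.0765 M
#' @export
sodium_from_carbonate_buffer <- function(total_mM, pH, pKa2 = 10.33) {
  stopifnot(all(total_mM > 0))
  f <- 1 / (1 + 10^(pKa2 - pH))
  total_mM * (1 + f) / 1000
}
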
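#' Mass-action parameters of the monomer/micelle equilibrium
#'
#' The closed mass-action (pseudo-phase-separation-free) description of
#' micellization treats aggregation as a single equilibrium
#' \deqn{n\,S \rightleftharpoons M_n, \qquad K = [M_n]/[S]^n,}
#' between free monomers \eqn{S} and micelles \eqn{M_n} of aggregation
#' number \eqn{n}. All concentrations are in mM, so \eqn{K} carries units
#' of mM\eqn{^{1-n}}. Fits return non-integer \eqn{n}; any real
#' \eqn{n \ge 2} is accepted.
#'
#' @param n Aggregation number (dimensionless, \eqn{\ge 2}, not necessarily
#'   an integer).
#' @param K Micellization equilibrium constant in mM\eqn{^{1-n}}
#'   (strictly positive).
#' @return An object of class \code{"mass_action_params"}: a list with
#'   elements \code{n} and \code{K}.
#' @seealso [monomer_concentration()], [cmc_from_params()], [params_from_cmc()]
#' @examples
#' p <- mass_action_params(n = 10, K = 1e8)
#' monomer_concentration(1, p)
#' @export
mass_action_params <- function(n, K) {
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n),
            is.numeric(K), length(K) == 1L, is.finite(K))
  if (n < 2) stop("aggregation number `n` must be >= 2", call. = FALSE)
  if (K <= 0) stop("equilibrium constant `K` must be > 0", call. = FALSE)
  structure(list(n = as.numeric(n), K = as.numeric(K)),
            class = "mass_action_params")
}

#' @export
print.mass_action_params <- function(x, ...) {
  cat(sprintf("Mass-action micellization parameters: n = %.4g, K = %.6g mM^(1-n)\n",
              x$n, x$K))
  invisible(x)
}

# log(exp(a) + exp(b)) without overflow
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

solve_monomer_one <- function(s_total, params, rtol) {
  if (s_total == 0) return(0)
  n <- params$n
  lk <- log(params$K)
  # root of s + n K s^n = s_total in u = log(s); both terms kept in log space
  f <- function(u) logsumexp2(u, log(n) + lk + n * u) - log(s_total)
  u1 <- log(s_total)                       # f(u1) >= 0 always
  u0 <- u1 - 1
  it <- 0L
  while (f(u0) > 0) {
    u0 <- u0 - 8
    it <- it + 1L
    if (it > 300L)
      stop("monomer_concentration: failed to bracket the mass-balance root ",
           "(pathological parameters)", call. = FALSE)
  }
  s <- exp(stats::uniroot(f, c(u0, u1), tol = 1e-14)$root)
  # Newton polish in linear space; near the root neither term can overflow
  for (i in 1:3) {
    resid <- s + exp(log(n) + lk + n * log(s)) - s_total
    fp <- 1 + exp(2 * log(n) + lk + (n - 1) * log(s))
    s_new <- s - resid / fp
    if (is.finite(s_new) && s_new > 0) s <- s_new
  }
  resid <- s + exp(log(n) + lk + n * log(s)) - s_total
  if (!is.finite(resid) || abs(resid) > rtol * s_total)
    stop(sprintf(
      "monomer_concentration: solve did not converge (relative residual %.3e)",
      abs(resid) / s_total), call. = FALSE)
  s
}

#' Free-monomer concentration at a given total surfactant concentration
#'
#' Solves the mass balance \eqn{S_{tot} = [S] + nK[S]^n} for the free-monomer
#' concentration \eqn{[S]}. The root is bracketed in \eqn{\log [S]} (so that
#' \eqn{nK[S]^n} never overflows even for large \eqn{n} and \eqn{K}) and
#' polished by Newton steps; the relative mass-balance residual of the
#' returned value is guaranteed to be below \code{rtol}, otherwise an error
#' is raised (never a silent clamp).
#'
#' @param s_total Total surfactant concentration(s) in mM (vectorized,
#'   \eqn{\ge 0}).
#' @param params A [mass_action_params()] object.
#' @param rtol Maximum tolerated relative mass-balance residual.
#' @return Numeric vector of monomer concentrations (mM), the same length as
#'   \code{s_total}.
#' @examples
#' p <- mass_action_params(2, 1)
#' monomer_concentration(1, p)  # closed form: root of 2 s^2 + s - 1 = 0
#' @export
monomer_concentration <- function(s_total, params, rtol = 1e-10) {
  stopifnot(inherits(params, "mass_action_params"),
            is.numeric(s_total), all(is.finite(s_total)), all(s_total >= 0))
  vapply(s_total, solve_monomer_one, numeric(1), params = params, rtol = rtol)
}

#' Derivative of the monomer concentration with respect to total concentration
#'
#' Analytic derivative of the mass balance:
#' \deqn{d[S]/dS_{tot} = 1 / (1 + n^2 K [S]^{n-1}),}
#' evaluated in log space (as an inverse logit) so it is accurate for any
#' magnitude of \eqn{n^2 K [S]^{n-1}}. Always lies in \eqn{(0, 1]}.
#'
#' @param s_monomer Free-monomer concentration(s) in mM (vectorized).
#' @inheritParams monomer_concentration
#' @return Numeric vector of dimensionless derivatives in \eqn{(0, 1]}.
#' @export
monomer_derivative <- function(s_monomer, params) {
  stopifnot(inherits(params, "mass_action_params"),
            is.numeric(s_monomer), all(s_monomer >= 0))
  t <- 2 * log(params$n) + log(params$K) + (params$n - 1) * log(s_monomer)
  stats::plogis(-t)
}

#' Full equilibrium state of the aggregation equilibrium
#'
#' Convenience wrapper returning, for each total concentration, the monomer
#' concentration, the fraction of surfactant held in micelles, and the
#' derivative \eqn{d[S]/dS_{tot}}.
#'
#' @inheritParams monomer_concentration
#' @return A data frame with columns \code{s_total}, \code{s_monomer},
#'   \code{micellar_fraction} and \code{ds_dstot}.
#' @export
equilibrium_state <- function(s_total, params) {
  s <- monomer_concentration(s_total, params)
  data.frame(
    s_total = s_total,
    s_monomer = s,
    micellar_fraction = ifelse(s_total > 0, pmax(0, 1 - s / s_total), 0),
    ds_dstot = monomer_derivative(s, params)
  )
}

# Interior value t* = n^2 K s*^(n-1) at which d2[S]/dStot2 is extremal.
# Writing D2(s) = -(n-1) n^2 K s^(n-2) / (1 + n^2 K s^(n-1))^3 and setting
# d log|D2| / d log s = 0 gives t* = (n-2)/(2n-1); degenerate at n = 2.
inflection_t_star <- function(n) (n - 2) / (2 * n - 1)

#' Critical micelle concentration implied by mass-action parameters
#'
#' The mass-action model has no sharp transition, so a convention is needed
#' to attach a single cmc to an \eqn{(n, K)} pair. The default
#' (\code{"inflection"}) takes the total concentration at which
#' \eqn{d^2[S]/dS_{tot}^2} is extremal -- the steepest point of the sigmoid
#' ITC transition, i.e. the operational transition center. That extremum has
#' the closed form \eqn{n^2 K s^{*\,n-1} = (n-2)/(2n-1)} in the monomer
#' concentration \eqn{s^*}, and \eqn{cmc = s^*(1 + t^*/n)}. The alternative
#' \code{"mole_fraction"} convention uses \eqn{K = x_{cmc}^{-n}} with the
#' cmc expressed as a mole fraction.
#'
#' @inheritParams monomer_concentration
#' @param convention \code{"inflection"} (default) or \code{"mole_fraction"}.
#' @param water_molarity Molarity of water (M) used by the mole-fraction
#'   convention.
#' @return The cmc in mM.
#' @seealso [params_from_cmc()] for the exact inverse.
#' @export
cmc_from_params <- function(params, convention = c("inflection", "mole_fraction"),
                            water_molarity = 55.5) {
  convention <- match.arg(convention)
  n <- params$n
  if (convention == "mole_fraction")
    return(1000 * water_molarity * exp(-log(params$K) / n))
  if (n <= 2)
    stop("the inflection cmc criterion is flat for n <= 2; no cmc is defined",
         call. = FALSE)
  t_star <- inflection_t_star(n)
  log_s_star <- (log(t_star) - 2 * log(n) - log(params$K)) / (n - 1)
  cmc <- exp(log_s_star) * (1 + t_star / n)
  if (!is.finite(cmc) || cmc <= 0)
    stop("cmc criterion over/underflowed for these parameters", call. = FALSE)
  cmc
}

#' Mass-action parameters from an aggregation number and a cmc
#'
#' Exact inverse of [cmc_from_params()] under the same convention: given
#' \eqn{n} and the cmc it returns the \eqn{K} whose implied cmc is the one
#' supplied.
#'
#' @param n Aggregation number (\eqn{> 2} for the inflection convention).
#' @param cmc Critical micelle concentration in mM.
#' @inheritParams cmc_from_params
#' @return A [mass_action_params()] object.
#' @examples
#' p <- params_from_cmc(10, 0.44)
#' cmc_from_params(p)  # 0.44
#' @export
params_from_cmc <- function(n, cmc, convention = c("inflection", "mole_fraction"),
                            water_molarity = 55.5) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2,
            is.numeric(cmc), length(cmc) == 1L, cmc > 0)
  if (convention == "mole_fraction") {
    x <- cmc / (1000 * water_molarity)
    return(mass_action_params(n, exp(-n * log(x))))
  }
  if (n <= 2)
    stop("the inflection cmc criterion is flat for n <= 2; K is not identifiable",
         call. = FALSE)
  t_star <- inflection_t_star(n)
  s_star <- cmc / (1 + t_star / n)
  K <- exp(log(t_star) - 2 * log(n) - (n - 1) * log(s_star))
  mass_action_params(n, K)
}
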
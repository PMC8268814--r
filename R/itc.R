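#' One isothermal-titration-calorimetry dilution experiment
#'
#' Container for a demicellization ITC titration: a concentrated (well above
#' the cmc) surfactant solution is injected stepwise into buffer, and the
#' heat evolved per mole of injectant is recorded for every injection.
#'
#' @param syringe_conc Syringe (titrant) concentration in mM.
#' @param cell_volume Calorimeter cell volume in microlitres.
#' @param injection_volumes Per-injection volumes in microlitres.
#' @param heats Per-injection heats normalized per mole of injectant
#'   (kJ/mol); same length as \code{injection_volumes}.
#' @param temperature Cell temperature in K.
#' @param buffer_total_conc Total buffer concentration in mM (optional,
#'   used for sodium speciation).
#' @param pH Buffer pH (optional).
#' @param label Free-text label for the experiment.
#' @return An object of class \code{"itc_series"}.
#' @seealso [fit_demicellization()], [gen_itc_experiment()], [read_itc_series()]
#' @export
itc_series <- function(syringe_conc, cell_volume, injection_volumes, heats,
                       temperature = 298.15, buffer_total_conc = NA_real_,
                       pH = NA_real_, label = "") {
  stopifnot(is.numeric(syringe_conc), length(syringe_conc) == 1L, syringe_conc > 0,
            is.numeric(cell_volume), length(cell_volume) == 1L, cell_volume > 0,
            is.numeric(injection_volumes), is.numeric(heats),
            is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  if (length(injection_volumes) != length(heats))
    stop("`injection_volumes` and `heats` must have the same length", call. = FALSE)
  if (length(injection_volumes) && any(injection_volumes <= 0))
    stop("all injection volumes must be > 0", call. = FALSE)
  structure(list(
    syringe_conc = syringe_conc,
    cell_volume = cell_volume,
    injection_volumes = as.numeric(injection_volumes),
    heats = as.numeric(heats),
    temperature = temperature,
    buffer_total_conc = buffer_total_conc,
    pH = pH,
    label = as.character(label)
  ), class = "itc_series")
}

#' @export
print.itc_series <- function(x, ...) {
  cat(sprintf("ITC titration \"%s\": %d injections of %s uL, syringe %.4g mM, cell %.4g uL, T = %.2f K\n",
              x$label, length(x$heats),
              paste(format(unique(x$injection_volumes)), collapse = "/"),
              x$syringe_conc, x$cell_volume, x$temperature))
  if (length(x$heats))
    cat(sprintf("  heats: %.3f .. %.3f kJ/mol\n", x$heats[1L],
                x$heats[length(x$heats)]))
  invisible(x)
}

#' Cumulative cell concentration after each injection
#'
#' Standard perfusion-cell displacement bookkeeping: each injection of
#' volume \eqn{v_j} displaces an equal volume of mixed cell content, so the
#' total surfactant concentration after injection \eqn{i} is
#' \deqn{c_i = c_{syr}\bigl(1 - \prod_{j \le i}(1 - v_j/V_0)\bigr).}
#'
#' @param series An [itc_series()] object.
#' @return Strictly increasing numeric vector of total concentrations (mM),
#'   one per injection (empty schedule gives an empty vector).
#' @export
cumulative_concentrations <- function(series) {
  stopifnot(inherits(series, "itc_series"))
  v <- series$injection_volumes
  if (!length(v)) return(numeric(0))
  if (any(v >= series$cell_volume))
    stop("invalid schedule: injection volume >= cell volume", call. = FALSE)
  series$syringe_conc * (1 - cumprod(1 - v / series$cell_volume))
}

# Weighted straight-line fit; closed form, returns weighted r^2.
weighted_line_fit <- function(x, y, w = rep(1, length(x))) {
  sw <- sum(w)
  xm <- sum(w * x) / sw
  ym <- sum(w * y) / sw
  sxx <- sum(w * (x - xm)^2)
  syy <- sum(w * (y - ym)^2)
  sxy <- sum(w * (x - xm) * (y - ym))
  if (sxx <= 0) stop("degenerate abscissa in line fit", call. = FALSE)
  slope <- sxy / sxx
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 1
  list(intercept = ym - slope * xm, slope = slope, r_squared = r2)
}


#' Linearization of demicellization heats
#'
#' Transforms per-injection heats into the straight-line form used to read
#' off the aggregation number. The demicellization degree
#' \eqn{x_i = (\Delta H_i - \Delta H_{dil})/\Delta H_{demic}} estimates
#' \eqn{d[S]/dS_{tot}}, and the mass-action model obeys the exact identity
#' \deqn{\frac{d\,\ln\{x^{-1} - 1\}}{d\,\ln S_{tot}} =
#'   \frac{n-1}{n} + \frac{(n-1)^2}{n}\,x,}
#' so plotting the log-derivative \eqn{y} against \eqn{x} yields a line with
#' intercept \eqn{(n-1)/n} and slope \eqn{(n-1)^2/n}. The derivative is
#' estimated on a staggered grid: each two-point difference of
#' \eqn{\ln(x^{-1}-1)} is centred on the midpoint between consecutive
#' \eqn{\ln S_{tot}} values and paired with the mean of the two \eqn{x}
#' values, which halves the truncation bias of a collocated central
#' stencil near the steep transition. The two extreme differences are
#' down-weighted by 0.5. Points whose \eqn{x} falls outside
#' \code{(clip, 1 - clip)} are dropped and counted; propagating the heat
#' noise through \eqn{\ln(x^{-1}-1)} and the difference quotient gives each
#' point the inverse-variance weight \eqn{(x(1-x)\,\Delta\ln S_{tot})^2}.
#'
#' @param heats Per-injection heats (kJ/mol).
#' @param s_totals Total concentrations (mM) the heats refer to; strictly
#'   increasing, same length as \code{heats}.
#' @param dH_demic Demicellization enthalpy (kJ/mol), nonzero.
#' @param dH_dil Dilution enthalpy (kJ/mol).
#' @param clip Exclusion bound: usable points need \eqn{x \in} (clip, 1-clip).
#' @return A data frame with one row per staggered difference and columns
#'   \code{s_total} (geometric mean of the pair), \code{x}, \code{y} and
#'   \code{weight}; the number of discarded input points is attached as
#'   attribute \code{"n_dropped"}. Fails with an explicit error when fewer
#'   than 4 usable points remain.
#' @export
linearize_demicellization <- function(heats, s_totals, dH_demic, dH_dil,
                                      clip = 1e-4) {
  stopifnot(length(heats) == length(s_totals), is.numeric(dH_demic),
            is.numeric(dH_dil), dH_demic != 0)
  x_all <- (heats - dH_dil) / dH_demic
  keep <- is.finite(x_all) & x_all > clip & x_all < 1 - clip
  if (sum(keep) < 4L)
    stop(sprintf(paste0(
      "linearize_demicellization: only %d usable points with degree of ",
      "demicellization in (0,1); fitting impossible ",
      "(check the signs of dH_demic/dH_dil)"), sum(keep)), call. = FALSE)
  xk <- x_all[keep]
  l <- log(s_totals[keep])
  z <- log(1 / xk - 1)
  m <- length(l)
  y <- diff(z) / diff(l)
  x <- (xk[-1L] + xk[-m]) / 2
  # inverse-variance weights: var(y) from heat noise scales as
  # 1 / (x (1-x) dl)^2 through z = ln(1/x - 1) and the difference quotient
  w <- (x * (1 - x) * diff(l))^2
  w[c(1L, length(w))] <- w[c(1L, length(w))] * 0.5
  out <- data.frame(s_total = exp((l[-1L] + l[-m]) / 2), x = x, y = y,
                    weight = w)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Aggregation number from the linearized-plot intercept and slope
#'
#' Inverts the line parameters of [linearize_demicellization()]: the
#' intercept is \eqn{(n-1)/n} and the slope \eqn{(n-1)^2/n}. Returns the
#' intercept-only estimate \eqn{1/(1-intercept)}, the slope-only estimate
#' (larger root of \eqn{n^2 - (slope+2)n + 1 = 0}), and a joint estimate
#' minimizing the sum of squared relative residuals of both line parameters
#' (each residual divided by the magnitude of its observed value, so the two
#' are commensurate).
#'
#' @param intercept Observed intercept (usable when in (0,1)).
#' @param slope Observed slope (usable when > 0).
#' @return A list with \code{n} (joint), \code{n_intercept}, \code{n_slope}
#'   and logical \code{consistent} (FALSE, with a warning, when the two
#'   single-parameter estimates disagree by more than 50\%).
#' @export
aggregation_number_from_line <- function(intercept, slope) {
  n_int <- if (is.finite(intercept) && intercept > 0 && intercept < 1)
    1 / (1 - intercept) else NA_real_
  n_slope <- if (is.finite(slope) && slope > 0) {
    b <- slope + 2
    (b + sqrt(b^2 - 4)) / 2
  } else NA_real_
  if (is.na(n_int) && is.na(n_slope))
    stop("neither intercept in (0,1) nor slope > 0: no usable line parameter",
         call. = FALSE)
  if (!is.na(n_int) && !is.na(n_slope)) {
    s_int <- max(abs(intercept), 1e-3)
    s_slp <- max(abs(slope), 1e-3)
    obj <- function(n)
      ((intercept - (n - 1) / n) / s_int)^2 +
      ((slope - (n - 1)^2 / n) / s_slp)^2
    upper <- max(4, 4 * max(n_int, n_slope))
    n_joint <- stats::optimize(obj, c(2, upper), tol = 1e-10)$minimum
  } else {
    n_joint <- if (is.na(n_int)) n_slope else n_int
  }
  consistent <- TRUE
  if (!is.na(n_int) && !is.na(n_slope)) {
    rel <- abs(n_int - n_slope) / mean(c(n_int, n_slope))
    if (rel > 0.5) {
      consistent <- FALSE
      warning(sprintf(
        "intercept- and slope-based aggregation numbers disagree by %.0f%%",
        100 * rel), call. = FALSE)
    }
  }
  list(n = max(2, n_joint), n_intercept = n_int, n_slope = n_slope,
       consistent = consistent)
}

# Concentration each injection heat is attributed to: the secant
# (s_i - s_{i-1})/(c_i - c_{i-1}) is closest to the derivative at the
# interval midpoint.
injection_midpoints <- function(conc) (c(0, conc[-length(conc)]) + conc) / 2

# Demicellization degree at the model's transition center (the inflection
# point of the enthalpogram): x* = 1/(1 + t*) with t* = (n-2)/(2n-1).
transition_center_x <- function(n) 1 / (1 + inflection_t_star(n))

# Weighted fit of the one-parameter mass-action line family
# y = (n-1)/n + ((n-1)^2/n) x; returns the best n and its RSS.  Constraining
# the inner fit to this family keeps the outer enthalpy search from settling
# on highly linear but unphysical configurations.
constrained_line_fit <- function(x, y, w) {
  f <- function(n) {
    a <- (n - 1) / n
    b <- (n - 1)^2 / n
    sum(w * (y - a - b * x)^2)
  }
  o <- stats::optimize(f, c(2.0001, 500), tol = 1e-9)
  list(n = o$minimum, rss = o$objective)
}

# cmc estimate: log-interpolated crossing of the raw demicellization degree
# through the model's transition-center value x*(n).
cmc_from_crossing <- function(x_raw, mids, n_hat) {
  m <- length(x_raw)
  x_star <- transition_center_x(n_hat)
  dx <- x_raw - x_star
  cross <- which(dx[-m] * dx[-1L] <= 0 & is.finite(dx[-m]) & is.finite(dx[-1L]))
  if (!length(cross))
    stop("no cmc in scanned range: the titration never crosses the transition center",
         call. = FALSE)
  i <- cross[1L]
  exp(log(mids[i]) + (x_star - x_raw[i]) *
        (log(mids[i + 1L]) - log(mids[i])) / (x_raw[i + 1L] - x_raw[i]))
}

#' Fit the mass-action demicellization model to an ITC titration
#'
#' Full analysis of one dilution enthalpogram. An outer Nelder--Mead search
#' over \eqn{(\Delta H_{demic}, \Delta H_{dil})}, initialized from the first
#' and last 10\% plateau means, maximizes the linearity of the
#' [linearize_demicellization()] plot, scored as the normalized weighted
#' residual of the inner fit; the inner fit is constrained to the
#' mass-action line family \eqn{y = (n-1)/n + ((n-1)^2/n)\,x}, so its
#' single parameter is the aggregation number itself. Because the
#' linearization differentiates discretely sampled data, its points carry
#' a small schedule-dependent truncation bias even for noise-free model
#' data; the fit therefore alternates the outer search with a model-based
#' correction (the current parameter estimates are pushed through a
#' noise-free simulation of the same injection schedule, the systematic
#' residual of the linearized points from the exact line is measured and
#' subtracted from the data before the next round, while the search box
#' shrinks to a trust region). On clean model data this self-consistent
#' loop converges to the generating parameters; the unconstrained line
#' diagnostics (intercept, slope, \eqn{r^2}, and the single-parameter
#' estimates of [aggregation_number_from_line()]) are reported alongside.
#' The cmc is read off as the concentration at which the demicellization
#' degree crosses the model's transition-center value
#' \eqn{x^* = (2n-1)/(3(n-1))} (the inflection point of the sigmoid,
#' matching the convention of [cmc_from_params()]), and \eqn{K} follows
#' from [params_from_cmc()].
#'
#' @param series An [itc_series()] with at least 10 injections spanning the
#'   transition.
#' @param drop_first Drop the first injection (common ITC practice for the
#'   diffusion-contaminated first aliquot)? Default \code{FALSE}.
#' @param clip Passed to [linearize_demicellization()].
#' @param iterations Number of outer-search / bias-correction rounds.
#' @param control Passed to [stats::optim()] for the outer search.
#' @return An object of class \code{"demic_fit"}: a list with elements
#'   \code{n}, \code{dH_demic}, \code{dH_dil}, \code{K}, \code{cmc},
#'   \code{line_intercept}, \code{line_slope}, \code{r_squared},
#'   \code{n_intercept}, \code{n_slope}, \code{consistent},
#'   \code{n_dropped}, \code{convergence} and \code{temperature}.
#' @examples
#' truth <- synthetic_truth(n = 10, cmc = 0.45, dH_demic = -5, dH_dil = -0.2,
#'                          noise_sd = 0)
#' ser <- gen_itc_experiment(truth, default_itc_schedule())
#' fit_demicellization(ser)
#' @export
fit_demicellization <- function(series, drop_first = FALSE, clip = 1e-4,
                                iterations = 3L,
                                control = list(maxit = 2000, reltol = 1e-12)) {
  stopifnot(inherits(series, "itc_series"))
  conc <- cumulative_concentrations(series)
  heats <- series$heats
  mids <- injection_midpoints(conc)
  if (drop_first && length(heats)) {
    conc_sim <- conc
    mids <- mids[-1L]
    heats <- heats[-1L]
  } else {
    conc_sim <- conc
  }
  m <- length(heats)
  if (m < 10L)
    stop("fit_demicellization: need at least 10 injections", call. = FALSE)

  # transition sanity: the heats must actually move between two plateaus
  sigma_hat <- stats::mad(diff(heats)) / sqrt(2)
  rng <- diff(range(heats))
  if (rng < max(5 * sigma_hat, 1e-8 * max(abs(heats), 1)))
    stop("no cmc in scanned range: heat range does not exceed the noise floor",
         call. = FALSE)

  k <- max(2L, ceiling(0.1 * m))
  dil0 <- mean(heats[(m - k + 1L):m])
  demic0 <- mean(heats[1:k]) - dil0
  if (abs(demic0) < 1e-12)
    stop("no cmc in scanned range: plateau heats are indistinguishable",
         call. = FALSE)

  bias_fun <- function(x) rep(0, length(x))
  # guard against runaway scales: r^2 alone is scale-free, so keep the
  # enthalpies within a box around the current center.  Round 1 searches a
  # broad region around the plateau-derived start; once the model-based
  # bias correction is active the box shrinks to a trust region around the
  # previous round (the correction could otherwise manufacture spurious
  # highly-linear solutions far from the data-determined plateaus).
  box <- list(center = c(demic0, dil0), ratio = 2.5, dil_width = 1)
  penalty <- function(par) {
    p <- 0
    r1 <- par[1L] / box$center[1L]
    if (!is.finite(r1) || r1 <= 0) return(100)
    if (r1 < 1 / box$ratio || r1 > box$ratio)
      p <- p + 1 + 10 * (abs(log(r1)) - log(box$ratio))^2
    d2 <- abs(par[2L] - box$center[2L]) / abs(box$center[1L])
    if (d2 > box$dil_width) p <- p + 1 + 10 * (d2 - box$dil_width)^2
    p
  }
  objective <- function(par) {
    pen <- penalty(par)
    if (pen >= 100) return(100)
    tryCatch({
      lin <- linearize_demicellization(heats, mids, par[1L], par[2L], clip = clip)
      yc <- lin$y - bias_fun(lin$x)
      cf <- constrained_line_fit(lin$x, yc, lin$weight)
      sw <- sum(lin$weight)
      ym <- sum(lin$weight * yc) / sw
      tss <- max(sum(lin$weight * (yc - ym)^2), 1e-300)
      cf$rss / tss + pen
    }, error = function(e) 2 + pen)
  }

  par <- c(demic0, dil0)
  n_hat <- NA_real_
  lin <- NULL
  yc <- NULL
  cmc <- NA_real_
  opt <- NULL
  for (round in seq_len(max(1L, iterations))) {
    opt <- stats::optim(par, objective, method = "Nelder-Mead", control = control)
    par <- opt$par
    lin <- linearize_demicellization(heats, mids, par[1L], par[2L], clip = clip)
    yc <- lin$y - bias_fun(lin$x)
    n_hat <- constrained_line_fit(lin$x, yc, lin$weight)$n
    x_raw <- (heats - par[2L]) / par[1L]
    cmc <- cmc_from_crossing(x_raw, mids, n_hat)
    if (round == max(1L, iterations)) break
    # measure the linearization's own truncation residual on noise-free
    # model data over this schedule, at the current parameter estimates
    p_hat <- params_from_cmc(n_hat, cmc)
    s_model <- monomer_concentration(conc_sim, p_hat)
    h_model <- par[2L] + par[1L] * diff(c(0, s_model)) / diff(c(0, conc_sim))
    if (drop_first) h_model <- h_model[-1L]
    bias_ok <- tryCatch({
      lin_m <- linearize_demicellization(h_model, mids, par[1L], par[2L],
                                         clip = clip)
      resid_m <- lin_m$y -
        ((n_hat - 1) / n_hat + (n_hat - 1)^2 / n_hat * lin_m$x)
      xg <- lin_m$x
      bg <- resid_m
      bias_fun <- function(x) stats::approx(xg, bg, xout = x, rule = 2)$y
      TRUE
    }, error = function(e) FALSE)
    if (!bias_ok) break
    box <- list(center = par, ratio = 1.3, dil_width = 0.15)
  }
  # unconstrained line diagnostics on the bias-corrected points
  line <- weighted_line_fit(lin$x, yc, lin$weight)
  agg <- aggregation_number_from_line(line$intercept, line$slope)
  K <- params_from_cmc(n_hat, cmc)$K

  structure(list(
    n = n_hat, dH_demic = par[1L], dH_dil = par[2L], K = K, cmc = cmc,
    line_intercept = line$intercept, line_slope = line$slope,
    r_squared = line$r_squared,
    n_intercept = agg$n_intercept, n_slope = agg$n_slope,
    consistent = agg$consistent,
    n_dropped = attr(lin, "n_dropped"),
    convergence = opt$convergence,
    temperature = series$temperature,
    label = series$label
  ), class = "demic_fit")
}

#' @export
print.demic_fit <- function(x, ...) {
  cat("Mass-action demicellization fit\n")
  cat(sprintf("  n        = %.3f  (intercept-only %.3f, slope-only %.3f)\n",
              x$n, x$n_intercept, x$n_slope))
  cat(sprintf("  dH_demic = %.4g kJ/mol, dH_dil = %.4g kJ/mol\n",
              x$dH_demic, x$dH_dil))
  cat(sprintf("  cmc      = %.4g mM,  K = %.4g mM^(1-n)\n", x$cmc, x$K))
  cat(sprintf("  line: intercept %.4f, slope %.4f, r^2 = %.6f  (%d points dropped)\n",
              x$line_intercept, x$line_slope, x$r_squared, x$n_dropped))
  if (!x$consistent)
    cat("  warning: intercept- and slope-based n estimates are inconsistent\n")
  invisible(x)
}
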
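#' Surface-tension vs concentration curve
#'
#' Container for a tensiometry dilution series: surface tension gamma
#' (mN/m) measured at strictly increasing surfactant concentrations. Below
#' the cmc gamma falls roughly linearly in \eqn{\ln c}; above it the curve
#' flattens, and the break locates the cmc.
#'
#' @param concentration Concentrations in mM, strictly increasing, > 0.
#' @param gamma Surface tensions in mN/m, same length; at least 6 points.
#' @param temperature Temperature in K.
#' @param label Free-text label.
#' @return An object of class \code{"surface_tension_curve"}.
#' @seealso [detect_cmc_breakpoint()], [gen_surface_tension_curve()]
#' @export
surface_tension_curve <- function(concentration, gamma, temperature = 298.15,
                                  label = "") {
  stopifnot(is.numeric(concentration), is.numeric(gamma),
            length(concentration) == length(gamma))
  if (length(concentration) < 6L)
    stop("surface_tension_curve: need >= 6 points", call. = FALSE)
  if (any(concentration <= 0))
    stop("concentrations must be strictly positive", call. = FALSE)
  if (any(diff(concentration) <= 0))
    stop("concentrations must be strictly increasing", call. = FALSE)
  structure(list(concentration = as.numeric(concentration),
                 gamma = as.numeric(gamma),
                 temperature = temperature, label = as.character(label)),
            class = "surface_tension_curve")
}

#' @export
print.surface_tension_curve <- function(x, ...) {
  cat(sprintf(
    "Surface-tension curve \"%s\": %d points, c = %.4g..%.4g mM, gamma = %.1f..%.1f mN/m\n",
    x$label, length(x$gamma), min(x$concentration), max(x$concentration),
    min(x$gamma), max(x$gamma)))
  invisible(x)
}

#' @export
plot.surface_tension_curve <- function(x, ...) {
  graphics::plot(log(x$concentration), x$gamma,
                 xlab = "ln( c / mM )", ylab = expression(gamma ~ (mN/m)),
                 main = x$label, ...)
  invisible(x)
}

# RSS of a straight line through (x, y), plus its coefficients
line_rss <- function(x, y) {
  f <- weighted_line_fit(x, y)
  r <- y - f$intercept - f$slope * x
  list(rss = sum(r^2), intercept = f$intercept, slope = f$slope)
}

# Continuous two-segment fit with the breakpoint FIXED at psi:
# gamma = a + b t + d (t - psi)_+ , linear least squares.
segmented_fit_at <- function(t, g, psi) {
  X <- cbind(1, t, pmax(t - psi, 0))
  cf <- qr.coef(qr(X), g)
  cf[is.na(cf)] <- 0
  r <- g - X %*% cf
  list(rss = sum(r^2), psi = psi,
       pre_slope = cf[2L], post_slope = cf[2L] + cf[3L])
}

#' Locate the cmc as the breakpoint of a surface-tension curve
#'
#' Fits a continuous two-segment linear model in \eqn{(\ln c, \gamma)} by
#' exhaustive closed-form search: for every interior interval between
#' consecutive points, two unconstrained lines are fitted to the left and
#' right subsets; when their intersection falls inside the interval it is
#' the optimal continuous breakpoint for that split, otherwise the
#' breakpoint is pinned at the interval ends and the constrained continuous
#' model refitted. The global minimum-RSS breakpoint is returned (ties
#' broken toward the lower concentration) and \eqn{cmc = e^{\psi}}. An
#' F-test against the single-line model guards against spurious breaks.
#'
#' @param curve A [surface_tension_curve()].
#' @param alpha Significance level of the two-segment vs one-line F-test;
#'   if the improvement is not significant an explicit
#'   \dQuote{no breakpoint} error is raised.
#' @param min_points Minimum number of points required on each side.
#' @return A list of class \code{"tension_fit"} with \code{cmc} (mM),
#'   \code{pre_slope}, \code{post_slope} (mN/m per ln-unit), \code{rss},
#'   \code{rss_single}, \code{p_value} and logical \code{slope_ordered}
#'   (TRUE when the post-cmc slope magnitude is smaller, as expected; a
#'   warning is emitted otherwise).
#' @examples
#' cv <- gen_surface_tension_curve(cmc = 0.4, pre_slope = -8, plateau = 53.4)
#' detect_cmc_breakpoint(cv)$cmc
#' @export
detect_cmc_breakpoint <- function(curve, alpha = 0.05, min_points = 3L) {
  stopifnot(inherits(curve, "surface_tension_curve"))
  t <- log(curve$concentration)
  g <- curve$gamma
  m <- length(t)
  if (m < 2L * min_points)
    stop(sprintf("need >= %d points on each side of a candidate breakpoint",
                 min_points), call. = FALSE)

  single <- line_rss(t, g)
  scale2 <- max(stats::var(g), .Machine$double.eps)

  best <- NULL
  for (k in min_points:(m - min_points)) {
    left <- line_rss(t[1:k], g[1:k])
    right <- line_rss(t[(k + 1L):m], g[(k + 1L):m])
    cand <- NULL
    if (abs(left$slope - right$slope) > 1e-12) {
      psi <- (right$intercept - left$intercept) / (left$slope - right$slope)
      if (psi >= t[k] && psi <= t[k + 1L])
        cand <- list(rss = left$rss + right$rss, psi = psi,
                     pre_slope = left$slope, post_slope = right$slope)
    }
    if (is.null(cand)) {
      c1 <- segmented_fit_at(t, g, t[k])
      c2 <- segmented_fit_at(t, g, t[k + 1L])
      cand <- if (c1$rss <= c2$rss) c1 else c2
    }
    if (is.null(best) || cand$rss < best$rss - 1e-12 * scale2)
      best <- cand
  }

  # two-segment model has 4 parameters, the single line 2
  if (single$rss <= 1e-10 * scale2 * m)
    stop("no breakpoint: the curve is a single straight line", call. = FALSE)
  Fstat <- ((single$rss - best$rss) / 2) / (best$rss / (m - 4))
  p_value <- if (best$rss <= 1e-10 * scale2 * m) 0
  else stats::pf(Fstat, 2, m - 4, lower.tail = FALSE)
  if (!is.finite(p_value) || p_value > alpha)
    stop(sprintf(
      "no breakpoint: two-segment fit not better than a single line (p = %.3g)",
      p_value), call. = FALSE)

  slope_ordered <- abs(best$post_slope) < abs(best$pre_slope)
  if (!slope_ordered)
    warning("post-cmc slope is steeper than the pre-cmc slope; breakpoint may not be a cmc",
            call. = FALSE)
  structure(list(cmc = exp(best$psi),
                 pre_slope = unname(best$pre_slope),
                 post_slope = unname(best$post_slope),
                 rss = best$rss, rss_single = single$rss,
                 p_value = p_value, slope_ordered = slope_ordered),
            class = "tension_fit")
}

#' @export
print.tension_fit <- function(x, ...) {
  cat(sprintf(
    "Surface-tension breakpoint: cmc = %.4g mM (slopes %.3f -> %.3f mN/m per ln unit, RSS %.3g, p = %.3g)\n",
    x$cmc, x$pre_slope, x$post_slope, x$rss, x$p_value))
  invisible(x)
}
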
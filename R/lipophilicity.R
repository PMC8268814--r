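#' Mean squared residual of a log P predictor
#'
#' Benchmark statistic for a computational log P method against experimental
#' values: \eqn{\sum (\log P_{theor} - \log P_{exp})^2 / n}, the mean of the
#' squared residuals (plain \eqn{n} in the denominator). Records without an
#' experimental value are ignored.
#'
#' @param predicted Predicted log P values.
#' @param experimental Experimental log P values (NA allowed), same length.
#' @return The mean squared residual (dimensionless, log10 units squared).
#' @export
mean_squared_residual <- function(predicted, experimental) {
  stopifnot(length(predicted) == length(experimental))
  keep <- is.finite(experimental) & is.finite(predicted)
  if (!any(keep))
    stop("mean_squared_residual: no records with an experimental value",
         call. = FALSE)
  mean((predicted[keep] - experimental[keep])^2)
}

#' Reliability class of a log P predictor
#'
#' Standard benchmarking bands for the mean squared residual: up to 0.5
#' (inclusive) the predictor is \code{"reliable"}, above 0.5 and up to 1
#' (inclusive) \code{"acceptable"}, above 1 \code{"not_acceptable"}.
#'
#' @param residual Mean squared residual(s), \eqn{\ge 0} (vectorized).
#' @return Character vector of classes.
#' @export
classify_reliability <- function(residual) {
  stopifnot(is.numeric(residual), all(residual >= 0))
  ifelse(residual <= 0.5, "reliable",
         ifelse(residual <= 1, "acceptable", "not_acceptable"))
}

#' Construct a log P / cmc calibration line
#'
#' @param slope Slope of log P on \eqn{\log_{10}(cmc/\mathrm{mM})}.
#' @param intercept Intercept (log10 units).
#' @param r_squared Coefficient of determination of the fit.
#' @param n_points Number of points behind the fit.
#' @return An object of class \code{"logp_cmc_fit"}.
#' @export
logp_cmc_fit <- function(slope, intercept, r_squared = NA_real_,
                         n_points = NA_integer_) {
  stopifnot(is.numeric(slope), is.numeric(intercept))
  if (is.finite(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, n_points = n_points),
            class = "logp_cmc_fit")
}

#' @export
print.logp_cmc_fit <- function(x, ...) {
  cat(sprintf("log P = %.3f %+.3f log10(cmc/mM)", x$intercept, x$slope))
  if (is.finite(x$r_squared)) cat(sprintf("  (r^2 = %.3f", x$r_squared))
  if (is.finite(x$n_points)) cat(sprintf(", n = %d", x$n_points))
  if (is.finite(x$r_squared)) cat(")")
  cat("\n")
  invisible(x)
}

#' Reference lipophilicity / cmc calibration for bile-salt derivatives
#'
#' The published calibration for C3-substituted cholate derivatives and
#' natural bile salts,
#' \deqn{\mathrm{Virtual\ log} P = -(1.00\pm0.09)\log_{10}(cmc/\mathrm{mM})
#' + (2.79\pm0.09), \quad r^2 = 0.948,}
#' shipped as a constant: the underlying point set spans literature cmc
#' values that are not redistributable here, so the line is for use, not
#' regeneration.
#'
#' @return A [logp_cmc_fit()] with slope \eqn{-1.00}, intercept 2.79 and
#'   \eqn{r^2 = 0.948}.
#' @export
reference_logp_cmc_fit <- function() {
  logp_cmc_fit(slope = -1.00, intercept = 2.79, r_squared = 0.948)
}

#' Fit the log P / cmc calibration by least squares
#'
#' Ordinary least squares of log P on \eqn{\log_{10}(cmc/\mathrm{mM})}.
#'
#' @param logp Predicted (e.g. Virtual) log P values.
#' @param cmc cmc values in mM (> 0); at least 3 points with distinct cmc.
#' @return A [logp_cmc_fit()].
#' @export
fit_logp_cmc <- function(logp, cmc) {
  stopifnot(length(logp) == length(cmc), all(cmc > 0))
  if (length(logp) < 3L)
    stop("fit_logp_cmc: need >= 3 points", call. = FALSE)
  x <- log10(cmc)
  if (length(unique(x)) < 2L)
    stop("fit_logp_cmc: degenerate abscissa (all cmc equal)", call. = FALSE)
  line <- weighted_line_fit(x, logp)
  logp_cmc_fit(line$slope, line$intercept, line$r_squared, length(logp))
}

#' Predict log P from a cmc (and vice versa)
#'
#' The double-logarithmic calibration lets either quantity stand in for the
#' other: \code{predict_logp_from_cmc()} evaluates
#' \eqn{intercept + slope\,\log_{10}(cmc)}; \code{predict_cmc_from_logp()}
#' is its exact inverse.
#'
#' @param cmc cmc in mM (> 0, vectorized).
#' @param logp log P (log10 units, vectorized).
#' @param fit A [logp_cmc_fit()]; defaults to the published reference line
#'   [reference_logp_cmc_fit()].
#' @return Predicted log P (log10 units) or cmc (mM).
#' @examples
#' predict_logp_from_cmc(0.336)  # 3.26 for the adamantyl cholate derivative
#' @export
predict_logp_from_cmc <- function(cmc, fit = reference_logp_cmc_fit()) {
  stopifnot(inherits(fit, "logp_cmc_fit"), all(cmc > 0))
  fit$intercept + fit$slope * log10(cmc)
}

#' @rdname predict_logp_from_cmc
#' @export
predict_cmc_from_logp <- function(logp, fit = reference_logp_cmc_fit()) {
  stopifnot(inherits(fit, "logp_cmc_fit"), fit$slope != 0)
  10^((logp - fit$intercept) / fit$slope)
}

#' Score a panel of log P predictors against experimental values
#'
#' Applies [mean_squared_residual()] and [classify_reliability()] to every
#' predictor column of a benchmark table.
#'
#' @param table A data frame with one row per compound, an
#'   \code{experimental} column, and one column per predictor (any column
#'   other than \code{compound} and \code{experimental}).
#' @return A data frame with columns \code{predictor},
#'   \code{mean_squared_residual} and \code{reliability}, one row per
#'   predictor, in the column order of the input.
#' @examples
#' score_logp_predictors(read_logp_table())
#' @export
score_logp_predictors <- function(table) {
  stopifnot(is.data.frame(table), "experimental" %in% names(table))
  predictors <- setdiff(names(table), c("compound", "experimental"))
  if (!length(predictors))
    stop("score_logp_predictors: no predictor columns found", call. = FALSE)
  msr <- vapply(predictors, function(p)
    mean_squared_residual(table[[p]], table$experimental), numeric(1))
  data.frame(predictor = predictors,
             mean_squared_residual = unname(msr),
             reliability = classify_reliability(unname(msr)),
             row.names = NULL)
}
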
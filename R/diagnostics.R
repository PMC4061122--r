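# Residual diagnostics, goodness of fit, exposure-response summaries.

#' Sample autocorrelation function of a residual series
#'
#' Standard sample ACF with the biased (1/n) denominator, reported at lags
#' `0..max_lag` (the lag-0 value is identically 1).
#'
#' @param x numeric series with `length(x) > max_lag + 1`.
#' @param max_lag deepest lag.
#' @return named numeric vector of length `max_lag + 1`.
#' @export
residual_acf <- function(x, max_lag = 30L) {
  if (length(x) <= max_lag + 1L) stop("series too short for max_lag")
  a <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                             demean = TRUE)$acf)
  stats::setNames(a, 0:max_lag)
}

#' Sample partial autocorrelation function
#'
#' Computed by the Durbin-Levinson recursion (as in [stats::pacf()]),
#' reported at lags `1..max_lag`.
#'
#' @inheritParams residual_acf
#' @return named numeric vector of length `max_lag`.
#' @export
residual_pacf <- function(x, max_lag = 30L) {
  if (length(x) <= max_lag + 1L) stop("series too short for max_lag")
  p <- as.numeric(stats::pacf(x, lag.max = max_lag, plot = FALSE)$acf)
  stats::setNames(p, 1:max_lag)
}

#' Goodness of fit
#'
#' Primary definition: squared Pearson correlation between observed counts
#' and fitted means (count scale).  A deviance-based pseudo-R-squared
#' (`1 - residual deviance / null deviance`) is available as a secondary
#' measure.
#'
#' @param fit a `gam_fit` or `mgam_fit`.
#' @param type `"pearson"` (default) or `"deviance"`.
#' @return scalar.
#' @export
r_squared <- function(fit, type = c("pearson", "deviance")) {
  type <- match.arg(type)
  y <- fit$y; mu <- fit$fitted_mu
  if (type == "pearson") {
    if (stats::sd(mu) == 0 || stats::sd(y) == 0) return(0)
    return(stats::cor(y, mu)^2)
  }
  dev <- function(y, mu) {
    t1 <- ifelse(y > 0, y * log(y / mu), 0)
    2 * sum(t1 - (y - mu))
  }
  1 - dev(y, mu) / dev(y, mean(y))
}

#' Risk ratio implied by a log-linear slope
#'
#' `RR = exp(slope * delta)`: the multiplicative change in expected counts
#' for a `delta` degC change along a locally linear stretch of the
#' exposure-response curve.  Rounding to the conventional 3 decimals is
#' left to the report layer.
#'
#' @param slope log-counts per degC.
#' @param delta temperature change in degC.
#' @return risk ratio (scalar or vector).
#' @export
rr_from_slope <- function(slope, delta) exp(slope * delta)

#' Evaluate the fitted temperature effect on a grid
#'
#' @param fit a `gam_fit` or `mgam_fit`.
#' @param grid temperatures (degC); defaults to a 0.1 degC grid over the
#'   observed lag-weighted temperature span.
#' @return data frame with columns `temp` and `effect` (log scale, centered
#'   at the fitted curve's own level).
#' @export
temperature_effect <- function(fit, grid = NULL) {
  if (is.null(grid))
    grid <- seq(min(fit$tstar), max(fit$tstar), by = 0.1)
  B <- natural_spline_basis(grid, fit$temp_spec)
  eff <- as.numeric(B %*% fit$coefficients[fit$temp_cols])
  data.frame(temp = grid, effect = eff)
}

#' Piecewise slopes and risk ratios of the fitted temperature curve
#'
#' Evaluates the fitted temperature spline on a 0.1 degC grid within each
#' requested range (intersected with the observed exposure span) and
#' reports the least-squares slope (log-counts per degC) together with the
#' implied risk ratios for 1 and 5 degC changes.
#'
#' @param fit a `gam_fit` or `mgam_fit`.
#' @param ranges list of `c(from, to)` degC intervals.  Defaults to the
#'   conventional reporting ranges 0-11, 11-27, 27-30 (the plateau, also
#'   reported as a slope) and 30-35 degC.
#' @return data frame with columns `from`, `to`, `slope`, `rr_1c`, `rr_5c`.
#' @export
piecewise_slopes <- function(fit,
                             ranges = list(c(0, 11), c(11, 27), c(27, 30),
                                           c(30, 35))) {
  span <- range(fit$tstar)
  rows <- lapply(ranges, function(r) {
    lo <- max(r[1], span[1]); hi <- min(r[2], span[2])
    if (hi - lo < 0.5) {
      warning(sprintf("range [%g, %g] outside observed exposure span; skipped",
                      r[1], r[2]))
      return(NULL)
    }
    grid <- seq(lo, hi, by = 0.1)
    eff <- temperature_effect(fit, grid)$effect
    slope <- stats::cov(grid, eff) / stats::var(grid)
    data.frame(from = r[1], to = r[2], slope = slope,
               rr_1c = rr_from_slope(slope, 1), rr_5c = rr_from_slope(slope, 5))
  })
  do.call(rbind, rows)
}

#' Day-of-week multiplicative profile
#'
#' Exponentiated day-of-week effects (Monday reference included as 1 before
#' normalization), renormalized to weekly geometric mean 1 so the profile
#' does not depend on the reference category.  Entries multiply to 1.
#'
#' @param fit a converged `gam_fit` or `mgam_fit`.
#' @return named numeric vector Mon..Sun.
#' @export
dow_profile <- function(fit) {
  co <- c(0, fit$coefficients[fit$dow_cols])
  e <- exp(co)
  e <- e / geometric_mean(e)
  stats::setNames(e, dow_names)
}

#' Assemble a diagnostics report
#'
#' Residual ACF/PACF, goodness of fit, piecewise slope / risk-ratio table,
#' day-of-week profile and the fitted temperature curve: the machinery
#' behind the standard figure set of a temperature-morbidity analysis.
#'
#' @param fit a `gam_fit` or `mgam_fit`.
#' @param max_lag deepest residual lag.
#' @param ranges slope reporting ranges, see [piecewise_slopes()].
#' @return list of class `diagnostics_report`.
#' @export
diagnostics_report <- function(fit, max_lag = 30L,
                               ranges = list(c(0, 11), c(11, 27), c(27, 30),
                                             c(30, 35))) {
  r <- pearson_residuals(fit)
  structure(list(acf = residual_acf(r, max_lag)[-1],
                 pacf = residual_pacf(r, max_lag),
                 r_squared = r_squared(fit),
                 r_squared_deviance = r_squared(fit, "deviance"),
                 slope_table = piecewise_slopes(fit, ranges),
                 dow_profile = dow_profile(fit),
                 temp_curve = temperature_effect(fit),
                 max_lag = max_lag),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("<diagnostics_report>\n")
  cat(sprintf("  R^2 (count scale) %.3f   pseudo-R^2 (deviance) %.3f\n",
              x$r_squared, x$r_squared_deviance))
  cat(sprintf("  max |ACF| %.3f, max |PACF| %.3f over lags 1..%d\n",
              max(abs(x$acf)), max(abs(x$pacf)), x$max_lag))
  st <- x$slope_table
  st$slope <- round(st$slope, 4)
  st$rr_1c <- round(st$rr_1c, 3); st$rr_5c <- round(st$rr_5c, 3)
  print(st, row.names = FALSE)
  cat("  DOW profile:",
      paste(sprintf("%s %.3f", names(x$dow_profile), x$dow_profile),
            collapse = "  "), "\n")
  invisible(x)
}
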
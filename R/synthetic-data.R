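# Synthetic daily count / temperature generator.
#
# Emulates a multi-year urban emergency-care count series: Poisson counts
# whose log mean carries a rising time trend, day-of-week effects, a
# V-shaped piecewise-linear effect of a 3-day lag-weighted mean temperature,
# and an AR(p) random effect on the log scale.  Temperature follows an
# annual sinusoid (peak in late July) plus AR(1) noise.

#' Simulation configuration
#'
#' Bundles every "true" parameter of the data-generating process so that
#' simulation studies can compare estimates against known truth.
#'
#' Defaults describe a 5.5-year series of a few hundred events per day in a
#' subtropical Northern-Hemisphere city: annual mean temperature 17 degC with
#' amplitude 12 degC (daily mean roughly -3 to 37 degC once AR(1) noise with
#' marginal sd 2.5 degC is added), a rising trend of 0.12 log-counts per
#' year, a Sunday-max / Wednesday-min day-of-week profile, and a V-shaped
#' temperature effect that falls at -0.0024 log-counts/degC below 11 degC and
#' -0.0116 between 11 and 27 degC, is flat on the 27-30 degC plateau, and
#' rises at 0.0113 above 30 degC.
#'
#' @param n_days number of days to simulate (>= 4; lag-3 exposure needs three
#'   burn-in days).
#' @param start_date first calendar date.
#' @param seed integer RNG seed; identical configurations give bit-identical
#'   series.
#' @param temp_mean_annual,temp_amplitude annual mean and sinusoid amplitude
#'   of temperature (degC).
#' @param temp_noise_sd marginal standard deviation of the AR(1) temperature
#'   noise (degC).
#' @param temp_ar AR(1) coefficient of the temperature noise, in \[0, 1).
#' @param intercept log-count scale intercept.
#' @param trend_slope linear time trend, log-counts per year.
#' @param dow_effects length-7 named vector of log-scale day-of-week offsets
#'   (Mon..Sun).
#' @param lag_weights non-negative 3-vector summing to 1: weights of
#'   temperature at lags 1..3 days.
#' @param breakpoints temperatures (b1, b2) where the piecewise-linear effect
#'   changes slope (degC).
#' @param plateau_end upper end of the flat minimum-risk band (degC);
#'   requires b1 < b2 < plateau_end.
#' @param slopes `(s_low, s_mid, s_high)` log-counts per degC below b1,
#'   between b1 and b2, and above `plateau_end`.
#' @param ar_coeffs AR coefficients of the log-scale random effect (possibly
#'   empty); must be stationary.
#' @param innovation_sd standard deviation of the AR innovations (log scale).
#' @return an object of class `sim_config`.
#' @seealso [simulate_series()], [simulate_temperature()],
#'   [true_temperature_effect()]
#' @export
sim_config <- function(n_days = 2000L,
                       start_date = as.Date("2007-01-01"),
                       seed = 1L,
                       temp_mean_annual = 17,
                       temp_amplitude = 12,
                       temp_noise_sd = 2.5,
                       temp_ar = 0.6,
                       intercept = 5.5,
                       trend_slope = 0.12,
                       dow_effects = c(Mon = 0, Tue = -0.02, Wed = -0.06,
                                       Thu = -0.03, Fri = -0.01, Sat = 0.02,
                                       Sun = 0.06),
                       lag_weights = c(0.5, 0.3, 0.2),
                       breakpoints = c(11, 27),
                       plateau_end = 30,
                       slopes = c(-0.0024, -0.0116, 0.0113),
                       ar_coeffs = 0.5,
                       innovation_sd = 0.05) {
  cfg <- list(n_days = as.integer(n_days), start_date = as.Date(start_date),
              seed = as.integer(seed), temp_mean_annual = temp_mean_annual,
              temp_amplitude = temp_amplitude, temp_noise_sd = temp_noise_sd,
              temp_ar = temp_ar, intercept = intercept,
              trend_slope = trend_slope, dow_effects = dow_effects,
              lag_weights = lag_weights, breakpoints = breakpoints,
              plateau_end = plateau_end, slopes = slopes,
              ar_coeffs = as.numeric(ar_coeffs),
              innovation_sd = innovation_sd)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_days < 4L) stop("n_days must be at least 4 (lag-3 exposure needs 3 burn-in days)")
  if (length(cfg$dow_effects) != 7L) stop("dow_effects must have length 7 (Mon..Sun)")
  w <- cfg$lag_weights
  if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-10)
    stop("lag_weights must be a non-negative 3-vector summing to 1")
  if (cfg$temp_ar < 0 || cfg$temp_ar >= 1) stop("temp_ar must lie in [0, 1)")
  if (cfg$temp_noise_sd < 0 || cfg$innovation_sd < 0)
    stop("noise standard deviations must be non-negative")
  b <- cfg$breakpoints
  if (!(b[1] < b[2] && b[2] < cfg$plateau_end))
    stop("breakpoints must satisfy b1 < b2 < plateau_end")
  if (!ar_stationary(cfg$ar_coeffs))
    stop("ar_coeffs do not define a stationary AR process")
  invisible(cfg)
}

#' Simulate a daily temperature series
#'
#' Annual sinusoid (peak on day-of-year 207, late July) plus AR(1) Gaussian
#' noise started from its stationary distribution.
#'
#' @param config a [sim_config()].
#' @param .set_seed set the configured seed before drawing (`FALSE` when
#'   called inside [simulate_series()], which manages the seed itself).
#' @return numeric vector of daily mean temperatures (degC), length `n_days`.
#' @export
simulate_temperature <- function(config, .set_seed = TRUE) {
  validate_sim_config(config)
  if (.set_seed) set.seed(config$seed)
  n <- config$n_days
  dates <- config$start_date + seq_len(n) - 1L
  doy <- as.integer(format(dates, "%j"))
  det <- config$temp_mean_annual +
    config$temp_amplitude * cos(2 * pi * (doy - 207) / 365.25)
  e <- numeric(n)
  if (config$temp_noise_sd > 0) {
    # temp_noise_sd is the marginal sd of the AR(1) noise; innovations are
    # scaled so the process is stationary with exactly that sd
    phi <- config$temp_ar
    innov_sd <- config$temp_noise_sd * sqrt(1 - phi^2)
    e[1] <- stats::rnorm(1, 0, config$temp_noise_sd)
    eps <- stats::rnorm(n - 1L, 0, innov_sd)
    for (t in 2:n) e[t] <- phi * e[t - 1L] + eps[t - 1L]
  }
  det + e
}

#' True piecewise-linear temperature effect
#'
#' Continuous piecewise-linear log-scale effect used by the generator: slope
#' `s_low` below `b1`, `s_mid` on `[b1, b2]`, zero on the plateau
#' `[b2, plateau_end]`, and `s_high` above.  Anchored to 0 at `b2`; the
#' anchor is arbitrary because the model intercept absorbs the level.
#'
#' @param temp temperatures (degC), any length.
#' @param config a [sim_config()].
#' @return log-scale effects, same length as `temp`.
#' @export
true_temperature_effect <- function(temp, config) {
  b1 <- config$breakpoints[1]; b2 <- config$breakpoints[2]
  pe <- config$plateau_end
  s <- config$slopes
  out <- numeric(length(temp))
  hi <- temp >= pe
  mid <- temp >= b1 & temp < b2
  low <- temp < b1
  out[hi] <- s[3] * (temp[hi] - pe)
  out[mid] <- s[2] * (temp[mid] - b2)
  out[low] <- s[2] * (b1 - b2) + s[1] * (temp[low] - b1)
  out
}

#' Simulate a daily count + temperature series
#'
#' For days `t >= 4` the log mean is
#' `intercept + f(T*_t) + trend_slope * t/365.25 + dow(date_t) + delta_t`
#' with `T*_t` the lag-weighted mean of the previous three days'
#' temperatures and `delta_t` a stationary AR(p) Gaussian process.  The
#' first three (burn-in) days use the same-day temperature in place of
#' `T*`; all fitting functions drop them.  Counts are Poisson draws.
#'
#' @param config a [sim_config()].
#' @return a [daily_series()] with `truth` attached (`true_mu`,
#'   `true_delta`, `true_eta`).
#' @export
simulate_series <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_days
  dates <- config$start_date + seq_len(n) - 1L
  temp <- simulate_temperature(config, .set_seed = FALSE)

  texp <- temp
  if (n >= 4L) {
    w <- config$lag_weights
    texp[4:n] <- w[1] * temp[3:(n - 1L)] + w[2] * temp[2:(n - 2L)] +
      w[3] * temp[1:(n - 3L)]
  }

  delta <- simulate_ar_path(config$ar_coeffs, config$innovation_sd, n)
  trend <- config$trend_slope * (seq_len(n) - 1L) / 365.25
  dow <- unname(config$dow_effects[day_of_week(dates)])
  eta <- config$intercept + true_temperature_effect(texp, config) + trend + dow
  mu <- exp(eta + delta)
  counts <- stats::rpois(n, mu)

  daily_series(dates, counts, temp,
               truth = list(mu = mu, delta = delta, eta = eta))
}

# Stationary AR(p) path: exact stationary start for p <= 1, 200-step warm-up
# discard otherwise.
simulate_ar_path <- function(ar_coeffs, innovation_sd, n) {
  p <- length(ar_coeffs)
  if (innovation_sd == 0) return(numeric(n))
  if (p == 0L) return(stats::rnorm(n, 0, innovation_sd))
  if (p == 1L) {
    rho <- ar_coeffs
    d <- numeric(n)
    d[1] <- stats::rnorm(1, 0, innovation_sd / sqrt(1 - rho^2))
    eps <- stats::rnorm(n - 1L, 0, innovation_sd)
    for (t in 2:n) d[t] <- rho * d[t - 1L] + eps[t - 1L]
    return(d)
  }
  warm <- 200L
  m <- n + warm
  d <- numeric(m)
  eps <- stats::rnorm(m, 0, innovation_sd)
  for (t in seq_len(m)) {
    lags <- 0
    for (i in seq_len(min(p, t - 1L))) lags <- lags + ar_coeffs[i] * d[t - i]
    d[t] <- lags + eps[t]
  }
  d[(warm + 1L):m]
}

#' Daily count and temperature series
#'
#' The fundamental data container: strictly consecutive dates, non-negative
#' integer counts and daily mean temperatures, optionally daily min/max
#' temperatures and (for simulated data) the latent truth.
#'
#' @param dates consecutive `Date`s, length >= 4.
#' @param counts non-negative integers.
#' @param temp_mean daily mean temperature (degC).
#' @param temp_min,temp_max optional daily extremes; must bracket
#'   `temp_mean` elementwise.
#' @param truth optional list with elements `mu`, `delta`, `eta` from the
#'   generator.
#' @return an object of class `daily_series`.
#' @export
daily_series <- function(dates, counts, temp_mean, temp_min = NULL,
                         temp_max = NULL, truth = NULL) {
  dates <- as.Date(dates)
  n <- length(dates)
  if (n < 4L) stop("a daily series needs at least 4 days")
  if (length(counts) != n || length(temp_mean) != n)
    stop("dates, counts and temp_mean must have equal length")
  if (any(diff(as.integer(dates)) != 1L)) {
    gaps <- dates[which(diff(as.integer(dates)) != 1L)] + 1L
    stop("dates must be strictly consecutive; missing after: ",
         paste(format(gaps), collapse = ", "))
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be non-negative integers")
  if (any(!is.finite(temp_mean))) stop("temp_mean must be finite")
  if (!is.null(temp_min) && !is.null(temp_max)) {
    if (any(temp_min > temp_mean | temp_mean > temp_max))
      stop("temp_min <= temp_mean <= temp_max must hold elementwise")
  }
  structure(list(dates = dates, counts = as.integer(round(counts)),
                 temp_mean = as.numeric(temp_mean),
                 temp_min = temp_min, temp_max = temp_max, truth = truth),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> %d days (%s .. %s)\n", length(x$dates),
              format(x$dates[1]), format(x$dates[length(x$dates)])))
  cat(sprintf("  counts: mean %.1f, range [%d, %d]\n", mean(x$counts),
              min(x$counts), max(x$counts)))
  cat(sprintf("  temp_mean: range [%.1f, %.1f] degC\n", min(x$temp_mean),
              max(x$temp_mean)))
  if (!is.null(x$truth)) cat("  latent truth attached\n")
  invisible(x)
}
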
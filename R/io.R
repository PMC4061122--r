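# File I/O: CSV series, YAML/JSON configuration, JSON fit serialization.

#' Read a daily series from CSV
#'
#' Expects columns `date` (ISO-8601), `count`, `temp_mean` and optionally
#' `temp_min`, `temp_max`; truth columns prefixed `true_` are restored when
#' present.  Calendar gaps and non-integer or negative counts are hard
#' errors.
#'
#' @param path CSV file path.
#' @return a [daily_series()].
#' @export
read_daily_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "count", "temp_mean")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  dates <- as.Date(df$date)
  if (any(is.na(dates))) stop("unparseable dates in ", path)
  truth <- NULL
  if (all(c("true_mu", "true_delta") %in% names(df)))
    truth <- list(mu = df$true_mu, delta = df$true_delta,
                  eta = df$true_eta)
  daily_series(dates, df$count, df$temp_mean,
               temp_min = df$temp_min, temp_max = df$temp_max, truth = truth)
}

#' Write a daily series to CSV
#'
#' @param series a [daily_series()].
#' @param path output path.
#' @export
write_daily_series <- function(series, path) {
  df <- data.frame(date = format(series$dates), count = series$counts,
                   temp_mean = series$temp_mean)
  if (!is.null(series$temp_min)) df$temp_min <- series$temp_min
  if (!is.null(series$temp_max)) df$temp_max <- series$temp_max
  if (!is.null(series$truth)) {
    df$true_mu <- series$truth$mu
    df$true_delta <- series$truth$delta
    df$true_eta <- series$truth$eta
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' A flat mapping mirroring the [sim_config()] fields.
#'
#' @param path file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

# Serializable summary of a fit.
fit_to_list <- function(fit) {
  out <- list(model = class(fit)[1],
              df_temp = fit$df_temp, df_time = fit$df_time,
              coefficients = as.list(fit$coefficients),
              weights = as.numeric(fit$weights),
              loglik = fit$loglik, aic = fit$aic,
              converged = fit$converged, n_iter = fit$n_iter)
  if (inherits(fit, "mgam_fit")) {
    out$ar_order <- fit$ar_order
    out$ar_coeffs <- as.numeric(fit$ar_coeffs)
    out$innovation_sd <- fit$innovation_sd
    out$partial_loglik <- fit$partial_loglik
  }
  out
}

write_fit_json <- function(fit, path) {
  jsonlite::write_json(fit_to_list(fit), path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}

write_fitted_csv <- function(fit, path) {
  df <- data.frame(date = format(fit$dates), count = fit$y,
                   fitted_mu = fit$fitted_mu,
                   pearson_residual = pearson_residuals(fit))
  if (!is.null(fit$delta)) df$delta <- fit$delta
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
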
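# Model selection: time-trend df by seasonality invariance, temperature df
# by AIC, AR order by the residual ACF/PACF admissibility band plus AIC.

#' Admissibility of residual autocorrelations
#'
#' A fitted model's Pearson residuals are admissible when both the ACF and
#' the PACF fall inside the band `[-band, band]` at every lag `1..max_lag`.
#'
#' @param acf,pacf autocorrelation values at lags `1..max_lag`.
#' @param band half-width of the admissibility band (default 0.1).
#' @return `TRUE`/`FALSE`.
#' @export
acf_admissible <- function(acf, pacf, band = 0.1) {
  max(abs(acf)) <= band && max(abs(pacf)) <= band
}

#' Select the time-trend degrees of freedom by seasonality invariance
#'
#' For each candidate df the GAM is fitted, the fitted time trend removed,
#' and the residual seasonal profile (log fitted count minus trend, averaged
#' by day of year) computed per calendar year.  Year-to-year stability is
#' scored as the mean pairwise Pearson correlation of the annual profiles;
#' the smallest df whose score comes within `tol` of the best score is
#' returned, following the principle that the trend should be as smooth as
#' possible so it does not absorb the temperature seasonality.
#'
#' @param series a [daily_series()] spanning at least two full years.
#' @param candidates integer vector of candidate df (deduplicated, sorted).
#' @param df_temp temperature df held fixed during the scan.
#' @param tol stability-score tolerance for the smallest-df rule.
#' @param control a [fit_control()].
#' @return list with `df_time`, `candidate_table` and `rationale`.
#' @export
select_df_time <- function(series, candidates = 1:6, df_temp = 4L,
                           tol = 0.02, control = fit_control()) {
  if (length(series$counts) < 730L)
    stop("seasonality-invariance selection needs at least 2 full years; fix df_time manually")
  candidates <- sort(unique(as.integer(candidates)))
  scores <- vapply(candidates, function(df) {
    g <- fit_gam(series, df_temp, df, fix_weights = rep(1, 3) / 3,
                 control = control)
    seasonal_stability(g)
  }, numeric(1))
  best <- max(scores)
  chosen <- candidates[which(scores >= best - tol)[1]]
  tab <- data.frame(df_time = candidates, stability = scores)
  list(df_time = chosen, candidate_table = tab,
       rationale = sprintf(
         "smallest df with mean pairwise year-to-year seasonal-profile correlation within %.3f of the best (%.4f)",
         tol, best))
}

# Mean pairwise correlation across years of the day-of-year profile of
# log(fitted) minus the fitted time trend.
seasonal_stability <- function(fit) {
  Bt <- natural_spline_basis(seq_along(fit$series$counts)[-(1:3)],
                             fit$time_spec)
  trend <- as.numeric(Bt %*% fit$coefficients[fit$time_cols])
  seas <- log(fit$fitted_mu) - trend
  yr <- format(fit$dates, "%Y")
  doy <- as.integer(format(fit$dates, "%j"))
  years <- names(which(table(yr) >= 300))
  if (length(years) < 2L) stop("need at least 2 (nearly) complete years")
  prof <- lapply(years, function(y) {
    idx <- yr == y
    stats::setNames(seas[idx], doy[idx])
  })
  cors <- c()
  for (i in seq_along(prof)) for (j in seq_along(prof)) {
    if (j <= i) next
    common <- intersect(names(prof[[i]]), names(prof[[j]]))
    if (length(common) < 90L) next
    cors <- c(cors, stats::cor(prof[[i]][common], prof[[j]][common]))
  }
  mean(cors)
}

#' Select the temperature-spline degrees of freedom by AIC
#'
#' Fits the GAM (with freely estimated lag weights) for each candidate df
#' and returns the AIC minimizer; ties break toward the smaller df.
#' Candidates that fail to converge are dropped with a warning.
#'
#' @inheritParams select_df_time
#' @param df_time time-trend df held fixed.
#' @param candidates candidate temperature df (>= 1 value).
#' @return list with `df_temp`, `candidate_table` and `rationale`.
#' @export
select_df_temp <- function(series, df_time, candidates = 2:6,
                           control = fit_control()) {
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) < 1L) stop("need at least one candidate df")
  rows <- lapply(candidates, function(df) {
    g <- tryCatch(fit_gam(series, df, df_time, control = control),
                  error = function(e) NULL)
    if (is.null(g) || !g$converged) {
      warning(sprintf("df_temp = %d failed to converge; dropped", df))
      return(NULL)
    }
    data.frame(df_temp = df, aic = g$aic, loglik = g$loglik)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0L)
    stop("no candidate temperature df converged")
  chosen <- tab$df_temp[which.min(tab$aic)]
  list(df_temp = chosen, candidate_table = tab,
       rationale = "AIC minimizer among converged candidates; ties toward smaller df")
}

#' Select the autoregressive order from residual autocorrelations
#'
#' For each candidate order the (M)GAM is fitted and the Pearson-residual
#' ACF and PACF computed over lags `1..max_lag`.  An order is admissible
#' when both fall inside `[-0.1, 0.1]` at every lag; among admissible
#' orders the AIC minimizer is chosen (the mixed-model AIC is based on the
#' marginal partial likelihood, so orders are compared on an equal
#' footing).  If no order is admissible the order minimizing the worst
#' absolute autocorrelation is returned with a warning.
#'
#' @inheritParams select_df_temp
#' @param df_temp,df_time spline degrees of freedom.
#' @param p_candidates candidate AR orders.
#' @param max_lag deepest lag scanned (default 30, covering monthly-scale
#'   dependence).
#' @param band admissibility half-width.
#' @return list with `p`, `candidate_table`, `fits` and `rationale`.
#' @export
select_ar_order <- function(series, df_temp, df_time, p_candidates = 0:2,
                            max_lag = 30L, band = 0.1,
                            control = fit_control()) {
  p_candidates <- sort(unique(as.integer(p_candidates)))
  if (length(p_candidates) == 0L) stop("empty candidate list")
  g <- fit_gam(series, df_temp, df_time, control = control)
  fits <- list()
  rows <- lapply(p_candidates, function(p) {
    f <- fit_mgam(series, df_temp, df_time, p = p, init = g,
                  control = control)
    fits[[as.character(p)]] <<- f
    r <- pearson_residuals(f)
    a <- residual_acf(r, max_lag)[-1]   # drop lag 0
    pa <- residual_pacf(r, max_lag)
    data.frame(p = p, aic = f$aic, max_abs_acf = max(abs(a)),
               max_abs_pacf = max(abs(pa)),
               admissible = acf_admissible(a, pa, band))
  })
  tab <- do.call(rbind, rows)
  if (any(tab$admissible)) {
    adm <- tab[tab$admissible, ]
    chosen <- adm$p[which.min(adm$aic)]
    rationale <- sprintf(
      "AIC minimizer among orders with residual ACF and PACF inside [-%.2f, %.2f] at lags 1..%d",
      band, band, max_lag)
  } else {
    worst <- pmax(tab$max_abs_acf, tab$max_abs_pacf)
    chosen <- tab$p[which.min(worst)]
    rationale <- "no order admissible; returned the order minimizing the worst residual autocorrelation"
    warning(rationale)
  }
  list(p = chosen, candidate_table = tab, fits = fits, rationale = rationale)
}
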
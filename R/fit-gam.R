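# Poisson GAM with estimated distributed-lag weights.
#
# For fixed lag weights the model is an ordinary Poisson GLM in the spline
# and indicator columns, fitted by IRLS (stats::glm.fit).  The two free
# weight parameters (multinomial-logit coordinates on the 3-simplex) are
# then optimized on the profile log-likelihood with a quasi-Newton (BFGS)
# outer loop.

#' Fitting control parameters
#'
#' @param max_iter maximum IRLS iterations for the inner Poisson fit.
#' @param tol relative log-likelihood convergence tolerance.
#' @param outer_maxit maximum outer iterations for weight / AR parameter
#'   optimization.
#' @export
fit_control <- function(max_iter = 200L, tol = 1e-8, outer_maxit = 500L) {
  list(max_iter = as.integer(max_iter), tol = tol,
       outer_maxit = as.integer(outer_maxit))
}

#' Fit the Poisson GAM with distributed-lag temperature exposure
#'
#' Maximizes the Poisson log-likelihood of
#' `log mu_t = beta0 + s_temp(T*_t; df_temp) + s_time(t; df_time) + dow_t`
#' over the regression coefficients and, unless `fix_weights` is given, the
#' two free parameters of the lag weights `w` defining
#' `T*_t = w1 T_{t-1} + w2 T_{t-2} + w3 T_{t-3}`.  The first three days are
#' dropped (lag-3 burn-in).
#'
#' @param series a [daily_series()].
#' @param df_temp,df_time degrees of freedom of the temperature and
#'   time-trend natural splines.
#' @param fix_weights optional fixed [lag_weights()]; skips weight
#'   estimation.
#' @param control a [fit_control()].
#' @return an object of class `gam_fit` with elements `coefficients`,
#'   `weights`, `fitted_mu`, `loglik`, `aic`, `cov`, `converged`, `n_iter`,
#'   plus internal design metadata used by downstream reports.
#' @export
fit_gam <- function(series, df_temp = 6L, df_time = 2L, fix_weights = NULL,
                    control = fit_control()) {
  stopifnot(inherits(series, "daily_series"))
  n <- length(series$counts)
  if (n - 3L <= df_temp + df_time + 8L)
    stop("series too short for the requested degrees of freedom")
  y <- series$counts[-(1:3)]
  dates_fit <- series$dates[-(1:3)]

  # knots fixed once, at the equal-weight exposure
  cache <- make_design_cache(series, df_temp, df_time)
  d0 <- cache$assemble(rep(1, 3) / 3)
  if (qr(d0$X)$rank < ncol(d0$X))
    stop("singular design matrix: check temperature variation and weekday coverage")
  temp_spec <- cache$temp_spec; time_spec <- cache$time_spec
  lfac <- sum(lfactorial(y))

  profile <- function(w) {
    des <- cache$assemble(w)
    fit <- suppressWarnings(
      stats::glm.fit(des$X, y, family = stats::poisson(),
                     control = stats::glm.control(epsilon = control$tol,
                                                  maxit = control$max_iter)))
    mu <- fit$fitted.values
    list(fit = fit, des = des,
         loglik = sum(y * log(mu) - mu) - lfac)
  }

  if (!is.null(fix_weights)) {
    w <- lag_weights(unclass(fix_weights))
    theta <- NULL; theta_hessian <- NULL
    opt_conv <- TRUE; n_iter <- 1L
    n_free_w <- 0L
  } else {
    negpl <- function(theta) -profile(softmax3(theta))$loglik
    # Nelder-Mead: robust in 2 dimensions; quasi-Newton line searches can
    # overshoot onto the flat simplex-vertex plateau of the logit scale
    opt <- stats::optim(c(0, 0), negpl, method = "Nelder-Mead",
                        control = list(reltol = 1e-10,
                                       maxit = 50L * control$outer_maxit))
    theta <- opt$par
    theta_hessian <- stats::optimHess(theta, negpl)
    w <- lag_weights(softmax3(theta))
    opt_conv <- opt$convergence == 0L
    n_iter <- opt$counts[["function"]]
    n_free_w <- 2L
  }

  pf <- profile(w)
  glmf <- pf$fit
  beta <- glmf$coefficients
  mu <- glmf$fitted.values
  W <- mu
  cov <- tryCatch(solve(crossprod(pf$des$X * sqrt(W))),
                  error = function(e) matrix(NA_real_, length(beta), length(beta)))
  dimnames(cov) <- list(names(beta), names(beta))
  k <- length(beta) + n_free_w
  ll <- pf$loglik

  structure(list(coefficients = beta, weights = w, fitted_mu = mu,
                 loglik = ll, aic = -2 * ll + 2 * k, cov = cov,
                 df_temp = as.integer(df_temp), df_time = as.integer(df_time),
                 converged = opt_conv && glmf$converged,
                 n_iter = n_iter, n_params = k,
                 theta = theta, theta_hessian = theta_hessian,
                 free_weights = is.null(fix_weights),
                 temp_spec = temp_spec, time_spec = time_spec,
                 temp_cols = cache$temp_cols, time_cols = cache$time_cols,
                 dow_cols = cache$dow_cols,
                 tstar = pf$des$tstar, y = y, dates = dates_fit,
                 series = series, control = control),
            class = "gam_fit")
}

#' Pearson residuals of a fitted model
#'
#' `r_t = (Y_t - mu_t) / sqrt(mu_t)`.  For the mixed model the estimated
#' random-effect path enters through its one-step-ahead AR prediction
#' (`type = "prediction"`, the default): the same-day smoothed value would
#' absorb part of that day's Poisson noise and induce spurious negative
#' lag-1 autocorrelation, so autocorrelation diagnostics are computed on
#' innovation-type residuals.  `type = "smoothed"` uses the smoothed path
#' itself (the model's fitted means).
#'
#' @param fit a `gam_fit` or `mgam_fit`.
#' @param type residual flavour for mixed fits; ignored for plain GAM fits.
#' @return numeric vector aligned to the fitted days.
#' @export
pearson_residuals <- function(fit, type = c("prediction", "smoothed")) {
  type <- match.arg(type)
  mu <- fit$fitted_mu
  if (type == "prediction" && inherits(fit, "mgam_fit") &&
      length(fit$ar_coeffs) > 0) {
    rho <- fit$ar_coeffs
    p <- length(rho)
    d <- fit$delta
    n <- length(d)
    dpred <- d            # first p (conditioning) days keep the smoothed value
    for (t in (p + 1L):n)
      dpred[t] <- sum(rho * d[t - seq_len(p)])
    mu <- exp(log(mu) - d + dpred)
  }
  (fit$y - mu) / sqrt(mu)
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf("<%s> df_temp=%d df_time=%d  n=%d days\n", class(x)[1],
              x$df_temp, x$df_time, length(x$y)))
  cat(sprintf("  lag weights: (%.3f, %.3f, %.3f)%s\n", x$weights[1],
              x$weights[2], x$weights[3],
              if (x$free_weights) " [estimated]" else " [fixed]"))
  if (!is.null(x$ar_coeffs) && length(x$ar_coeffs) > 0)
    cat(sprintf("  AR(%d) coefficients: %s  innovation sd %.4f\n",
                length(x$ar_coeffs),
                paste(sprintf("%.3f", x$ar_coeffs), collapse = ", "),
                x$innovation_sd))
  cat(sprintf("  logLik %.2f  AIC %.2f  converged: %s\n",
              if (!is.null(x$partial_loglik)) x$partial_loglik else x$loglik,
              x$aic, x$converged))
  invisible(x)
}
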
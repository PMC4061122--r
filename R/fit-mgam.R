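# Mixed GAM: Poisson GAM with an AR(p) random effect on the log scale,
# estimated by maximum partial likelihood.
#
# Model:  Y_t ~ Poisson(mu_t),  log mu_t = eta_t(beta, w) + delta_t,
#         delta_t = sum_i rho_i delta_{t-i} + eps_t,  eps_t ~ N(0, sigma^2).
#
# The partial likelihood conditions on the first p usable days: innovations
# are penalized for t > p only, with a flat prior on delta_1..delta_p.  The
# random-effect path delta is estimated jointly with beta by penalized IRLS
# (the penalty is the AR innovation precision), i.e. a Laplace-style
# plug-in; the outer parameters (two weight logits, p partial
# autocorrelations on atanh scale, log sigma) maximize the Laplace-
# approximate profile partial likelihood
#   l(y | beta^, delta^) - |D delta^|^2/(2 sigma^2)
#     - (n-p) log sigma - 0.5 log det(W + D'D/sigma^2)
# where D is the AR differencing operator.  The partial-autocorrelation
# parameterization keeps every AR iterate inside the stationarity region by
# construction.

# Sparse AR differencing operator: row t-p has 1 at column t and -rho_i at
# column t-i.
ar_diff_matrix <- function(rho, n) {
  p <- length(rho)
  rows <- seq_len(n - p)
  i <- rep(rows, p + 1L)
  j <- c(rows + p, unlist(lapply(seq_len(p), function(l) rows + p - l)))
  x <- c(rep(1, n - p), rep(-rho, each = n - p))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n - p, n))
}

# Penalized IRLS for (beta, delta) given design X, AR precision DtD/sigma^2.
# Solved by block elimination: the delta system is banded sparse, and the
# symbolic Cholesky analysis is reused across calls via `chol_env`.
# `lfac = sum(lfactorial(y))` is passed in so the Poisson log-likelihood is
# cheap inside the loop.  Returns the profile pieces the PQL objective needs.
pirls <- function(X, y, DtD, sigma, beta0, delta0, lfac, tol = 1e-8,
                  max_iter = 100L, chol_env = NULL) {
  beta <- beta0; delta <- delta0
  Q <- DtD / sigma^2
  pen_ll <- function(beta, delta) {
    eta <- pmin(as.numeric(X %*% beta) + delta, 40)
    mu <- exp(eta)
    sum(y * eta - mu) - lfac -
      0.5 * as.numeric(Matrix::crossprod(delta, Q %*% delta))
  }
  obj <- pen_ll(beta, delta)
  for (it in seq_len(max_iter)) {
    eta <- pmin(as.numeric(X %*% beta) + delta, 40)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    A <- Matrix::forceSymmetric(Q + Matrix::Diagonal(x = mu))
    if (!is.null(chol_env) && !is.null(chol_env$template)) {
      ch <- Matrix::update(chol_env$template, A)
    } else {
      ch <- Matrix::Cholesky(A, LDL = FALSE)
      if (!is.null(chol_env)) chol_env$template <- ch
    }
    WX <- X * mu
    M <- as.matrix(Matrix::solve(ch, WX, system = "A"))
    m <- as.numeric(Matrix::solve(ch, mu * z, system = "A"))
    S <- crossprod(X, WX) - crossprod(WX, M)
    rhs <- crossprod(WX, z - m)
    beta_new <- as.numeric(solve(S, rhs))
    names(beta_new) <- colnames(X)
    delta_new <- m - as.numeric(M %*% beta_new)
    obj_new <- pen_ll(beta_new, delta_new)
    # step-halving safeguard
    step <- 1
    while (is.finite(obj) && (!is.finite(obj_new) || obj_new < obj - 1e-9) &&
           step > 1 / 64) {
      step <- step / 2
      beta_new <- beta + step * (beta_new - beta)
      delta_new <- delta + step * (delta_new - delta)
      obj_new <- pen_ll(beta_new, delta_new)
    }
    done <- is.finite(obj) && abs(obj_new - obj) <= tol * (abs(obj) + 1)
    beta <- beta_new; delta <- delta_new; obj <- obj_new
    if (done || it == max_iter) {
      ldetA <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
      mu <- exp(pmin(as.numeric(X %*% beta) + delta, 40))
      return(list(beta = beta, delta = delta, mu = mu, pen_ll = obj,
                  ldetA = ldetA, S = S, iters = it))
    }
  }
}

#' Fit the mixed GAM (Poisson GAM with AR(p) random effect)
#'
#' Maximizes the Laplace-approximate partial likelihood of the model
#' `log mu_t = eta_t(beta, w) + delta_t` with `delta` a stationary AR(p)
#' process, jointly over the regression coefficients, the lag weights, the
#' AR coefficients and the innovation scale.  Initialized from the ordinary
#' GAM fit (`delta = 0`); with `p = 0` the model reduces exactly to the GAM
#' and [fit_gam()] is returned (wrapped as an `mgam_fit`).
#'
#' @inheritParams fit_gam
#' @param p autoregressive order (>= 0).
#' @param init optional `gam_fit` used for initialization (avoids refitting
#'   when scanning several orders).
#' @return an object of class `mgam_fit` (extends `gam_fit`) with
#'   additionally `ar_coeffs`, `innovation_sd`, `delta`, `partial_loglik`
#'   (plug-in Poisson log-likelihood of days `p+1..n`), `objective` (the
#'   maximized Laplace profile partial likelihood) and `objective_trace`.
#' @export
fit_mgam <- function(series, df_temp = 6L, df_time = 2L, p = 1L, init = NULL,
                     control = fit_control()) {
  p <- as.integer(p)
  if (p < 0L) stop("p must be non-negative")
  if (p == 0L) {
    g <- if (!is.null(init)) init else fit_gam(series, df_temp, df_time,
                                               control = control)
    g$ar_order <- 0L
    g$ar_coeffs <- numeric(0)
    g$innovation_sd <- 0
    g$delta <- rep(0, length(g$y))
    g$partial_loglik <- g$loglik
    g$objective <- g$loglik
    g$objective_trace <- g$loglik
    class(g) <- c("mgam_fit", "gam_fit")
    return(g)
  }

  g <- if (!is.null(init)) init else fit_gam(series, df_temp, df_time,
                                             control = control)
  y <- g$y
  m <- length(y)
  if (m <= g$df_temp + g$df_time + 8L + p) stop("series too short for order p")

  # initial AR parameters from Yule-Walker on the GAM Pearson residuals,
  # initial sigma from the log-scale residual variance net of Poisson noise
  r <- pearson_residuals(g)
  ar0 <- tryCatch(stats::ar.yw(r, order.max = p, aic = FALSE)$ar,
                  error = function(e) rep(0, p))
  if (!ar_stationary(ar0)) ar0 <- rep(0, p)
  k0 <- pmin(pmax(ar_to_pacf(ar0), -0.9), 0.9)
  v_pois <- mean(1 / g$fitted_mu)
  s2 <- max(stats::var(log((y + 0.5) / g$fitted_mu)) - v_pois, 1e-4)
  sig0 <- sqrt(s2) * 0.7

  par0 <- c(if (g$free_weights) g$theta else theta_from_weights(pmax(unclass(g$weights), 1e-6)),
            atanh(k0), log(sig0))
  n_theta <- 2L
  cache <- make_design_cache(series, g$df_temp, g$df_time, g$temp_spec,
                             g$time_spec)
  lfac <- sum(lfactorial(y))
  warm <- new.env(parent = emptyenv())
  warm$beta <- g$coefficients
  warm$delta <- rep(0, m)
  chol_env <- new.env(parent = emptyenv())
  trace_env <- new.env(parent = emptyenv())
  trace_env$best <- -Inf
  trace_env$trace <- numeric(0)

  objective <- function(par) {
    w <- softmax3(par[1:n_theta])
    kpa <- tanh(par[n_theta + seq_len(p)])
    rho <- pacf_to_ar(kpa)
    sigma <- exp(pmin(pmax(par[n_theta + p + 1L], -7), 1.5))
    des <- cache$assemble(w)
    D <- ar_diff_matrix(rho, m)
    DtD <- Matrix::crossprod(D)
    fit <- pirls(des$X, y, DtD, sigma, warm$beta, warm$delta, lfac,
                 tol = control$tol, chol_env = chol_env)
    warm$beta <- fit$beta; warm$delta <- fit$delta
    obj <- fit$pen_ll - (m - p) * log(sigma) - 0.5 * fit$ldetA
    if (obj > trace_env$best) trace_env$best <- obj
    trace_env$trace <- c(trace_env$trace, trace_env$best)
    obj
  }

  opt <- stats::optim(par0, function(par) -objective(par),
                      method = "Nelder-Mead",
                      control = list(maxit = 200L * control$outer_maxit,
                                     reltol = control$tol))
  if (opt$convergence != 0L) {
    # restart once from the incumbent: cures Nelder-Mead simplex degeneracy
    opt2 <- stats::optim(opt$par, function(par) -objective(par),
                         method = "Nelder-Mead",
                         control = list(maxit = 200L * control$outer_maxit,
                                        reltol = control$tol))
    opt2$counts <- opt$counts + opt2$counts
    opt2$convergence <-
      if (opt2$convergence == 0L ||
          abs(opt$value - opt2$value) <= 1e-6 * (abs(opt$value) + 1)) 0L
      else opt2$convergence
    opt <- opt2
  }
  par <- opt$par
  trace <- trace_env$trace   # snapshot before the Hessian probes
  hess <- stats::optimHess(par, function(par) -objective(par))

  # final state at the optimum
  w <- lag_weights(softmax3(par[1:n_theta]))
  kpa <- tanh(par[n_theta + seq_len(p)])
  rho <- pacf_to_ar(kpa)
  sigma <- exp(pmin(pmax(par[n_theta + p + 1L], -7), 1.5))
  des <- cache$assemble(w)
  D <- ar_diff_matrix(rho, m)
  DtD <- Matrix::crossprod(D)
  fin <- pirls(des$X, y, DtD, sigma, warm$beta, warm$delta, lfac,
               tol = control$tol, chol_env = chol_env)
  mu <- fin$mu
  usable <- (p + 1L):m
  partial_ll <- sum(stats::dpois(y[usable], mu[usable], log = TRUE))
  k <- length(fin$beta) + 2L + p + 1L
  # AIC uses the Laplace marginal partial likelihood (random effect
  # integrated out), not the plug-in conditional likelihood: the estimated
  # delta path carries effective parameters far beyond the p + 1 counted
  # ones, so a plug-in AIC would always favour larger p
  aic <- -2 * (-opt$value) + 2 * k
  cov <- tryCatch(solve(fin$S), error = function(e)
    matrix(NA_real_, length(fin$beta), length(fin$beta)))
  dimnames(cov) <- list(names(fin$beta), names(fin$beta))

  structure(list(coefficients = fin$beta, weights = w, fitted_mu = mu,
                 loglik = sum(stats::dpois(y, mu, log = TRUE)),
                 partial_loglik = partial_ll,
                 aic = aic,
                 cov = cov, df_temp = g$df_temp, df_time = g$df_time,
                 ar_order = p, ar_coeffs = rho, innovation_sd = sigma,
                 delta = fin$delta,
                 objective = -opt$value,
                 objective_trace = trace,
                 converged = opt$convergence == 0L,
                 n_iter = opt$counts[["function"]], n_params = k,
                 theta = par[1:n_theta], outer_par = par,
                 outer_hessian = hess,
                 free_weights = TRUE,
                 temp_spec = g$temp_spec, time_spec = g$time_spec,
                 temp_cols = g$temp_cols, time_cols = g$time_cols,
                 dow_cols = g$dow_cols,
                 tstar = des$tstar, y = y, dates = g$dates,
                 series = series, control = control),
            class = c("mgam_fit", "gam_fit"))
}

#' Profile partial likelihood of the mixed GAM at fixed outer parameters
#'
#' Evaluates the Laplace-approximate partial likelihood with the regression
#' coefficients and random-effect path profiled out by penalized IRLS, at
#' user-supplied lag weights and AR parameters.  When `innovation_sd` is
#' `NULL` it is itself profiled by a one-dimensional search.  Useful for
#' grid-based checks of the optimizer.
#'
#' @inheritParams fit_mgam
#' @param weights lag weights (valid 3-vector).
#' @param ar_coeffs stationary AR coefficient vector of length `p`.
#' @param innovation_sd innovation scale, or `NULL` to profile it.
#' @return the profile objective value (scalar).
#' @export
mgam_profile_loglik <- function(series, df_temp, df_time, weights, ar_coeffs,
                                innovation_sd = NULL,
                                control = fit_control()) {
  if (!ar_stationary(ar_coeffs)) stop("ar_coeffs must be stationary")
  g <- fit_gam(series, df_temp, df_time, fix_weights = lag_weights(weights),
               control = control)
  y <- g$y; m <- length(y); p <- length(ar_coeffs)
  des <- build_design(series, df_temp, df_time, lag_weights(weights),
                      g$temp_spec, g$time_spec)
  D <- ar_diff_matrix(ar_coeffs, m)
  DtD <- Matrix::crossprod(D)
  lfac <- sum(lfactorial(y))
  chol_env <- new.env(parent = emptyenv())
  eval_sigma <- function(sigma) {
    fit <- pirls(des$X, y, DtD, sigma, g$coefficients, rep(0, m), lfac,
                 tol = control$tol, chol_env = chol_env)
    fit$pen_ll - (m - p) * log(sigma) - 0.5 * fit$ldetA
  }
  if (!is.null(innovation_sd)) return(eval_sigma(innovation_sd))
  opt <- stats::optimize(function(ls) -eval_sigma(exp(ls)),
                         interval = c(-7, 1.5), tol = 1e-6)
  -opt$objective
}
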
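test_that("the GAM recovers the generating lag weights", {
  # 3 replicates at n=1500 keep Monte-Carlo error small relative to the
  # +-0.08 bracket on the mean of w1-hat
  w_true <- c(0.6, 0.25, 0.15)
  what <- sapply(1:3, function(i) {
    s <- simulate_series(gam_truth_config(n_days = 1500, seed = 100 + i,
                                          lag_weights = w_true))
    unclass(fit_gam(s, df_temp = 6, df_time = 2)$weights)
  })
  expect_lt(abs(mean(what[1, ]) - 0.6), 0.08)
  expect_lt(abs(mean(what[2, ]) - 0.25), 0.08)
})

test_that("fixing the weights at the truth costs at most the free parameters", {
  s <- simulate_series(gam_truth_config(n_days = 800, seed = 31,
                                        lag_weights = c(1, 0, 0)))
  free <- fit_gam(s, 5, 2)
  fixed <- fit_gam(s, 5, 2, fix_weights = c(1, 0, 0))
  # nesting: free-weight deviance can beat the true-weight fit by at most
  # ~chi2(2); allow the conventional 2*(number of extra parameters)
  expect_lte(2 * (free$loglik - fixed$loglik), 2 * 2 + 4)
  expect_gte(free$loglik, fixed$loglik - 1e-6)
  # AIC bookkeeping counts the two free weight parameters
  expect_equal(free$aic, -2 * free$loglik + 2 * (length(free$coefficients) + 2))
  expect_equal(fixed$aic, -2 * fixed$loglik + 2 * length(fixed$coefficients))
})

test_that("temperature coefficients are jointly null when there is no effect", {
  # flat temperature truth; joint Wald test at fixed equal weights (the lag
  # weights are unidentified when the exposure has no effect)
  reps <- 40
  rej <- 0
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_days = 400, seed = 400 + i, slopes = c(0, 0, 0),
                      ar_coeffs = numeric(0), innovation_sd = 0)
    g <- fit_gam(simulate_series(cfg), df_temp = 4, df_time = 1,
                 fix_weights = rep(1, 3) / 3)
    b <- g$coefficients[g$temp_cols]
    V <- g$cov[g$temp_cols, g$temp_cols]
    stat <- as.numeric(t(b) %*% solve(V, b))
    if (stat > qchisq(0.95, length(b))) rej <- rej + 1
  }
  expect_lte(rej / reps, 0.15)
})

test_that("degenerate designs raise a singularity error", {
  s <- simulate_series(quick_config(n_days = 300, seed = 1))
  s$temp_mean[] <- 10  # constant exposure cannot support a spline
  expect_error(fit_gam(s, 4, 2), "distinct|singular")
})

test_that("series shorter than the parameter budget are rejected", {
  s <- simulate_series(quick_config(n_days = 20, seed = 2))
  expect_error(fit_gam(s, 6, 4), "too short")
})

test_that("Pearson residuals are zero at a perfect fit and unit-variance when well specified", {
  stub <- structure(list(y = c(3, 7, 11), fitted_mu = c(3, 7, 11)),
                    class = "gam_fit")
  expect_equal(pearson_residuals(stub), rep(0, 3))

  s <- simulate_series(gam_truth_config(n_days = 1500, seed = 77))
  g <- fit_gam(s, 6, 2)
  expect_gt(var(pearson_residuals(g)), 0.8)
  expect_lt(var(pearson_residuals(g)), 1.2)
})

test_that("overdispersed counts inflate the Pearson residual variance", {
  set.seed(11)
  n <- 1000
  mu <- 200
  y <- rnbinom(n, mu = mu, size = 20)  # variance mu + mu^2/20 = 5 mu
  r <- (y - mu) / sqrt(mu)
  expect_gt(var(r), 1.5)
})

test_that("fitted means are positive and the covariance is symmetric PSD", {
  s <- simulate_series(quick_config(n_days = 600, seed = 13))
  g <- fit_gam(s, 5, 2)
  expect_true(all(g$fitted_mu > 0))
  expect_equal(g$cov, t(g$cov), tolerance = 1e-10)
  ev <- eigen(g$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  expect_true(g$converged)
})
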
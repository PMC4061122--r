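test_that("temperature simulation is deterministic and degenerates correctly", {
  cfg <- quick_config(n_days = 400, seed = 42)
  expect_identical(simulate_temperature(cfg), simulate_temperature(cfg))

  flat <- quick_config(n_days = 400, temp_amplitude = 0, temp_noise_sd = 0)
  expect_equal(simulate_temperature(flat),
               rep(flat$temp_mean_annual, 400))

  expect_error(sim_config(n_days = 3), "at least 4")
})

test_that("default temperature climate covers a subtropical annual range", {
  cfg <- sim_config(n_days = 2000, seed = 1)
  temp <- simulate_temperature(cfg)
  expect_gt(min(temp), -10); expect_lt(max(temp), 40)
  # span must cover at least 0..30 degC, as observed mean temperatures do
  expect_lt(min(temp), 0); expect_gt(max(temp), 30)
  # sinusoid peaks in summer: July-August mean beats January mean
  dates <- cfg$start_date + seq_len(2000) - 1
  mo <- as.integer(format(dates, "%m"))
  expect_gt(mean(temp[mo %in% 7:8]), mean(temp[mo == 1]) + 15)
})

test_that("the true temperature effect is a V with a flat minimum band", {
  cfg <- sim_config()
  expect_equal(true_temperature_effect(27, cfg), 0)          # anchor at b2
  expect_equal(true_temperature_effect(32, cfg), 0.0113 * 2) # hand arithmetic
  grid <- seq(0, 35, by = 0.1)
  eff <- true_temperature_effect(grid, cfg)
  expect_true(all(true_temperature_effect(27, cfg) <= eff))
  # flat exactly on the plateau
  expect_equal(true_temperature_effect(seq(27, 30, 0.5), cfg), rep(0, 7))
  # continuity across breakpoints
  expect_equal(true_temperature_effect(11 - 1e-9, cfg),
               true_temperature_effect(11 + 1e-9, cfg), tolerance = 1e-6)
})

test_that("simulated series are deterministic and obey the count contract", {
  cfg <- quick_config(seed = 9)
  s1 <- simulate_series(cfg); s2 <- simulate_series(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$temp_mean, s2$temp_mean)
  expect_true(all(s1$counts >= 0))
  expect_s3_class(s1, "daily_series")
  expect_error(sim_config(ar_coeffs = c(1.2)), "stationary")
})

test_that("without a random effect the latent mean is the deterministic predictor", {
  cfg <- quick_config(n_days = 500, seed = 3, ar_coeffs = numeric(0),
                      innovation_sd = 0)
  s <- simulate_series(cfg)
  t <- seq_len(500)
  dow <- unname(cfg$dow_effects[as.integer(format(s$dates, "%u"))])
  texp <- s$temp_mean
  w <- cfg$lag_weights
  texp[4:500] <- w[1] * s$temp_mean[3:499] + w[2] * s$temp_mean[2:498] +
    w[3] * s$temp_mean[1:497]
  eta <- cfg$intercept + true_temperature_effect(texp, cfg) +
    cfg$trend_slope * (t - 1) / 365.25 + dow
  expect_equal(log(s$truth$mu), eta, tolerance = 1e-12)
})

test_that("yearly mean counts rise under the default trend", {
  s <- simulate_series(sim_config(n_days = 2000, seed = 2))
  yr <- format(s$dates, "%Y")
  means <- tapply(s$counts, yr, mean)
  means <- means[names(means) < "2012"]  # last partial year is noisy
  expect_true(all(diff(means) > 0))
})

test_that("the AR random effect has the configured autocorrelation", {
  s <- simulate_series(sim_config(n_days = 2000, seed = 4,
                                  ar_coeffs = 0.5, innovation_sd = 0.05))
  d <- s$truth$delta
  a1 <- stats::acf(d, lag.max = 5, plot = FALSE)$acf[2]
  expect_equal(a1, 0.5, tolerance = 0.05)
  # lags 1..5 track the analytic AR(1) ACF rho^k
  ak <- as.numeric(stats::acf(d, lag.max = 5, plot = FALSE)$acf)[-1]
  expect_lt(max(abs(ak - 0.5^(1:5))), 0.08)
  # marginal sd near the stationary value
  expect_equal(sd(d), 0.05 / sqrt(1 - 0.25), tolerance = 0.1)
})

test_that("counts are conditionally Poisson around the stored latent mean", {
  s <- simulate_series(sim_config(n_days = 10000, seed = 6))
  ratio <- s$counts / s$truth$mu
  se <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * se)
})

test_that("equal day-of-week effects give indistinguishable weekday totals", {
  cfg <- sim_config(n_days = 1400, seed = 8, dow_effects = rep(0, 7),
                    trend_slope = 0, slopes = c(0, 0, 0),
                    ar_coeffs = numeric(0), innovation_sd = 0)
  s <- simulate_series(cfg)
  wd <- as.integer(format(s$dates, "%u"))
  tot <- tapply(s$counts, wd, sum)
  expect_gt(stats::chisq.test(tot)$p.value, 0.01)
})

test_that("daily_series validates its invariants", {
  d <- as.Date("2020-01-01") + 0:9
  expect_error(daily_series(d[-3], rep(1, 9), rep(10, 9)), "consecutive")
  expect_error(daily_series(d, c(-1, rep(1, 9)), rep(10, 10)),
               "non-negative integers")
  expect_error(daily_series(d, rep(1.5, 10), rep(10, 10)),
               "non-negative integers")
  expect_error(daily_series(d, rep(1, 10), rep(10, 10),
                            temp_min = rep(11, 10), temp_max = rep(12, 10)),
               "elementwise")
  expect_silent(daily_series(d, rep(1, 10), rep(10, 10)))
})
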
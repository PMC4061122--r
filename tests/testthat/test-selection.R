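test_that("a linear time trend selects a small df and candidates deduplicate", {
  s <- simulate_series(gam_truth_config(n_days = 1100, seed = 81))
  sel <- select_df_time(s, candidates = c(1, 1, 2, 3, 4))
  expect_lte(sel$df_time, 2)
  expect_equal(nrow(sel$candidate_table), 4)  # duplicates removed
  expect_true(sel$df_time %in% sel$candidate_table$df_time)
})

test_that("time-trend selection refuses short series", {
  s <- simulate_series(quick_config(n_days = 400, seed = 82))
  expect_error(select_df_time(s, 1:3), "2 full years")
})

test_that("a bending trend needs more than a linear time basis", {
  # superpose a smooth ~2-year-period bend on the counts: a straight-line
  # trend leaves a slow wave whose phase shifts across years, destabilizing
  # the annual seasonal profile until the time spline can absorb it
  cfg <- gam_truth_config(n_days = 1100, seed = 83, trend_slope = 0)
  s <- simulate_series(cfg)
  bend <- exp(0.3 * sin(2 * pi * seq_along(s$counts) / 730))
  set.seed(83)
  s2 <- daily_series(s$dates, rpois(1100, s$truth$mu * bend), s$temp_mean)
  sel <- select_df_time(s2, candidates = 1:5)
  expect_gt(sel$df_time, 1)
})

test_that("AIC prefers enough curvature for a V and linearity for a line", {
  # V-shaped truth needs at least 3 df
  s <- simulate_series(gam_truth_config(n_days = 1200, seed = 84))
  sel <- select_df_temp(s, df_time = 1, candidates = 2:6)
  expect_gte(sel$df_temp, 3)
  expect_equal(sel$candidate_table$df_temp[which.min(sel$candidate_table$aic)],
               sel$df_temp)

  # linear truth: df = 1 wins most of the time; allow df 2 on a noisy draw
  sl <- simulate_series(linear_temp_config(n_days = 1200, seed = 85))
  sel1 <- select_df_temp(sl, df_time = 1, candidates = 1:5)
  expect_lte(sel1$df_temp, 2)

  # a single candidate comes back unchanged
  sel_one <- select_df_temp(s, df_time = 1, candidates = 4)
  expect_equal(sel_one$df_temp, 4)
})

test_that("the admissibility band is exactly +-0.1", {
  acf_ok <- rep(0.05, 30); pacf_ok <- rep(0.05, 30)
  expect_true(acf_admissible(acf_ok, pacf_ok))
  acf_edge <- acf_ok; acf_edge[7] <- 0.100001
  expect_false(acf_admissible(acf_edge, pacf_ok))
  acf_edge[7] <- 0.0999
  expect_true(acf_admissible(acf_edge, pacf_ok))
  pacf_edge <- pacf_ok; pacf_edge[3] <- -0.100001
  expect_false(acf_admissible(acf_ok, pacf_edge))
})

test_that("AR order selection matches the generating process", {
  # white-noise truth: p = 0 admissible and chosen
  s0 <- simulate_series(sim_config(n_days = 1200, seed = 86,
                                   ar_coeffs = numeric(0), innovation_sd = 0))
  sel0 <- select_ar_order(s0, 5, 2, p_candidates = 0:2)
  expect_equal(sel0$p, 0)
  expect_true(sel0$candidate_table$admissible[1])

  # AR(1) truth: p = 0 inadmissible, p >= 1 admissible and chosen
  s1 <- simulate_series(sim_config(n_days = 1200, seed = 87,
                                   ar_coeffs = 0.5, innovation_sd = 0.05))
  sel1 <- select_ar_order(s1, 5, 2, p_candidates = 0:2)
  expect_false(sel1$candidate_table$admissible[1])
  expect_gte(sel1$p, 1)

  # single-candidate list returns that candidate with its evidence row
  sel_one <- select_ar_order(s1, 5, 2, p_candidates = 1)
  expect_equal(sel_one$p, 1)
  expect_equal(nrow(sel_one$candidate_table), 1)

  expect_error(select_ar_order(s1, 5, 2, p_candidates = integer(0)), "empty")
})

test_that("selection is deterministic", {
  s <- simulate_series(quick_config(n_days = 800, seed = 88))
  a <- select_df_temp(s, 1, candidates = 3:5)
  b <- select_df_temp(s, 1, candidates = 3:5)
  expect_identical(a$candidate_table, b$candidate_table)
})
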
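test_that("a 1-df natural spline is affine in x and extrapolates linearly", {
  x <- seq(0, 10, length.out = 50)
  sp <- spline_spec(x, df = 1)
  b <- natural_spline_basis(x, sp)
  expect_equal(ncol(b), 1L)
  fit <- lm(b[, 1] ~ x)
  expect_lt(max(abs(residuals(fit))), 1e-10)

  # beyond the boundary knots every column is linear: zero second difference
  sp4 <- spline_spec(seq(1, 100), df = 4)
  hi <- sp4$boundary_knots[2] + c(1, 2, 3) * 2.5
  bh <- natural_spline_basis(hi, sp4)
  second_diff <- bh[1, ] - 2 * bh[2, ] + bh[3, ]
  expect_lt(max(abs(second_diff)), 1e-9)
  lo <- sp4$boundary_knots[1] - c(3, 2, 1) * 4
  bl <- natural_spline_basis(lo, sp4)
  expect_lt(max(abs(bl[1, ] - 2 * bl[2, ] + bl[3, ])), 1e-9)
})

test_that("the basis spans the truncated-power natural-spline space", {
  # oracle: the textbook truncated-power construction (constant, linear,
  # and d_k(x) - d_{K-1}(x) terms) over the same knot set; the two bases
  # differ columnwise but must span the same function space
  x <- seq(1, 100)
  sp <- spline_spec(x, df = 4)
  knots <- c(sp$boundary_knots[1], sp$interior_knots, sp$boundary_knots[2])
  K <- length(knots)
  dk <- function(x, k) {
    (pmax(x - knots[k], 0)^3 - pmax(x - knots[K], 0)^3) / (knots[K] - knots[k])
  }
  oracle <- cbind(1, x, sapply(seq_len(K - 2),
                               function(k) dk(x, k) - dk(x, K - 1)))
  ours <- cbind(1, natural_spline_basis(x, sp))
  expect_equal(ncol(oracle), ncol(ours))
  for (j in seq_len(ncol(oracle))) {
    res <- residuals(lm(oracle[, j] ~ ours - 1))
    expect_lt(max(abs(res)), 1e-7)
  }
  # and conversely
  for (j in seq_len(ncol(ours))) {
    res <- residuals(lm(ours[, j] ~ oracle - 1))
    expect_lt(max(abs(res)), 1e-7)
  }
})

test_that("spline specification rejects degenerate inputs", {
  expect_error(spline_spec(1:50, df = 0), "at least 1")
  expect_error(spline_spec(rep(1:3, 10), df = 5), "distinct")
})

test_that("day-of-week indicators use Monday as reference", {
  d <- as.Date("2024-01-01") + 0:6   # a Monday
  m <- dow_indicator(d)
  expect_equal(unname(m[1, ]), rep(0, 6))          # Monday row
  expect_equal(unname(m[7, "dow_Sun"]), 1)         # Sunday
  expect_equal(sum(m[7, ]), 1)
  expect_equal(unname(colSums(m)), rep(1, 6))      # one of each weekday
  expect_true(all(rowSums(m) <= 1))
})

test_that("the lag-weighted exposure matches hand arithmetic", {
  temp <- c(5, 10, 20, 12, 7)
  # day t=4: lags (T3,T2,T1)=(20,10,5) -> (12,20,10) for t=5
  out <- lagged_weighted_temperature(temp, c(0.5, 0.3, 0.2))
  expect_equal(out[2], 0.5 * 12 + 0.3 * 20 + 0.2 * 10)  # = 14.0
  expect_equal(out[1], 0.5 * 20 + 0.3 * 10 + 0.2 * 5)

  # degenerate weights pick out lag 1 exactly
  expect_equal(lagged_weighted_temperature(temp, c(1, 0, 0)), temp[3:4])
  # convexity: constant temperature stays constant
  expect_equal(lagged_weighted_temperature(rep(8, 10), c(0.2, 0.5, 0.3)),
               rep(8, 7))
  expect_error(lagged_weighted_temperature(1:3, c(1, 0, 0)), "at least 4")
  expect_error(lagged_weighted_temperature(1:10, c(0.9, 0.2, -0.1)),
               "non-negative")
})

test_that("the exposure is affine-equivariant because weights sum to one", {
  set.seed(5)
  temp <- rnorm(60, 15, 8)
  w <- c(0.6, 0.25, 0.15)
  a <- 1.8; b <- -4
  expect_equal(lagged_weighted_temperature(a * temp + b, w),
               a * lagged_weighted_temperature(temp, w) + b,
               tolerance = 1e-12)
})

test_that("the assembled design has full column rank on realistic data", {
  s <- simulate_series(quick_config(n_days = 400, seed = 10))
  des <- mgamtemp:::build_design(s, 5, 3, c(0.5, 0.3, 0.2))
  expect_equal(qr(des$X)$rank, ncol(des$X))
  expect_equal(nrow(des$X), 400 - 3)
  expect_false(anyNA(des$X))
})
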
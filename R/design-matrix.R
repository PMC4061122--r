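# Fixed-effect design: natural-spline bases for the lag-weighted temperature
# and the time trend, plus day-of-week indicators (Monday reference).

#' Lag weights for the distributed-lag temperature exposure
#'
#' Non-negative weights over lags 1..3 (calendar days before the count day)
#' summing to one.
#'
#' @param w numeric 3-vector.
#' @return an object of class `lag_weights`.
#' @export
lag_weights <- function(w) {
  w <- as.numeric(w)
  if (length(w) != 3L) stop("lag weights must have length 3")
  if (any(w < 0)) stop("lag weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-10) stop("lag weights must sum to 1")
  structure(w, names = c("w1", "w2", "w3"), class = "lag_weights")
}

#' Natural-spline specification
#'
#' Fixes the knots of a natural cubic spline basis so the basis can be
#' evaluated reproducibly on new values.  By default interior knots sit at
#' equal quantiles of `x` and boundary knots at the range of `x` (the
#' [splines::ns()] convention); beyond the boundary knots the basis
#' extrapolates linearly.  Placing the boundary knots inside the data range
#' (say the 1st and 99th percentiles) is available via
#' `boundary_quantiles`, but it linearizes the outer percentiles of the
#' fitted curve and systematically attenuates slopes reported over extreme
#' covariate ranges, so the data range is the default.
#'
#' @param x values used to place knots.
#' @param df degrees of freedom (number of basis columns), >= 1.
#' @param interior_knots,boundary_knots optional explicit knots.
#' @param boundary_quantiles quantiles defining the boundary knots when not
#'   given explicitly.
#' @return an object of class `spline_spec`.
#' @export
spline_spec <- function(x, df, interior_knots = NULL, boundary_knots = NULL,
                        boundary_quantiles = c(0, 1)) {
  df <- as.integer(df)
  if (df < 1L) stop("df must be at least 1")
  if (length(unique(x)) <= df)
    stop("need more distinct values than degrees of freedom")
  if (is.null(boundary_knots))
    boundary_knots <- unname(stats::quantile(x, boundary_quantiles))
  if (is.null(interior_knots)) {
    if (df > 1L) {
      probs <- seq_len(df - 1L) / df
      interior_knots <- unname(stats::quantile(x, probs))
    } else interior_knots <- numeric(0)
  }
  if (length(interior_knots) != df - 1L)
    stop("number of interior knots must equal df - 1")
  if (length(interior_knots) > 0) {
    if (any(diff(interior_knots) <= 0) ||
        any(interior_knots <= boundary_knots[1]) ||
        any(interior_knots >= boundary_knots[2]))
      stop("interior knots must be strictly increasing and strictly inside the boundary knots")
  }
  structure(list(df = df, interior_knots = interior_knots,
                 boundary_knots = boundary_knots),
            class = "spline_spec")
}

#' Evaluate a natural cubic spline basis
#'
#' Cubic between knots, linear beyond the boundary knots, `df` columns
#' (intercept excluded).  Wraps [splines::ns()] with the fixed knots of a
#' [spline_spec()], so evaluation at new `x` uses the original knots.
#'
#' @param x values at which to evaluate.
#' @param spec a [spline_spec()].
#' @return matrix with `length(x)` rows and `spec$df` columns.
#' @export
natural_spline_basis <- function(x, spec) {
  if (any(!is.finite(x))) stop("x must be finite")
  b <- splines::ns(x, knots = spec$interior_knots,
                   Boundary.knots = spec$boundary_knots)
  b <- unclass(b)[, , drop = FALSE]
  attributes(b)[setdiff(names(attributes(b)), "dim")] <- NULL
  b
}

#' Day-of-week indicator block
#'
#' One-hot indicators for Tuesday..Sunday; Monday is the reference (all six
#' columns zero).  The reference choice is presentation-invariant because
#' the report layer re-expresses effects relative to the weekly geometric
#' mean.
#'
#' @param dates a `Date` vector.
#' @return numeric matrix with columns `dow_Tue`..`dow_Sun`.
#' @export
dow_indicator <- function(dates) {
  d <- day_of_week(dates)
  m <- matrix(0, length(d), 6L,
              dimnames = list(NULL, paste0("dow_", dow_names[2:7])))
  for (j in 2:7) m[d == j, j - 1L] <- 1
  m
}

#' Lag-weighted mean temperature
#'
#' `T*_t = w1 T_{t-1} + w2 T_{t-2} + w3 T_{t-3}` for `t >= 4` (1-based);
#' "lag k" means k calendar days before the count day.  Because the weights
#' sum to one, `T*` is affine-equivariant in the temperature scale.
#'
#' @param temp temperature vector, length >= 4.
#' @param weights a [lag_weights()] or plain valid 3-vector.
#' @return vector of length `length(temp) - 3`, aligned to days 4..n.
#' @export
lagged_weighted_temperature <- function(temp, weights) {
  n <- length(temp)
  if (n < 4L) stop("need at least 4 days for a lag-3 exposure")
  w <- lag_weights(unclass(weights))
  w[1] * temp[3:(n - 1L)] + w[2] * temp[2:(n - 2L)] + w[3] * temp[1:(n - 3L)]
}

# Assemble the full fixed-effect design for days t >= 4.
#
# Knot placement convention: the temperature-spline knots are fixed from the
# equal-weight (1/3, 1/3, 1/3) exposure before any weight optimization and
# held fixed while the weights update; a moving basis would make the
# likelihood discontinuous in the weights.  Time-trend knots come from the
# day index with boundary knots at its range.
build_design <- function(series, df_temp, df_time, weights,
                         temp_spec = NULL, time_spec = NULL) {
  n <- length(series$counts)
  if (is.null(temp_spec)) {
    t0 <- lagged_weighted_temperature(series$temp_mean, rep(1, 3) / 3)
    temp_spec <- spline_spec(t0, df_temp)
  }
  tindex <- seq_len(n)[-(1:3)]
  if (is.null(time_spec))
    time_spec <- spline_spec(tindex, df_time, boundary_quantiles = c(0, 1))
  tstar <- lagged_weighted_temperature(series$temp_mean, weights)
  bt <- natural_spline_basis(tstar, temp_spec)
  colnames(bt) <- paste0("temp_ns_", seq_len(ncol(bt)))
  bs <- natural_spline_basis(tindex, time_spec)
  colnames(bs) <- paste0("time_ns_", seq_len(ncol(bs)))
  dowm <- dow_indicator(series$dates[-(1:3)])
  X <- cbind(`(Intercept)` = 1, bt, bs, dowm)
  list(X = X, tstar = tstar, temp_spec = temp_spec, time_spec = time_spec,
       temp_cols = 1L + seq_len(ncol(bt)),
       time_cols = 1L + ncol(bt) + seq_len(ncol(bs)),
       dow_cols = 1L + ncol(bt) + ncol(bs) + seq_len(6L))
}

# Precomputed design pieces that do not depend on the lag weights: the lag
# matrix of temperatures (so T* = L w), and the constant intercept /
# time-spline / day-of-week columns.  assemble(w) rebuilds only the
# temperature block, which is what the weight optimizer needs in its loop.
make_design_cache <- function(series, df_temp, df_time, temp_spec = NULL,
                              time_spec = NULL) {
  temp <- series$temp_mean
  n <- length(temp)
  L <- cbind(temp[3:(n - 1L)], temp[2:(n - 2L)], temp[1:(n - 3L)])
  if (is.null(temp_spec)) temp_spec <- spline_spec(rowMeans(L), df_temp)
  tindex <- seq_len(n)[-(1:3)]
  if (is.null(time_spec))
    time_spec <- spline_spec(tindex, df_time, boundary_quantiles = c(0, 1))
  bs <- natural_spline_basis(tindex, time_spec)
  colnames(bs) <- paste0("time_ns_", seq_len(ncol(bs)))
  dowm <- dow_indicator(series$dates[-(1:3)])
  fixed <- cbind(bs, dowm)
  k_temp <- temp_spec$df
  temp_names <- paste0("temp_ns_", seq_len(k_temp))
  assemble <- function(w) {
    tstar <- as.numeric(L %*% w)
    bt <- natural_spline_basis(tstar, temp_spec)
    colnames(bt) <- temp_names
    X <- cbind(`(Intercept)` = 1, bt, fixed)
    list(X = X, tstar = tstar)
  }
  list(assemble = assemble, temp_spec = temp_spec, time_spec = time_spec,
       temp_cols = 1L + seq_len(k_temp),
       time_cols = 1L + k_temp + seq_len(time_spec$df),
       dow_cols = 1L + k_temp + time_spec$df + seq_len(6L))
}
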
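# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Map two unconstrained parameters to the 3-simplex (multinomial logit with
# the third category as reference).  Enforces w >= 0, sum(w) = 1 by
# construction.
softmax3 <- function(theta) {
  e <- exp(c(theta, 0) - max(theta, 0))
  e / sum(e)
}

# Inverse of softmax3; requires w strictly inside the simplex.
theta_from_weights <- function(w) {
  if (any(w <= 0)) stop("weights on the simplex boundary cannot be mapped to logit scale")
  log(w[1:2] / w[3])
}

geometric_mean <- function(x) exp(mean(log(x)))

# AR(p) coefficients <-> partial autocorrelations (Levinson recursions).
# The partial-autocorrelation parameterization maps (-1,1)^p onto the
# stationarity region, so constrained optimization is unconstrained in
# atanh(pacf) coordinates.
pacf_to_ar <- function(k) {
  a <- numeric(0)
  for (j in seq_along(k)) {
    if (j > 1L) a <- a - k[j] * rev(a)
    a <- c(a, k[j])
  }
  a
}

ar_to_pacf <- function(a) {
  p <- length(a)
  k <- numeric(p)
  if (p == 0L) return(k)
  for (j in p:1) {
    k[j] <- a[j]
    if (j > 1L) {
      if (abs(k[j]) >= 1) stop("non-stationary AR coefficients")
      a <- (a[1:(j - 1L)] + k[j] * rev(a[1:(j - 1L)])) / (1 - k[j]^2)
    }
  }
  k
}

#' Check stationarity of AR coefficients
#'
#' An AR(p) process is stationary when all roots of its characteristic
#' polynomial lie outside the unit circle.
#'
#' @param ar_coeffs numeric vector of AR coefficients (may be empty).
#' @return `TRUE` or `FALSE`.
#' @export
ar_stationary <- function(ar_coeffs) {
  if (length(ar_coeffs) == 0L) return(TRUE)
  if (any(!is.finite(ar_coeffs))) return(FALSE)
  all(Mod(polyroot(c(1, -ar_coeffs))) > 1)
}

day_of_week <- function(dates) {
  # 1 = Monday ... 7 = Sunday, locale-independent
  as.integer(format(dates, "%u"))
}

dow_names <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
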
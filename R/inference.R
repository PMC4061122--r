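# Inference on the distributed-lag weights.

#' Pairwise tests on the estimated lag weights
#'
#' Delta-method standard errors of the lag weights under the sum-to-one
#' constraint (propagated from the multinomial-logit coordinates through the
#' profile-likelihood Hessian), Wald z-tests of `w1 = w2`, `w1 = w3` and
#' `w2 = w3`, and a constrained refit with `w2 = w3` reporting the common
#' tail weight and its standard error.
#'
#' @param fit a converged `gam_fit` or `mgam_fit` with freely estimated
#'   weights.
#' @param refit_constrained also perform the `w2 = w3` constrained refit
#'   (requires refitting the model; set `FALSE` to skip).
#' @return a list of class `weight_inference` with elements `weights`, `se`,
#'   `cov`, `tests` (data frame), `common_tail` (estimate, se) and
#'   `boundary` (flag: `TRUE` when an estimated weight sits on the simplex
#'   boundary, making the Wald tests unreliable).
#' @export
weight_inference <- function(fit, refit_constrained = TRUE) {
  if (!isTRUE(fit$free_weights) || is.null(fit$theta))
    stop("weight inference requires a fit with freely estimated weights")
  if (!isTRUE(fit$converged))
    warning("fit did not converge; weight inference may be unreliable")

  if (inherits(fit, "mgam_fit") && fit$ar_order > 0) {
    hh <- fit$outer_hessian
    cov_all <- tryCatch(solve(hh), error = function(e) NULL)
    theta_cov <- if (is.null(cov_all)) matrix(NA_real_, 2, 2) else cov_all[1:2, 1:2]
  } else {
    theta_cov <- tryCatch(solve(fit$theta_hessian),
                          error = function(e) matrix(NA_real_, 2, 2))
  }

  w <- as.numeric(fit$weights)
  # Jacobian of softmax at theta (third logit fixed at 0): dw_i/dtheta_j
  J <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) J[i, j] <- w[i] * ((i == j) - w[j])
  cov_w <- J %*% theta_cov %*% t(J)
  se_w <- sqrt(pmax(diag(cov_w), 0))

  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  tests <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    d <- w[i] - w[j]
    se <- sqrt(max(cov_w[i, i] + cov_w[j, j] - 2 * cov_w[i, j], 0))
    z <- if (se > 0) d / se else NA_real_
    data.frame(hypothesis = sprintf("w%d = w%d", i, j), diff = d, se = se,
               z = z, p_value = 2 * stats::pnorm(-abs(z)))
  }))

  boundary <- any(w < 1e-3)
  if (boundary)
    warning("estimated weight on the simplex boundary; Wald tests flagged unreliable")

  common <- NULL
  if (refit_constrained) common <- constrained_tail_refit(fit)

  structure(list(weights = stats::setNames(w, c("w1", "w2", "w3")),
                 se = stats::setNames(se_w, c("w1", "w2", "w3")),
                 cov = cov_w, tests = tests, common_tail = common,
                 boundary = boundary),
            class = "weight_inference")
}

# Refit with w2 = w3 = (1 - w1)/2, one free logit; returns the common tail
# weight and its delta-method SE.
constrained_tail_refit <- function(fit) {
  series <- fit$series
  ctrl <- fit$control
  w_of <- function(th) {
    e <- exp(th)
    c(e, 1, 1) / (e + 2)
  }
  if (inherits(fit, "mgam_fit") && fit$ar_order > 0) {
    p <- fit$ar_order
    npl <- function(th)
      -mgam_profile_loglik(series, fit$df_temp, fit$df_time, w_of(th),
                           constrained_ar(fit, th), innovation_sd = NULL,
                           control = ctrl)
    # hold the AR parameters at their unconstrained optimum; the weights and
    # AR structure are close to orthogonal
    opt <- stats::optimize(npl, interval = c(-4, 4), tol = 1e-6)
  } else {
    negpl <- function(th) {
      g <- fit_gam(series, fit$df_temp, fit$df_time,
                   fix_weights = lag_weights(w_of(th)), control = ctrl)
      -g$loglik
    }
    npl <- negpl
    opt <- stats::optimize(npl, interval = c(-4, 4), tol = 1e-6)
  }
  th <- opt$minimum
  h <- stats::optimHess(th, npl)[1, 1]
  w <- w_of(th)
  dw2 <- -w[1] * w[2]          # d w2 / d theta
  se <- if (h > 0) abs(dw2) / sqrt(h) else NA_real_
  list(estimate = w[2], se = se, w1 = w[1], objective = -opt$objective)
}

constrained_ar <- function(fit, th) fit$ar_coeffs

#' @export
print.weight_inference <- function(x, ...) {
  cat("<weight_inference>\n  weights (se):",
      paste(sprintf("%.3f (%.3f)", x$weights, x$se), collapse = "  "), "\n")
  print(x$tests, row.names = FALSE)
  if (!is.null(x$common_tail))
    cat(sprintf("  constrained w2 = w3: %.3f (se %.3f)\n",
                x$common_tail$estimate, x$common_tail$se))
  if (x$boundary) cat("  WARNING: boundary estimate; tests unreliable\n")
  invisible(x)
}
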
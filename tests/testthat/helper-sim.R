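# Small simulation configurations shared across tests.  Sizes are chosen so
# the whole suite runs in minutes while keeping Monte-Carlo error well below
# the tolerances being asserted.

quick_config <- function(n_days = 700, seed = 1, ...) {
  sim_config(n_days = n_days, seed = seed, ...)
}

# GAM-truth data: no random effect (model I)
gam_truth_config <- function(n_days = 700, seed = 1, ...) {
  sim_config(n_days = n_days, seed = seed, ar_coeffs = numeric(0),
             innovation_sd = 0, ...)
}

# a linear exposure-response: piecewise structure pushed below the observed
# temperature range so only the upper linear piece is active
linear_temp_config <- function(n_days = 700, seed = 1, slope = -0.01, ...) {
  sim_config(n_days = n_days, seed = seed, breakpoints = c(-60, -55),
             plateau_end = -50, slopes = c(0, 0, slope),
             ar_coeffs = numeric(0), innovation_sd = 0, ...)
}

expect_rel_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b) / pmax(abs(b), 1e-8)), tol)
}
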
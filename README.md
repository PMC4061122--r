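# mgamtemp

Mixed generalized additive models for temperature-driven daily event
counts.

Environmental-epidemiology count series — daily emergency examinations,
hospital admissions, mortality — respond to ambient temperature with a
short lag, on top of a rising secular trend, a weekly rhythm, and serial
correlation that ordinary Poisson regression ignores.  `mgamtemp`
implements the analysis this situation calls for:

* a **Poisson GAM** with natural-spline smooths of a *distributed-lag
  weighted mean temperature* and of calendar time, plus day-of-week
  effects:

  log mu_t = b0 + f(T\*_t) + g(t) + dow_t,  with
  T\*_t = w1 T_{t-1} + w2 T_{t-2} + w3 T_{t-3}, w_l >= 0, sum w_l = 1,

  where the three lag weights are **estimated jointly** with the curve;
* a **mixed GAM (MGAM)** adding a stationary AR(p) random effect delta_t
  on the log scale (delta_t = sum_i rho_i delta_{t-i} + eps_t), estimated
  by maximum partial likelihood with the random-effect path profiled out
  by penalized IRLS and a Laplace correction;
* the three **model-selection** procedures used with these models:
  time-trend df by year-to-year seasonality invariance, temperature df by
  AIC, AR order by the residual ACF/PACF admissibility band [-0.1, 0.1];
* **inference on the lag weights** (delta-method SEs on the simplex, Wald
  tests of pairwise equality, constrained equal-tail refit);
* **diagnostics and reports**: residual ACF/PACF, count-scale R^2,
  piecewise slopes of the fitted exposure-response curve with risk ratios
  exp(slope x Delta), and the normalized multiplicative day-of-week
  profile;
* a first-class **synthetic-data generator** reproducing every structural
  feature above, so the whole pipeline is testable without restricted
  registry data.

The methods vignette (`vignettes/mgam-methods.Rmd`) documents the models,
the estimation algorithm, and every numerical design choice.

## Worked example

```r
library(mgamtemp)

# a 5.5-year synthetic series: V-shaped temperature effect, rising trend,
# Sunday-max/Wednesday-min weekly pattern, AR(1) log-scale autocorrelation
s <- simulate_series(sim_config(n_days = 2000, seed = 1))

g <- fit_gam(s, df_temp = 10, df_time = 2)    # independence model
m <- fit_mgam(s, df_temp = 10, df_time = 2, p = 1, init = g)
print(m)
```

```
<mgam_fit> df_temp=10 df_time=2  n=1997 days
  lag weights: (0.506, 0.436, 0.058) [estimated]
  AR(1) coefficients: 0.532  innovation sd 0.0517
  logLik -8259.62  AIC 19123.25  converged: TRUE
```

The generating truth here is weights (0.5, 0.3, 0.2), rho = 0.5,
innovation sd 0.05: the AR parameters land close on a single series,
while the tail lag weights scatter more (their single-series standard
errors are of order 0.1); averaged over the 30-replicate studies in
`tests/testthat/test-acceptance.R` all parameters recover within tight
bands.  The diagnostics report turns the fit
into the quantities such an analysis publishes:

```r
diagnostics_report(m, ranges = list(c(0, 11), c(11, 27), c(30, 35)))
```

```
<diagnostics_report>
  R^2 (count scale) 0.976   pseudo-R^2 (deviance) 0.974
  max |ACF| 0.053, max |PACF| 0.059 over lags 1..30
 from to   slope rr_1c rr_5c
    0 11 -0.0009 0.999 0.996
   11 27 -0.0120 0.988 0.942
   30 35  0.0039 1.004 1.020
  DOW profile: Mon 1.008  Tue 0.990  Wed 0.944  Thu 0.972  Fri 0.995  Sat 1.027  Sun 1.068
```

Reading it: expected counts fall by about 5.8% per 5 °C of warming on
mild (11-27 °C) days, are nearly flat on cold days in this draw, reach
their minimum on the 27-30 °C plateau, and rise on hot days (the
hot-tail slope rests on ~4% of days and is the noisiest entry); residual
autocorrelations sit well inside the +-0.1 admissibility band once the
AR(1) random effect is in the model; the weekly profile peaks on Sunday
and bottoms on Wednesday.

`run_pipeline(run_config(...))` chains selection, both fits, diagnostics
and JSON/CSV artifacts; the `analysis/` scripts (01 simulate, 02 select,
03 fit, 04 diagnostics) run the same workflow as a narrative two-series
study and write their tables under `results/`.

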
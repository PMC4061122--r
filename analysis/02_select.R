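#!/usr/bin/env Rscript
# Stage 2: model selection for each population.
#
# Chooses, in the order the method prescribes: the time-trend df by
# year-to-year seasonality invariance, the temperature-spline df by AIC,
# and the AR order by the +-0.1 residual ACF/PACF admissibility band plus
# AIC.

library(mgamtemp)
dir.create("results/selection", recursive = TRUE, showWarnings = FALSE)

for (sex in c("female", "male")) {
  s <- read_daily_series(sprintf("scratch/data/%s_series.csv", sex))
  st <- select_df_time(s, candidates = 1:4)
  sd_ <- select_df_temp(s, st$df_time, candidates = c(4, 6, 8, 10, 12))
  sp <- select_ar_order(s, sd_$df_temp, st$df_time, p_candidates = 0:2)
  out <- list(df_time = st$df_time, df_temp = sd_$df_temp, p = sp$p,
              df_time_table = st$candidate_table,
              df_temp_table = sd_$candidate_table,
              p_table = sp$candidate_table)
  jsonlite::write_json(out, sprintf("results/selection/%s.json", sex),
                       auto_unbox = TRUE, digits = 12, dataframe = "rows")
  cat(sprintf("[%s] df_time=%d df_temp=%d p=%d | GAM max|ACF| %.3f -> MGAM %.3f\n",
              sex, st$df_time, sd_$df_temp, sp$p,
              sp$candidate_table$max_abs_acf[sp$candidate_table$p == 0],
              sp$candidate_table$max_abs_acf[sp$candidate_table$p == sp$p]))
}
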
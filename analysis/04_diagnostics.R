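#!/usr/bin/env Rscript
# Stage 4: residual diagnostics, goodness of fit, exposure-response slopes
# with risk ratios, and day-of-week profiles for both populations.

library(mgamtemp)
dir.create("results/diagnostics", recursive = TRUE, showWarnings = FALSE)

for (sex in c("female", "male")) {
  s <- read_daily_series(sprintf("scratch/data/%s_series.csv", sex))
  sel <- jsonlite::read_json(sprintf("results/selection/%s.json", sex))
  g <- fit_gam(s, sel$df_temp, sel$df_time)
  m <- fit_mgam(s, sel$df_temp, sel$df_time, p = sel$p, init = g)
  rep <- suppressWarnings(diagnostics_report(m))
  st <- rep$slope_table
  st$slope <- round(st$slope, 4)
  st$rr_1c <- round(st$rr_1c, 3); st$rr_5c <- round(st$rr_5c, 3)
  write.table(st, sprintf("results/diagnostics/%s_slopes.tsv", sex),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(day = names(rep$dow_profile),
                         effect = round(rep$dow_profile, 3)),
              sprintf("results/diagnostics/%s_dow.tsv", sex),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(r_squared = rep$r_squared,
                            r_squared_deviance = rep$r_squared_deviance,
                            max_abs_acf = max(abs(rep$acf)),
                            max_abs_pacf = max(abs(rep$pacf))),
                       sprintf("results/diagnostics/%s_fit_quality.json", sex),
                       auto_unbox = TRUE, digits = 12)
  cat(sprintf("[%s] R^2 %.3f | slopes:", sex, rep$r_squared))
  cat(sprintf(" [%g,%g]=%.4f", st$from, st$to, st$slope), "\n")
}
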
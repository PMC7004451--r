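#!/usr/bin/env Rscript
# Stage 2 -- assign exposures.
#
# Links each residence to its nearest PM2.5 monitor (50-km cap) and weather
# station, averages PM2.5 and dew point over the weeks 3-8 critical window,
# detects extreme heat events under both run rules (EHE95: >=2 days above
# the seasonal 95th percentile; EHE90: >=3 days above the 90th), and
# dichotomizes PM2.5 at the control 80th percentile.

library(heatpm)

cfg <- pipeline_config(output_dir = "scratch/pipeline", seed = 42L)
exposure <- pipeline_expose(cfg)

n <- nrow(exposure)
excl <- table(exposure$exclusion_reason, useNA = "ifany")
cat(sprintf("exposure rows: %d\n", n))
cat(sprintf("PM2.5 cut-point (control 80th percentile): %.2f ug/m3\n",
            attr(exposure, "pm_threshold")))
cat(sprintf("high PM2.5: %.1f%% | EHE95 exposed: %.1f%% | EHE90 exposed: %.1f%%\n",
            100 * mean(exposure$pm_high, na.rm = TRUE),
            100 * mean(exposure$ehe95_exposed),
            100 * mean(exposure$ehe90_exposed)))
cat(sprintf(">=1 window day in spring/summer: %.1f%% | entire window: %.1f%% | >=1 summer day: %.1f%%\n",
            100 * mean(exposure$any_day_spring_summer),
            100 * mean(exposure$entire_window_spring_summer),
            100 * mean(exposure$any_day_summer)))
cat("exclusions:\n"); print(excl)

summary_tbl <- data.frame(
  quantity = c("n_subjects", "pm_threshold_ugm3", "pct_high_pm",
               "pct_ehe95", "pct_ehe90", "pct_any_spring_summer",
               "pct_entire_spring_summer", "pct_any_summer",
               "n_excluded_no_monitor"),
  value = round(c(n, attr(exposure, "pm_threshold"),
                  100 * mean(exposure$pm_high, na.rm = TRUE),
                  100 * mean(exposure$ehe95_exposed),
                  100 * mean(exposure$ehe90_exposed),
                  100 * mean(exposure$any_day_spring_summer),
                  100 * mean(exposure$entire_window_spring_summer),
                  100 * mean(exposure$any_day_summer),
                  sum(!is.na(exposure$exclusion_reason))), 2))
write.csv(summary_tbl, "results/02_exposure_summary.csv", row.names = FALSE)
cat("wrote results/02_exposure_summary.csv\n")
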
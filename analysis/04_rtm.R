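#!/usr/bin/env Rscript
# Step 4: the regression-to-the-mean battery on the simulated study pair,
# and its Monte-Carlo calibration: type-I error when only measurement noise
# is present (gamma = 0) and power as regulation strength grows.

suppressPackageStartupMessages(library(kicer))
co <- read_cohort_csv("results/cohort.csv")
tr <- co[co$arm == "test_retest", ]
ch <- co[co$arm == "challenge", ]

rpt <- rtm_battery(tr, ch)
print(rpt)
write_report_json(rpt, "results/rtm_report.json")
cat("wrote results/rtm_report.json\n")

cal <- calibration_sim(gamma_grid = c(0, 0.3, 0.6, 0.9), n_sim = 2000,
                       alpha = 0.05, seed = 7,
                       base_config = cohort_config(sigma_drift = 5e-4))
print(cal)
cat("at gamma = 0 both tests sit near the nominal 5% level;\n")
cat("the correlation comparison, not the ANOVA interaction, carries the power\n")
cat("against set-point regulation (regulation toward the population mean\n")
cat("shifts no group mean for the interaction to detect).\n")
write.csv(cal, "results/calibration.csv", row.names = FALSE)
cat("wrote results/calibration.csv\n")
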
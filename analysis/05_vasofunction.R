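#!/usr/bin/env Rscript
# Reduce the simulated myography data to basal tone and percent-of-
# maximal-dilation curves by group.

source("analysis/00_design.R")

records <- c(
  make_dose_response(5, 64, 96, noise_sd = 2, seed = MASTER_SEED + 1,
                     condition = "NT"),
  make_dose_response(5, 62, 96, noise_sd = 2, seed = MASTER_SEED + 2,
                     condition = "HT", efficacy = 0.6),
  make_dose_response(5, 64, 96, noise_sd = 2, seed = MASTER_SEED + 3,
                     condition = "NT", treatment = "l-NAME",
                     efficacy = 0.4)
)
cs <- summarize_curves(records)
readr::write_csv(cs$curves, file.path(results_dir(), "dilation_curves.csv"))
readr::write_csv(cs$basal_tone, file.path(results_dir(), "basal_tone.csv"))

for (i in seq_len(nrow(cs$basal_tone))) {
  r <- cs$basal_tone[i, ]
  cat(sprintf("%s/%s: basal tone %.1f +/- %.1f%% (n = %d)\n",
              r$condition, r$treatment, r$mean_pct, r$sem_pct, r$n))
}
top <- dplyr::filter(cs$curves, dose_log10_M == max(dose_log10_M))
cat("Dilation at the top adenosine dose:\n")
print(as.data.frame(top[, c("condition", "treatment", "mean_pct",
                            "sem_pct")]), row.names = FALSE)
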
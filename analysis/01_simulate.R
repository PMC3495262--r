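#!/usr/bin/env Rscript
# Simulate the synthetic cohort: renders one artery phantom per animal
# (NT vs HT differing only in a 1.56x media preset) and a matched
# myography experiment, and writes the ground-truth cohort table.

source("analysis/00_design.R")

co <- make_cohort(cohort_design(), render = FALSE)
readr::write_csv(co$cohort, file.path(results_dir(), "cohort_truth.csv"))

cat("Simulated", nrow(co$cohort), "animals;",
    "true HT/NT media ratio:",
    round(mean(co$cohort$media_true_um[co$cohort$condition == "HT"]) /
            mean(co$cohort$media_true_um[co$cohort$condition == "NT"]), 3),
    "\n")

# arteriole dose-response data: coronary arterioles, NT with full
# dilation, HT with attenuated efficacy, plus an l-NAME arm
records <- c(
  make_dose_response(5, 64, 96, noise_sd = 2, seed = MASTER_SEED + 1,
                     condition = "NT"),
  make_dose_response(5, 62, 96, noise_sd = 2, seed = MASTER_SEED + 2,
                     condition = "HT", efficacy = 0.6),
  make_dose_response(5, 64, 96, noise_sd = 2, seed = MASTER_SEED + 3,
                     condition = "NT", treatment = "l-NAME",
                     efficacy = 0.4)
)
readr::write_csv(dose_response_table(records),
                 file.path(results_dir(), "dose_response.csv"))
cat("Wrote", length(records), "vessels of dose-response data\n")
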
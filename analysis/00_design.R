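# Shared study design for the analysis scripts: a two-arm (NT vs HT)
# coronary-type cohort at week 8 whose only preset difference is a 1.56x
# thicker media in the HT arm, plus per-class composition presets.
# Sourced by the numbered drivers; nothing here runs an analysis.

library(arterymorph)

MASTER_SEED <- 20260401

cohort_design <- function() {
  pre_nt <- phantom_preset("muscular_two_lamellae")
  pre_ht <- phantom_preset("muscular_two_lamellae",
                           layer_thicknesses_um = c(5, 30 * 1.56, 15))
  study_design(
    data.frame(condition = c("NT", "HT"), week = 8, n_animals = 5),
    list(NT_8 = pre_nt, HT_8 = pre_ht),
    master_seed = MASTER_SEED)
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}
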
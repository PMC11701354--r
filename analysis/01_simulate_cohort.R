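#!/usr/bin/env Rscript
# Step 1 — simulate the waiting-list cohort.
#
# Draws a synthetic orthopaedic waiting-list cohort of 1025 patients whose
# stage-pass prevalences match the evaluated triage pathway (90/1025 stage-1
# positive, 20/90 passing clinical review, 8/20 referred), and writes the
# patient table and latent labels for the downstream steps.

suppressPackageStartupMessages(library(scstriage))

seed <- 20260921L
dir.create("results", showWarnings = FALSE)

cfg <- cohort_config(seed = seed)  # n = 1025, funnel defaults
cohort <- generate_cohort(cfg)

write_patients_csv(cohort$patients, "results/patients.csv")
lab <- cohort$labels
for (cl in c("stage1_qualifying", "stage2_pass", "referred")) {
  lab[[cl]] <- ifelse(lab[[cl]], "true", "false")
}
utils::write.csv(lab, "results/labels.csv", row.names = FALSE, quote = FALSE)

cat(sprintf("simulated %d patients (seed %d): %d stage-1 qualifying, %d stage-2, %d referred\n",
            nrow(cohort$patients), seed, sum(cohort$labels$stage1_qualifying),
            sum(cohort$labels$stage2_pass), sum(cohort$labels$referred)))
cat("wrote results/patients.csv, results/labels.csv\n")
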
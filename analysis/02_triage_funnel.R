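#!/usr/bin/env Rscript
# Step 2 — apply the stage-1 rule and tabulate the two-stage funnel.
#
# Reads the simulated cohort from step 1, evaluates the 6-including /
# 7-excluding indicator rule for every patient, and follows stage-1
# positives through the latent clinical-review and referral gates.

suppressPackageStartupMessages(library(scstriage))

patients <- read_patients_csv("results/patients.csv")
labels <- utils::read.csv("results/labels.csv", stringsAsFactors = FALSE)
labels$stage2_pass <- labels$stage2_pass == "true"
labels$referred <- labels$referred == "true"

funnel <- run_funnel(patients, labels)
print(funnel)

write_decisions_csv(funnel$decisions, "results/decisions.csv")
utils::write.csv(data.frame(stage = names(funnel$counts), count = funnel$counts),
                 "results/funnel_counts.csv", row.names = FALSE, quote = FALSE)
utils::write.csv(as.data.frame(table(pathway = funnel$pathway)),
                 "results/pathways.csv", row.names = FALSE, quote = FALSE)
cat("wrote results/decisions.csv, results/funnel_counts.csv, results/pathways.csv\n")
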
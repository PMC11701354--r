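#!/usr/bin/env Rscript
# Step 6 — consolidated evaluation report.
#
# Runs the whole battery through the pipeline in one deterministic pass
# (same seed as the stepwise scripts) and writes the consolidated JSON
# report, per-patient decisions, and a human-readable summary.

suppressPackageStartupMessages(library(scstriage))

seed <- 20260921L
cfg <- run_config("synthetic", seed = seed,
                  cohort = cohort_config(seed = seed))
report <- run_evaluation(cfg)
print(report)
write_evaluation_report(report, "results/full_report")
cat("wrote results/full_report/{report.json,decisions.csv,summary.txt}\n")
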
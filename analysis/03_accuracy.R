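#!/usr/bin/env Rscript
# Step 3 — diagnostic accuracy of the triage indication.
#
# Two tables: (a) the synthetic cohort's stage-2 triage indication vs its
# latent referral decision; (b) the reported worked example (tp=8, fp=12,
# fn=0, tn=1005), whose point estimates are Se 100%, Sp 98.8%, PPV 40%,
# NPV 100%, with the 3/n rule-of-three lower bound 99.7% for the NPV.

suppressPackageStartupMessages(library(scstriage))

patients <- read_patients_csv("results/patients.csv")
labels <- utils::read.csv("results/labels.csv", stringsAsFactors = FALSE)
labels$stage2_pass <- labels$stage2_pass == "true"
labels$referred <- labels$referred == "true"

funnel <- run_funnel(patients, labels)
indicated <- funnel$pathway %in% c("fast_track", "referred")
syn <- accuracy_metrics(build_table(indicated, labels$referred))
cat("synthetic cohort:\n"); print(syn)

ex <- reference_worked_example()
cat("\nreported worked example:\n"); print(ex$accuracy)
cat(sprintf("NPV rule-of-three interval: %.4f-%.4f\n",
            ex$npv_rule_of_three[["lower"]], ex$npv_rule_of_three[["upper"]]))

both <- rbind(cbind(source = "synthetic", as.data.frame(syn)),
              cbind(source = "reported", as.data.frame(ex$accuracy)))
utils::write.csv(both, "results/accuracy.csv", row.names = FALSE, quote = FALSE)
cat("wrote results/accuracy.csv\n")
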
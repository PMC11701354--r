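#!/usr/bin/env Rscript
# Step 4 — inter- and intra-rater reliability on a 50-patient subsample.
#
# Four simulated clinicians rate a stratified 50-patient subsample of the
# cohort; the first rater rates it twice for test-retest reliability.
# Reported: Fleiss' kappa, the pairwise Cohen's kappa matrix with the
# >= 0.70 reliability verdict, and overall/positive/negative agreement
# pooled as the mean over the six rater pairs.

suppressPackageStartupMessages(library(scstriage))

seed <- 20260921L
labels <- utils::read.csv("results/labels.csv", stringsAsFactors = FALSE)
qualifying <- labels$stage1_qualifying == "true"

sub <- scstriage:::rating_subsample(qualifying, 50L, seed + 1L)
raters <- default_raters()
ratings <- simulate_ratings(qualifying[sub], raters, seed + 2L,
                            subject_ids = labels$patient_id[sub])
rep <- agreement_report(ratings)
print(rep)

retest <- simulate_ratings(qualifying[sub], raters[1], seed + 3L)
intra <- intra_rater(ratings[, 1], retest[, 1])
cat(sprintf("intra-rater (test-retest, %s): kappa %.2f, overall agreement %.0f%%\n",
            raters[[1]]$rater_id, intra$kappa, 100 * intra$agreement[["overall"]]))

write_ratings_csv(ratings, "results/ratings.csv")
utils::write.csv(rep$pairwise, "results/agreement_pairwise.csv",
                 row.names = FALSE, quote = FALSE)
jsonlite::write_json(list(fleiss_kappa = rep$fleiss_kappa,
                          pooled_agreement = as.list(rep$pooled_agreement),
                          intra_rater = list(kappa = intra$kappa,
                                             agreement = as.list(intra$agreement))),
                     "results/agreement.json", auto_unbox = TRUE, digits = NA,
                     pretty = TRUE)
cat("wrote results/ratings.csv, results/agreement_pairwise.csv, results/agreement.json\n")
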
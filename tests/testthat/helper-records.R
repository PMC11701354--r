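# Shared fixtures and independent oracles, built in code at test time.

# A record meeting every including indicator with no exclusions.
make_record <- function(...) {
  rec <- list(patient_id = "p1",
              prior_back_surgery = TRUE,
              pain_location = "mixed",
              dn4_score = 5L,
              pain_duration_months = 24,
              nprs_leg = 7L,
              nprs_back = 6L,
              age_years = 55,
              absolute_contraindication = FALSE,
              widespread_pain = FALSE,
              substance_abuse = FALSE,
              responded_conservative = FALSE,
              prior_scs = FALSE,
              anatomic_abnormality = FALSE)
  mods <- list(...)
  rec[names(mods)] <- mods
  rec
}

# Random patient table spanning the full field ranges (no missing values).
random_patients <- function(n, seed) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("r%05d", seq_len(n)),
    prior_back_surgery = sample(c(TRUE, FALSE), n, replace = TRUE),
    pain_location = sample(c("back", "leg", "mixed"), n, replace = TRUE),
    dn4_score = sample(0:10, n, replace = TRUE),
    pain_duration_months = round(runif(n, 0, 120), 1),
    nprs_leg = sample(0:10, n, replace = TRUE),
    nprs_back = sample(0:10, n, replace = TRUE),
    age_years = round(runif(n, 10, 90), 1),
    absolute_contraindication = runif(n) < 0.2,
    widespread_pain = runif(n) < 0.2,
    substance_abuse = runif(n) < 0.2,
    responded_conservative = runif(n) < 0.3,
    prior_scs = runif(n) < 0.1,
    anatomic_abnormality = runif(n) < 0.2,
    stringsAsFactors = FALSE)
}

# Independent stage-1 oracle: direct field comparisons, no rule machinery.
brute_force_stage1 <- function(df) {
  with(df,
    prior_back_surgery &
    pain_location %in% c("leg", "mixed") &
    !is.na(dn4_score) & dn4_score > 3 &
    pain_duration_months >= 3 &
    nprs_leg >= nprs_back &
    nprs_leg >= 5 &
    !absolute_contraindication & !widespread_pain & !substance_abuse &
    !responded_conservative & !prior_scs & !anatomic_abnormality &
    age_years > 18)
}

# Independent Cohen's kappa oracle: integer cross-tabulation arithmetic.
oracle_cohen_kappa <- function(x, y) {
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  n <- a + b + c_ + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  (po - pe) / (1 - pe)
}

# Scott's pi: pooled marginals over the two raters.
oracle_scott_pi <- function(x, y) {
  n <- length(x)
  po <- mean(x == y)
  p <- (sum(x) + sum(y)) / (2 * n)
  pe <- p^2 + (1 - p)^2
  (po - pe) / (1 - pe)
}

# Closed-form expected Cohen's kappa for two conditionally independent
# raters with sensitivities s and specificities sp against a latent label
# with prevalence pi.
expected_cohen_kappa <- function(pi, s1, sp1, s2, sp2) {
  p11 <- pi * s1 * s2 + (1 - pi) * (1 - sp1) * (1 - sp2)
  p00 <- pi * (1 - s1) * (1 - s2) + (1 - pi) * sp1 * sp2
  m1 <- pi * s1 + (1 - pi) * (1 - sp1)
  m2 <- pi * s2 + (1 - pi) * (1 - sp2)
  po <- p11 + p00
  pe <- m1 * m2 + (1 - m1) * (1 - m2)
  (po - pe) / (1 - pe)
}

# Closed-form expected Fleiss' kappa for r identical conditionally
# independent raters (per-subject positive-call probability s for latent
# positives, 1 - sp for latent negatives).
expected_fleiss_kappa <- function(pi, s, sp) {
  po <- pi * (s^2 + (1 - s)^2) + (1 - pi) * (sp^2 + (1 - sp)^2)
  p1 <- pi * s + (1 - pi) * (1 - sp)
  pe <- p1^2 + (1 - p1)^2
  (po - pe) / (1 - pe)
}
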
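# Synthetic cohort, rater, and usability-response generators.
#
# The generator emulates a heterogeneous orthopaedic waiting-list population
# with a configurable fraction of stage-1-qualifying patients, plus latent
# Bernoulli gates for the clinical-review and referral stages, so the default
# configuration reproduces the two-stage funnel prevalences
# 1025 -> 90 -> 20 -> 8 in expectation.

#' Marginal distributions for synthetic patient fields
#'
#' Parameters of the per-field distributions used by [generate_cohort()],
#' split by latent qualifying status where the rule constrains a field.
#' No PROM correlation structure beyond what the funnel requires is modelled.
#'
#' @param p_prior_surgery probability of prior back surgery among
#'   non-qualifying patients.
#' @param p_location category probabilities (back/leg/mixed) for
#'   non-qualifying patients.
#' @param dn4_p_qualifying,dn4_p_other success probability of the
#'   binomial(10, p) DN4 draw by qualifying status (qualifying draws are
#'   truncated to > 3 to respect the rule).
#' @param duration_meanlog,duration_sdlog log-normal pain duration in months
#'   (default median 24 months).
#' @param age_mean,age_sd normal age in years, truncated to the adult range
#'   for qualifying patients.
#' @param p_exclusion per-flag probabilities of the seven exclusion features
#'   among non-qualifying patients.
#' @return named list of marginal parameters.
#' @export
cohort_marginals <- function(p_prior_surgery = 0.40,
                             p_location = c(back = 0.45, leg = 0.25, mixed = 0.30),
                             dn4_p_qualifying = 0.65, dn4_p_other = 0.30,
                             duration_meanlog = log(24), duration_sdlog = 0.8,
                             age_mean = 55, age_sd = 13,
                             p_exclusion = c(absolute_contraindication = 0.03,
                                             widespread_pain = 0.10,
                                             substance_abuse = 0.04,
                                             responded_conservative = 0.30,
                                             prior_scs = 0.02,
                                             anatomic_abnormality = 0.08,
                                             age_le_18 = 0.01)) {
  for (p in c(p_prior_surgery, p_location, dn4_p_qualifying, dn4_p_other,
              p_exclusion)) check_prob(p, "marginal probability")
  list(p_prior_surgery = p_prior_surgery, p_location = p_location,
       dn4_p_qualifying = dn4_p_qualifying, dn4_p_other = dn4_p_other,
       duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
       age_mean = age_mean, age_sd = age_sd, p_exclusion = p_exclusion)
}

#' Configuration for the synthetic cohort generator
#'
#' The three stage probabilities default to the observed funnel proportions
#' of the evaluated triage pathway: 90 of 1025 assessed patients stage-1
#' positive, 20 of those 90 passing the orthopaedic review, 8 of those 20
#' referred to the chronic-pain department.
#'
#' @param n_patients cohort size (default 1025).
#' @param p_stage1_positive probability a patient satisfies the full stage-1
#'   rule (default 90/1025).
#' @param p_stage2_pass_given_stage1 conditional stage-2 pass probability
#'   (default 20/90).
#' @param p_referral_given_stage2 conditional referral probability
#'   (default 8/20).
#' @param dn4_missing_rate missing-completely-at-random rate for the DN4
#'   score (default 0, so accuracy analyses are unaffected by missingness).
#' @param marginals per-field distribution parameters, see
#'   [cohort_marginals()].
#' @param seed mandatory RNG seed; identical seed gives identical cohorts.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 1025,
                          p_stage1_positive = 90 / 1025,
                          p_stage2_pass_given_stage1 = 20 / 90,
                          p_referral_given_stage2 = 8 / 20,
                          dn4_missing_rate = 0,
                          marginals = cohort_marginals(),
                          seed) {
  if (missing(seed)) stop("`seed` is mandatory in cohort_config()", call. = FALSE)
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      n_patients < 0 || n_patients != floor(n_patients)) {
    stop("`n_patients` must be a non-negative integer", call. = FALSE)
  }
  check_prob(p_stage1_positive, "p_stage1_positive")
  check_prob(p_stage2_pass_given_stage1, "p_stage2_pass_given_stage1")
  check_prob(p_referral_given_stage2, "p_referral_given_stage2")
  check_prob(dn4_missing_rate, "dn4_missing_rate")
  structure(list(n_patients = as.integer(n_patients),
                 p_stage1_positive = p_stage1_positive,
                 p_stage2_pass_given_stage1 = p_stage2_pass_given_stage1,
                 p_referral_given_stage2 = p_referral_given_stage2,
                 dn4_missing_rate = dn4_missing_rate,
                 marginals = marginals, seed = as.integer(seed)),
            class = "cohort_config")
}

# Binomial(10, p) truncated to > 3, vectorised resampling.
rbinom_dn4_gt3 <- function(n, p) {
  x <- stats::rbinom(n, 10, p)
  while (any(bad <- x <= 3)) x[bad] <- stats::rbinom(sum(bad), 10, p)
  x
}

#' Generate a synthetic waiting-list cohort with latent labels
#'
#' Draws each patient's latent stage-1 qualifying status as
#' Bernoulli(`p_stage1_positive`), then fills the record so that qualifying
#' patients satisfy every including indicator and carry no exclusion, while
#' non-qualifying patients fail at least one indicator (draws that would
#' qualify by chance have one randomly chosen indicator violated). Latent
#' stage-2 and referral outcomes are nested Bernoulli gates, so the funnel
#' is monotone in every realisation.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with `patients` (data.frame, one
#'   row per patient) and `labels` (data.frame: `patient_id`,
#'   `stage1_qualifying`, `stage2_pass`, `referred`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  m <- config$marginals
  if (n == 0L) {
    empty <- data.frame(patient_id = character(0))
    for (f in names(.field_registry)) empty[[f]] <- logical(0)
    return(structure(list(
      patients = empty,
      labels = data.frame(patient_id = character(0),
                          stage1_qualifying = logical(0),
                          stage2_pass = logical(0), referred = logical(0))),
      class = "synthetic_cohort"))
  }
  with_seed(config$seed, {
    qual <- stats::rbinom(n, 1, config$p_stage1_positive) == 1L
    nq <- sum(qual)

    prior_surgery <- stats::rbinom(n, 1, m$p_prior_surgery) == 1L
    prior_surgery[qual] <- TRUE
    loc <- sample(names(m$p_location), n, replace = TRUE, prob = m$p_location)
    loc[qual] <- sample(c("leg", "mixed"), nq, replace = TRUE)
    dn4 <- stats::rbinom(n, 10, m$dn4_p_other)
    if (nq) dn4[qual] <- rbinom_dn4_gt3(nq, m$dn4_p_qualifying)
    dur <- stats::rlnorm(n, m$duration_meanlog, m$duration_sdlog)
    dur[qual] <- pmax(dur[qual], 3)
    nprs_leg <- sample(0:10, n, replace = TRUE)
    nprs_back <- sample(0:10, n, replace = TRUE)
    if (nq) {
      nprs_leg[qual] <- sample(5:10, nq, replace = TRUE)
      # back pain uniform on 0..leg so leg >= back holds
      nprs_back[qual] <- floor(stats::runif(nq) * (nprs_leg[qual] + 1))
    }
    age <- stats::rnorm(n, m$age_mean, m$age_sd)
    age <- pmin(pmax(age, 16), 95)
    age[qual] <- pmin(pmax(age[qual], 19), 95)

    flags <- c("absolute_contraindication", "widespread_pain", "substance_abuse",
               "responded_conservative", "prior_scs", "anatomic_abnormality")
    flagmat <- vapply(flags, function(f)
      stats::rbinom(n, 1, m$p_exclusion[[f]]) == 1L, logical(n))
    flagmat <- matrix(flagmat, nrow = n, dimnames = list(NULL, flags))
    flagmat[qual, ] <- FALSE
    minor <- !qual & stats::runif(n) < m$p_exclusion[["age_le_18"]]
    age[minor] <- stats::runif(sum(minor), 16, 18)

    patients <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n)),
      prior_back_surgery = prior_surgery,
      pain_location = loc,
      dn4_score = as.integer(dn4),
      pain_duration_months = dur,
      nprs_leg = as.integer(nprs_leg),
      nprs_back = as.integer(nprs_back),
      age_years = age,
      stringsAsFactors = FALSE)
    patients <- cbind(patients, as.data.frame(flagmat))

    # Accidental qualifiers among the non-qualifying draws get one randomly
    # chosen including indicator violated, keeping all other fields intact.
    dec <- evaluate_stage1_cohort(patients, default_triage_rule(), "fail")
    fix <- which(!qual & dec$stage1_positive)
    if (length(fix)) {
      how <- sample(4L, length(fix), replace = TRUE)
      for (k in seq_along(fix)) {
        i <- fix[k]
        switch(how[k],
          patients$nprs_leg[i] <- sample(0:4, 1),
          patients$dn4_score[i] <- sample(0:3, 1),
          patients$pain_location[i] <- "back",
          patients$prior_back_surgery[i] <- FALSE)
      }
    }
    if (config$dn4_missing_rate > 0) {
      patients$dn4_score[stats::runif(n) < config$dn4_missing_rate] <- NA_integer_
    }

    s2 <- qual & stats::rbinom(n, 1, config$p_stage2_pass_given_stage1) == 1L
    rf <- s2 & stats::rbinom(n, 1, config$p_referral_given_stage2) == 1L
    labels <- data.frame(patient_id = patients$patient_id,
                         stage1_qualifying = qual, stage2_pass = s2,
                         referred = rf, stringsAsFactors = FALSE)
    structure(list(patients = patients, labels = labels),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d patients, %d qualifying, %d stage-2, %d referred>\n",
              nrow(x$patients), sum(x$labels$stage1_qualifying),
              sum(x$labels$stage2_pass), sum(x$labels$referred)))
  invisible(x)
}

#' Construct a rater error model
#'
#' A latent-class misclassification model: the rater sees the latent true
#' eligibility label and calls it positive with probability
#' `p_correct_positive` when truly eligible, negative with probability
#' `p_correct_negative` when truly ineligible. Raters' calls are
#' conditionally independent given the latent label.
#'
#' @param rater_id identifier.
#' @param p_correct_positive rater sensitivity against the latent label.
#' @param p_correct_negative rater specificity against the latent label.
#' @return list of class `rater_model`.
#' @export
rater_model <- function(rater_id, p_correct_positive, p_correct_negative) {
  check_prob(p_correct_positive, "p_correct_positive")
  check_prob(p_correct_negative, "p_correct_negative")
  structure(list(rater_id = as.character(rater_id),
                 p_correct_positive = p_correct_positive,
                 p_correct_negative = p_correct_negative),
            class = "rater_model")
}

#' Simulate rater calls on subjects with latent labels
#'
#' @param latent_labels logical (or 0/1) vector of true eligibility, one per
#'   subject.
#' @param raters list of [rater_model()] objects (at least one).
#' @param seed mandatory RNG seed.
#' @param subject_ids optional subject identifiers (default S1..Sn).
#' @return integer matrix (subjects x raters) of 0/1 calls with dimnames;
#'   class `rating_matrix`, latent labels attached as attribute `"latent"`.
#' @export
simulate_ratings <- function(latent_labels, raters, seed, subject_ids = NULL) {
  if (length(raters) == 0L) stop("need at least one rater", call. = FALSE)
  if (length(latent_labels) == 0L) stop("need at least one subject", call. = FALSE)
  stopifnot(all(vapply(raters, inherits, logical(1), "rater_model")))
  lab <- as_binary(latent_labels, "latent_labels")
  n <- length(lab)
  ids <- subject_ids %||% sprintf("S%04d", seq_len(n))
  with_seed(seed, {
    calls <- vapply(raters, function(r) {
      p_pos <- ifelse(lab == 1L, r$p_correct_positive, 1 - r$p_correct_negative)
      stats::rbinom(n, 1, p_pos)
    }, integer(n))
    calls <- matrix(as.integer(calls), nrow = n,
                    dimnames = list(ids, vapply(raters, `[[`, character(1), "rater_id")))
    structure(calls, latent = lab, class = c("rating_matrix", class(calls)))
  })
}

#' Generate Likert responses with prescribed item means
#'
#' Builds an n-respondent set of 10-item responses (integers 1-5) whose
#' per-item sample means match the requested targets to within the closest
#' value achievable with integer responses. A target is achievable when the
#' nearest integer total differs from `n * target` by at most
#' `mean_tol * n`; the default tolerance of 0.005 on the mean corresponds to
#' targets printed to two decimals.
#'
#' @param n_respondents number of respondents (>= 1).
#' @param item_means numeric vector of 10 target means, each in `[1, 5]`.
#' @param seed mandatory RNG seed (controls which respondents get the
#'   remainder and the within-item spread; totals are deterministic).
#' @param mean_tol maximum allowed |achieved mean - target| (default 0.005).
#' @param spread number of seeded sum-preserving +1/-1 perturbation passes,
#'   giving between-respondent variance without moving any item mean.
#' @return integer matrix (respondents x 10) of class `sus_response_set`.
#' @export
generate_sus_responses <- function(n_respondents, item_means, seed,
                                   mean_tol = 0.005, spread = 2L) {
  if (n_respondents < 1L) stop("need at least one respondent", call. = FALSE)
  if (length(item_means) != 10L) stop("`item_means` must have length 10", call. = FALSE)
  if (any(item_means < 1 | item_means > 5)) {
    stop(sprintf("item mean target(s) outside [1, 5] for item(s): %s",
                 paste(which(item_means < 1 | item_means > 5), collapse = ", ")),
         call. = FALSE)
  }
  n <- as.integer(n_respondents)
  totals <- round(item_means * n)
  err <- abs(totals / n - item_means)
  if (any(bad <- err > mean_tol + 1e-12)) {
    stop(sprintf(paste0("target mean not achievable with %d respondents for ",
                        "item(s) %s (closest achievable mean off by %s)"),
                 n, paste(which(bad), collapse = ", "),
                 paste(format(signif(err[bad], 3)), collapse = ", ")),
         call. = FALSE)
  }
  with_seed(seed, {
    resp <- matrix(0L, nrow = n, ncol = 10L,
                   dimnames = list(sprintf("R%02d", seq_len(n)), paste0("item_", 1:10)))
    for (j in 1:10) {
      q <- totals[j] %/% n
      r <- totals[j] %% n
      col <- rep(q, n)
      if (r > 0) col[sample(n, r)] <- q + 1L
      if (spread > 0 && n > 1) {
        for (pass in seq_len(spread)) {
          i <- sample(n, 2L)
          if (col[i[1]] < 5L && col[i[2]] > 1L) {
            col[i[1]] <- col[i[1]] + 1L
            col[i[2]] <- col[i[2]] - 1L
          }
        }
      }
      resp[, j] <- as.integer(col)
    }
    structure(resp, class = c("sus_response_set", class(resp)))
  })
}
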
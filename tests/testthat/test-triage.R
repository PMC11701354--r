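test_that("the default rule has the printed indicator structure", {
  rule <- default_triage_rule()
  expect_s3_class(rule, "triage_rule")
  expect_equal(sum(rule$roles == "including"), 6)
  expect_equal(sum(rule$roles == "excluding"), 7)
  alt <- default_triage_rule("abstract_5")
  expect_equal(sum(alt$roles == "including"), 5)
  expect_false("prior_back_surgery" %in% alt$names)
})

test_that("a record meeting every indicative outcome is stage-1 positive", {
  dec <- evaluate_stage1(make_record())
  expect_true(dec$stage1_positive)
  expect_true(all(dec$satisfaction))
  expect_false(dec$needs_manual_review)
  expect_length(dec$missing_fields, 0)
})

test_that("single indicator failures and exclusion vetoes flip the decision", {
  # nprs_back lowered alongside so only the NPRS-leg threshold fails
  dec <- evaluate_stage1(make_record(nprs_leg = 4L, nprs_back = 4L))
  expect_false(dec$stage1_positive)
  expect_equal(names(which(!dec$satisfaction)), "nprs_leg")

  dec <- evaluate_stage1(make_record(widespread_pain = TRUE))
  expect_false(dec$stage1_positive)
  expect_equal(names(which(!dec$satisfaction)), "widespread_pain")

  dec <- evaluate_stage1(make_record(age_years = 17))
  expect_false(dec$stage1_positive)
  expect_equal(names(which(!dec$satisfaction)), "age_le_18")
})

test_that("exactly one of the 2^13 satisfy/violate patterns is positive", {
  rule <- default_triage_rule()
  k <- 13
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), k))
  names(grid) <- rule$names
  # realise each pattern field by field; the two nprs indicators share
  # fields, so their joint pattern picks a consistent (leg, back) pair
  nprs_pairs <- list(`TRUE.TRUE` = c(7L, 5L), `TRUE.FALSE` = c(4L, 3L),
                     `FALSE.TRUE` = c(5L, 7L), `FALSE.FALSE` = c(3L, 6L))
  pats <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    np <- nprs_pairs[[paste(g$leg_ge_back, g$nprs_leg, sep = ".")]]
    data.frame(patient_id = paste0("t", i),
               prior_back_surgery = g$prior_back_surgery,
               pain_location = if (g$pain_location) "leg" else "back",
               dn4_score = if (g$neuropathic_pain) 5L else 2L,
               pain_duration_months = if (g$pain_duration) 24 else 1,
               nprs_leg = np[1], nprs_back = np[2],
               age_years = if (g$age_le_18) 55 else 17,
               absolute_contraindication = !g$absolute_contraindication,
               widespread_pain = !g$widespread_pain,
               substance_abuse = !g$substance_abuse,
               responded_conservative = !g$responded_conservative,
               prior_scs = !g$prior_scs,
               anatomic_abnormality = !g$anatomic_abnormality,
               stringsAsFactors = FALSE)
  }))
  dec <- evaluate_stage1_cohort(pats, rule)
  expected_positive <- apply(as.matrix(grid), 1, all)
  expect_equal(dec$stage1_positive, unname(expected_positive))
  expect_equal(sum(dec$stage1_positive), 1L)
  # the satisfaction vector reproduces every requested pattern exactly
  sat <- as.matrix(dec[, paste0("ind_", rule$names)])
  expect_equal(unname(sat), unname(as.matrix(grid)))
})

test_that("rule engine agrees with brute-force re-evaluation on random records", {
  pats <- random_patients(10000, seed = 101)
  dec <- evaluate_stage1_cohort(pats, default_triage_rule())
  expect_equal(dec$stage1_positive, brute_force_stage1(pats))
})

test_that("threshold boundaries are as printed: DN4 strict, others inclusive", {
  expect_true(evaluate_stage1(make_record(dn4_score = 4L))$stage1_positive)
  expect_false(evaluate_stage1(make_record(dn4_score = 3L))$stage1_positive)
  expect_true(evaluate_stage1(make_record(pain_duration_months = 3.0))$stage1_positive)
  expect_false(evaluate_stage1(make_record(pain_duration_months = 2.9))$stage1_positive)
  expect_true(evaluate_stage1(make_record(nprs_leg = 5L, nprs_back = 5L))$stage1_positive)
  expect_true(evaluate_stage1(make_record(nprs_leg = 6L, nprs_back = 6L))$stage1_positive)
  # age exactly 18 is excluded (<= 18), 19 is not
  expect_false(evaluate_stage1(make_record(age_years = 18))$stage1_positive)
  expect_true(evaluate_stage1(make_record(age_years = 19))$stage1_positive)

  bnd <- evaluate_boundaries()
  expect_equal(bnd$minimal_satisfying[bnd$indicator == "neuropathic_pain"], "4")
  expect_equal(bnd$minimal_satisfying[bnd$indicator == "pain_duration"], "3")
  expect_equal(bnd$minimal_satisfying[bnd$indicator == "nprs_leg"], "5")
  expect_match(bnd$minimal_satisfying[bnd$indicator == "leg_ge_back"], "equality")
})

test_that("missing DN4 is negative, flagged for review only under review policy", {
  rec <- make_record(dn4_score = NA_integer_)
  dec <- evaluate_stage1(rec, missing_policy = "review")
  expect_false(dec$stage1_positive)
  expect_true(dec$needs_manual_review)
  expect_equal(dec$missing_fields, "dn4_score")
  expect_true(is.na(dec$satisfaction[["neuropathic_pain"]]))

  dec <- evaluate_stage1(rec, missing_policy = "fail")
  expect_false(dec$stage1_positive)
  expect_false(dec$needs_manual_review)

  # a record that also fails a present indicator is not a review case
  dec <- evaluate_stage1(make_record(dn4_score = NA_integer_, nprs_leg = 2L,
                                     nprs_back = 1L))
  expect_false(dec$needs_manual_review)
})

test_that("out-of-range field values raise errors naming the field", {
  expect_error(evaluate_stage1(make_record(nprs_leg = 11L)), "nprs_leg")
  expect_error(evaluate_stage1(make_record(dn4_score = -1L)), "dn4_score")
  expect_error(evaluate_stage1(make_record(pain_location = "arm")), "pain_location")
  expect_error(evaluate_stage1(make_record(pain_duration_months = -2)),
               "pain_duration_months")
})

test_that("removing an excluding indicator never decreases the positive count, adding never increases it", {
  pats <- random_patients(2000, seed = 202)
  rule <- default_triage_rule()
  base_n <- sum(evaluate_stage1_cohort(pats, rule)$stage1_positive)
  for (drop in which(rule$roles == "excluding")) {
    reduced <- triage_rule(rule$indicators[-drop], version = "reduced")
    expect_gte(sum(evaluate_stage1_cohort(pats, reduced)$stage1_positive), base_n)
  }
  extra <- triage_rule(c(rule$indicators,
                         list(indicator("severe_leg_pain", "including",
                                        "nprs_leg", "ge", 8))),
                       version = "extended")
  expect_lte(sum(evaluate_stage1_cohort(pats, extra)$stage1_positive), base_n)
})

test_that("improving one field of a negative record never unsatisfies an unrelated indicator", {
  pats <- random_patients(300, seed = 303)
  rule <- default_triage_rule()
  dec <- evaluate_stage1_cohort(pats, rule)
  sat_cols <- paste0("ind_", rule$names)
  improvements <- list(
    list(field = "dn4_score", value = 10L, ind = "neuropathic_pain"),
    list(field = "pain_duration_months", value = 60, ind = "pain_duration"),
    list(field = "prior_back_surgery", value = TRUE, ind = "prior_back_surgery"),
    list(field = "widespread_pain", value = FALSE, ind = "widespread_pain"),
    list(field = "age_years", value = 50, ind = "age_le_18"))
  for (imp in improvements) {
    mod <- pats
    mod[[imp$field]] <- imp$value
    dec2 <- evaluate_stage1_cohort(mod, rule)
    other <- setdiff(sat_cols, paste0("ind_", imp$ind))
    expect_equal(dec2[, other], dec[, other])
    expect_true(all(dec2[[paste0("ind_", imp$ind)]]))
  }
})

test_that("rules round-trip through YAML and the shipped profiles load", {
  rule <- default_triage_rule()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rule_yaml(rule, path)
  rt <- read_rule_yaml(path)
  pats <- random_patients(500, seed = 404)
  expect_equal(evaluate_stage1_cohort(pats, rt), evaluate_stage1_cohort(pats, rule))

  shipped <- read_rule_yaml(system.file("extdata", "rule_table1.yaml",
                                        package = "scstriage"))
  expect_equal(evaluate_stage1_cohort(pats, shipped)$stage1_positive,
               brute_force_stage1(pats))
  expect_error(read_rule_yaml(withr::local_tempfile(lines = "version: empty",
                                                    fileext = ".yaml")),
               "no indicators")
})

test_that("the funnel nests its stages and handles degenerate cohorts", {
  # nobody qualifies
  pats <- random_patients(50, seed = 505)
  pats$prior_back_surgery <- FALSE
  labels <- data.frame(patient_id = pats$patient_id, stage2_pass = TRUE,
                       referred = TRUE)
  f <- run_funnel(pats, labels)
  expect_equal(unname(f$counts), c(50, 0, 0, 0))

  # one qualifying patient passing every latent gate
  one <- as.data.frame(make_record(), stringsAsFactors = FALSE)
  f1 <- run_funnel(one, data.frame(patient_id = "p1", stage2_pass = TRUE,
                                   referred = TRUE))
  expect_equal(unname(f1$counts), c(1, 1, 1, 1))
  expect_equal(as.character(f1$pathway), "referred")

  expect_error(run_funnel(pats[0, ], labels), "empty")
  expect_error(run_funnel(pats, labels[-1, ]), "missing")
  expect_error(run_funnel(pats, NULL), "labels")
})
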
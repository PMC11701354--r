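# Stage-1 triage rule engine and two-stage funnel bookkeeping.
#
# The rule is a pure conjunction: a patient is stage-1 positive iff every
# including indicator is present AND every excluding indicator is absent.
# Indicators are declarative predicates over patient-record fields, so the
# default rule ships as data (a YAML file in inst/extdata) rather than code.

# Registry of patient-record fields the rule engine may reference: scale
# type and admissible range. Used for input validation and for boundary
# reports on numeric indicators.
.field_registry <- list(
  prior_back_surgery       = list(type = "logical"),
  pain_location            = list(type = "categorical", levels = c("back", "leg", "mixed")),
  dn4_score                = list(type = "integer", min = 0, max = 10, optional = TRUE),
  pain_duration_months     = list(type = "numeric", min = 0, max = Inf),
  nprs_leg                 = list(type = "integer", min = 0, max = 10),
  nprs_back                = list(type = "integer", min = 0, max = 10),
  age_years                = list(type = "numeric", min = 0, max = Inf),
  absolute_contraindication = list(type = "logical"),
  widespread_pain          = list(type = "logical"),
  substance_abuse          = list(type = "logical"),
  responded_conservative   = list(type = "logical"),
  prior_scs                = list(type = "logical"),
  anatomic_abnormality     = list(type = "logical")
)

#' Construct a triage indicator
#'
#' An indicator is a named predicate over one patient-record field (two for
#' the `ge_field` comparator, which compares two fields). Its `role` decides
#' how the predicate enters the conjunction: an *including* indicator must be
#' present (predicate true), an *excluding* indicator must be absent
#' (predicate false).
#'
#' @param name short identifier for the indicator.
#' @param role `"including"` or `"excluding"`.
#' @param field patient-record field the predicate reads.
#' @param comparator one of `"ge"`, `"gt"`, `"le"`, `"eq"`, `"in"`,
#'   `"ge_field"`. For `"ge_field"` the `threshold` names the second field.
#' @param threshold numeric threshold, logical value, category set, or (for
#'   `ge_field`) the name of the field on the right-hand side.
#' @param label human-readable description, e.g. `"DN4 > 3"`.
#' @return an object of class `triage_indicator`.
#' @export
indicator <- function(name, role = c("including", "excluding"),
                      field, comparator, threshold = NULL, label = name) {
  role <- match.arg(role)
  if (!field %in% names(.field_registry)) {
    stop(sprintf("unknown patient field '%s' in indicator '%s'", field, name),
         call. = FALSE)
  }
  comparator <- match.arg(comparator, c("ge", "gt", "le", "eq", "in", "ge_field"))
  reg <- .field_registry[[field]]
  if (comparator %in% c("ge", "gt", "le") && reg$type %in% c("integer", "numeric")) {
    if (!is.numeric(threshold) || threshold < reg$min || threshold > reg$max) {
      stop(sprintf("threshold %s outside the scale of field '%s'",
                   format(threshold), field), call. = FALSE)
    }
  }
  if (comparator == "ge_field" && !threshold %in% names(.field_registry)) {
    stop(sprintf("ge_field comparator needs a field name, got '%s'", threshold),
         call. = FALSE)
  }
  structure(list(name = name, role = role, field = field,
                 comparator = comparator, threshold = threshold, label = label),
            class = "triage_indicator")
}

#' Construct a triage rule from indicators
#'
#' @param indicators list of [indicator()] objects.
#' @param version rule version tag.
#' @return an object of class `triage_rule`.
#' @export
triage_rule <- function(indicators, version = "custom") {
  stopifnot(length(indicators) >= 1,
            all(vapply(indicators, inherits, logical(1), "triage_indicator")))
  nm <- vapply(indicators, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("indicator names must be unique", call. = FALSE)
  structure(list(indicators = indicators, version = version,
                 names = nm,
                 roles = vapply(indicators, `[[`, character(1), "role")),
            class = "triage_rule")
}

#' @export
print.triage_rule <- function(x, ...) {
  cat(sprintf("<triage_rule '%s': %d including, %d excluding>\n", x$version,
              sum(x$roles == "including"), sum(x$roles == "excluding")))
  for (ind in x$indicators) {
    cat(sprintf("  [%-9s] %-22s %s\n", ind$role, ind$name, ind$label))
  }
  invisible(x)
}

#' The default triage rule profiles
#'
#' `"table1"` is the full rule: six including indicators (prior back surgery,
#' leg or mixed pain location, DN4 > 3, pain duration >= 3 months, leg pain
#' >= back pain, NPRS leg >= 5) and seven excluding indicators (absolute
#' contraindications, widespread pain, alcohol/drug abuse, response to
#' conservative PRF/TENS/medication, prior SCS treatment, anatomic
#' abnormalities, age <= 18 years). `"abstract_5"` is an alternative profile
#' that drops the prior-back-surgery requirement; both circulate in practice
#' and the discrepancy is surfaced rather than resolved here.
#'
#' @param profile `"table1"` (default, 6 + 7 indicators) or `"abstract_5"`.
#' @return a [triage_rule()].
#' @export
default_triage_rule <- function(profile = c("table1", "abstract_5")) {
  profile <- match.arg(profile)
  inc <- list(
    indicator("prior_back_surgery", "including", "prior_back_surgery",
              "eq", TRUE, "Prior back surgery: yes"),
    indicator("pain_location", "including", "pain_location",
              "in", c("leg", "mixed"), "Pain location: leg/mixed"),
    indicator("neuropathic_pain", "including", "dn4_score",
              "gt", 3, "Neuropathic pain: DN4 > 3"),
    indicator("pain_duration", "including", "pain_duration_months",
              "ge", 3, "Pain duration >= 3 months"),
    indicator("leg_ge_back", "including", "nprs_leg",
              "ge_field", "nprs_back", "Leg pain >= back pain"),
    indicator("nprs_leg", "including", "nprs_leg",
              "ge", 5, "NPRS leg >= 5")
  )
  if (profile == "abstract_5") inc <- inc[-1]
  exc <- list(
    indicator("absolute_contraindication", "excluding", "absolute_contraindication",
              "eq", TRUE, "Absolute contraindications"),
    indicator("widespread_pain", "excluding", "widespread_pain",
              "eq", TRUE, "Widespread pain"),
    indicator("substance_abuse", "excluding", "substance_abuse",
              "eq", TRUE, "Alcohol/drugs abuse"),
    indicator("responded_conservative", "excluding", "responded_conservative",
              "eq", TRUE, "Response to PRF/TENS/medication"),
    indicator("prior_scs", "excluding", "prior_scs",
              "eq", TRUE, "Prior SCS treatment"),
    indicator("anatomic_abnormality", "excluding", "anatomic_abnormality",
              "eq", TRUE, "Anatomic abnormalities"),
    indicator("age_le_18", "excluding", "age_years",
              "le", 18, "Age <= 18 years")
  )
  triage_rule(c(inc, exc), version = profile)
}

# Evaluate one indicator's raw predicate over a patient data.frame.
# Returns logical with NA where the referenced field is missing.
indicator_condition <- function(ind, patients) {
  v <- patients[[ind$field]]
  if (is.null(v)) {
    stop(sprintf("patient table lacks field '%s' needed by indicator '%s'",
                 ind$field, ind$name), call. = FALSE)
  }
  switch(ind$comparator,
    ge = v >= ind$threshold,
    gt = v > ind$threshold,
    le = v <= ind$threshold,
    eq = v == ind$threshold,
    `in` = ifelse(is.na(v), NA, v %in% ind$threshold),
    ge_field = v >= patients[[ind$threshold]]
  )
}

# Fields an indicator reads.
indicator_fields <- function(ind) {
  if (ind$comparator == "ge_field") c(ind$field, ind$threshold) else ind$field
}

#' Validate a patient table against the field registry
#'
#' Checks presence, type, and scale range of every rule-relevant field.
#' Only `dn4_score` may be missing.
#'
#' @param patients data.frame of patient records.
#' @return the validated data.frame, invisibly.
#' @export
validate_patients <- function(patients) {
  stopifnot(is.data.frame(patients))
  if (!"patient_id" %in% names(patients)) {
    stop("patient table needs a 'patient_id' column", call. = FALSE)
  }
  if (anyDuplicated(patients$patient_id)) {
    stop("patient_id values must be unique within a cohort", call. = FALSE)
  }
  for (f in names(.field_registry)) {
    reg <- .field_registry[[f]]
    v <- patients[[f]]
    if (is.null(v)) stop(sprintf("patient table lacks field '%s'", f), call. = FALSE)
    if (anyNA(v) && !isTRUE(reg$optional)) {
      stop(sprintf("field '%s' has missing values but may not be missing", f),
           call. = FALSE)
    }
    ok <- switch(reg$type,
      logical = is.logical(v),
      categorical = all(is.na(v) | v %in% reg$levels),
      integer = is.numeric(v) && all(is.na(v) | (v == floor(v) & v >= reg$min & v <= reg$max)),
      numeric = is.numeric(v) && all(is.na(v) | (v >= reg$min & v <= reg$max))
    )
    if (!ok) {
      bad <- v[!is.na(v)]
      bad <- utils::head(bad[!vapply(bad, function(x) {
        switch(reg$type,
          logical = is.logical(x),
          categorical = x %in% reg$levels,
          integer = is.numeric(x) && x == floor(x) && x >= reg$min && x <= reg$max,
          numeric = is.numeric(x) && x >= reg$min && x <= reg$max)
      }, logical(1))], 3)
      stop(sprintf("field '%s' has out-of-range or mistyped value(s): %s",
                   f, paste(format(bad), collapse = ", ")), call. = FALSE)
    }
  }
  invisible(patients)
}

#' Evaluate the stage-1 rule over a cohort
#'
#' Strict conjunction over all indicators: `stage1_positive` is `TRUE` only
#' when every including indicator is present, every excluding indicator is
#' absent, and no referenced field is missing. Every indicator is always
#' evaluated (no short-circuiting), so the per-indicator satisfaction columns
#' are complete for reporting. A record whose only failures are missing
#' fields is negative; under `missing_policy = "review"` it is additionally
#' flagged `needs_manual_review`.
#'
#' @param patients data.frame of patient records (see [validate_patients()]).
#' @param rule a [triage_rule()]; default [default_triage_rule()].
#' @param missing_policy `"review"` (default) or `"fail"`.
#' @return data.frame with one row per patient: `patient_id`,
#'   `stage1_positive`, `needs_manual_review`, `missing_fields`
#'   (comma-separated, `""` if none), and one logical `ind_<name>` column per
#'   indicator (`NA` where the field was missing). Satisfaction means
#'   "contributes to a positive call": the predicate for including
#'   indicators, its negation for excluding ones.
#' @export
evaluate_stage1_cohort <- function(patients, rule = default_triage_rule(),
                                   missing_policy = c("review", "fail")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(rule, "triage_rule"))
  validate_patients(patients)
  n <- nrow(patients)
  sat <- matrix(NA, nrow = n, ncol = length(rule$indicators),
                dimnames = list(NULL, rule$names))
  for (j in seq_along(rule$indicators)) {
    ind <- rule$indicators[[j]]
    cond <- indicator_condition(ind, patients)
    sat[, j] <- if (ind$role == "including") cond else !cond
  }
  any_na <- apply(sat, 1L, anyNA)
  all_true <- apply(sat, 1L, function(r) all(r %in% TRUE))
  non_na_ok <- apply(sat, 1L, function(r) all(r[!is.na(r)]))
  positive <- all_true & !any_na
  review <- missing_policy == "review" & any_na & non_na_ok

  missing_fields <- character(n)
  if (any(any_na)) {
    for (i in which(any_na)) {
      miss <- unique(unlist(lapply(rule$indicators[is.na(sat[i, ])],
                                   indicator_fields)))
      miss <- miss[vapply(miss, function(f) is.na(patients[[f]][i]), logical(1))]
      missing_fields[i] <- paste(miss, collapse = ",")
    }
  }
  out <- data.frame(patient_id = patients$patient_id,
                    stage1_positive = positive,
                    needs_manual_review = review,
                    missing_fields = missing_fields,
                    stringsAsFactors = FALSE)
  satdf <- as.data.frame(sat)
  names(satdf) <- paste0("ind_", rule$names)
  cbind(out, satdf)
}

#' Evaluate the stage-1 rule for a single patient
#'
#' Single-record wrapper around [evaluate_stage1_cohort()].
#'
#' @inheritParams evaluate_stage1_cohort
#' @param record one-row data.frame or named list of patient fields.
#' @return an object of class `triage_decision`: `patient_id`,
#'   `stage1_positive`, named `satisfaction` logical vector, `missing_fields`
#'   character vector, `needs_manual_review`.
#' @examples
#' rec <- list(patient_id = "p1", prior_back_surgery = TRUE,
#'   pain_location = "mixed", dn4_score = 5L, pain_duration_months = 24,
#'   nprs_leg = 7L, nprs_back = 6L, age_years = 55,
#'   absolute_contraindication = FALSE, widespread_pain = FALSE,
#'   substance_abuse = FALSE, responded_conservative = FALSE,
#'   prior_scs = FALSE, anatomic_abnormality = FALSE)
#' evaluate_stage1(rec)$stage1_positive  # TRUE
#' @export
evaluate_stage1 <- function(record, rule = default_triage_rule(),
                            missing_policy = c("review", "fail")) {
  if (!is.data.frame(record)) record <- as.data.frame(record, stringsAsFactors = FALSE)
  stopifnot(nrow(record) == 1L)
  dec <- evaluate_stage1_cohort(record, rule, missing_policy)
  sat <- unlist(dec[1, paste0("ind_", rule$names)])
  names(sat) <- rule$names
  structure(list(patient_id = dec$patient_id[1],
                 stage1_positive = dec$stage1_positive[1],
                 satisfaction = sat,
                 missing_fields = if (nzchar(dec$missing_fields[1]))
                   strsplit(dec$missing_fields[1], ",", fixed = TRUE)[[1]] else character(0),
                 needs_manual_review = dec$needs_manual_review[1]),
            class = "triage_decision")
}

#' @export
print.triage_decision <- function(x, ...) {
  cat(sprintf("<triage_decision %s: %s%s>\n", x$patient_id,
              if (x$stage1_positive) "stage-1 POSITIVE" else "negative",
              if (x$needs_manual_review) " (manual review: missing fields)" else ""))
  status <- ifelse(is.na(x$satisfaction), "missing",
                   ifelse(x$satisfaction, "ok", "FAIL"))
  cat(paste(sprintf("  %-26s %s", names(x$satisfaction), status), collapse = "\n"), "\n")
  invisible(x)
}

#' Boundary report for numeric indicators
#'
#' Makes threshold semantics explicit: for each numeric indicator, the
#' minimal value that satisfies it. On integer scales a strict `>` moves the
#' boundary up by one (DN4 > 3 means DN4 >= 4); `>=` thresholds are
#' inclusive; the two-field leg-vs-back comparison is satisfied at equality.
#'
#' @param rule a [triage_rule()].
#' @return data.frame with `indicator`, `field`, `comparator`, `threshold`,
#'   `minimal_satisfying` (as character for the field-vs-field case).
#' @export
evaluate_boundaries <- function(rule = default_triage_rule()) {
  rows <- lapply(rule$indicators, function(ind) {
    reg <- .field_registry[[ind$field]]
    if (!ind$comparator %in% c("ge", "gt", "le", "ge_field")) return(NULL)
    minimal <- switch(ind$comparator,
      ge = format(ind$threshold),
      gt = if (reg$type == "integer") format(ind$threshold + 1)
           else paste0("> ", format(ind$threshold)),
      le = paste0("<= ", format(ind$threshold), " (exclusion present)"),
      ge_field = sprintf("%s == %s (equality satisfies)", ind$field, ind$threshold))
    data.frame(indicator = ind$name, field = ind$field,
               comparator = ind$comparator,
               threshold = if (is.numeric(ind$threshold)) ind$threshold else NA_real_,
               minimal_satisfying = minimal, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Run the two-stage funnel over a cohort
#'
#' Stage 1 applies the triage rule to patient-reported outcomes; stage 2
#' (clinical review) and the final referral decision are external labels,
#' either latent labels from the synthetic generator or a supplied reference
#' table. Counts are nested by construction: a patient only reaches stage 2
#' if stage-1 positive, and is only referred if they passed stage 2.
#'
#' @param patients data.frame of patient records.
#' @param labels data.frame with `patient_id`, `stage2_pass`, `referred`
#'   (logical). In synthetic mode this is the generator's `$labels`.
#' @param rule a [triage_rule()].
#' @param missing_policy passed to [evaluate_stage1_cohort()].
#' @return list of class `funnel_summary`: `counts` (named: assessed,
#'   stage1_positive, stage2_pass, referred), `pathway` (per-patient factor:
#'   not_indicated / manual_review / stage1_only / fast_track / referred),
#'   and the stage-1 `decisions` table.
#' @export
run_funnel <- function(patients, labels, rule = default_triage_rule(),
                       missing_policy = c("review", "fail")) {
  if (nrow(patients) == 0L) stop("cohort is empty", call. = FALSE)
  if (missing(labels) || is.null(labels) ||
      !all(c("patient_id", "stage2_pass", "referred") %in% names(labels))) {
    stop("`labels` must supply patient_id, stage2_pass and referred ",
         "(latent labels in synthetic mode, a reference table in data mode)",
         call. = FALSE)
  }
  dec <- evaluate_stage1_cohort(patients, rule, missing_policy)
  i <- match(dec$patient_id, labels$patient_id)
  if (anyNA(i)) stop("labels missing for some patients", call. = FALSE)
  s1 <- dec$stage1_positive
  s2 <- s1 & as.logical(labels$stage2_pass[i])
  rf <- s2 & as.logical(labels$referred[i])
  pathway <- ifelse(rf, "referred",
             ifelse(s2, "fast_track",
             ifelse(s1, "stage1_only",
             ifelse(dec$needs_manual_review, "manual_review", "not_indicated"))))
  structure(list(
    counts = c(assessed = nrow(patients), stage1_positive = sum(s1),
               stage2_pass = sum(s2), referred = sum(rf)),
    pathway = factor(pathway, levels = c("not_indicated", "manual_review",
                                         "stage1_only", "fast_track", "referred")),
    decisions = dec), class = "funnel_summary")
}

#' @export
print.funnel_summary <- function(x, ...) {
  cat("<funnel_summary>\n")
  cat(sprintf("  assessed        %6d\n  stage-1 positive%6d\n  stage-2 pass    %6d\n  referred        %6d\n",
              x$counts[["assessed"]], x$counts[["stage1_positive"]],
              x$counts[["stage2_pass"]], x$counts[["referred"]]))
  invisible(x)
}

#' Serialise a triage rule to YAML
#'
#' @param rule a [triage_rule()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_rule_yaml <- function(rule, path) {
  stopifnot(inherits(rule, "triage_rule"))
  obj <- list(version = rule$version,
              indicators = lapply(rule$indicators, function(ind) {
                list(name = ind$name, role = ind$role, field = ind$field,
                     comparator = ind$comparator, threshold = ind$threshold,
                     label = ind$label)
              }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a triage rule from YAML
#'
#' @param path YAML file written by [write_rule_yaml()] (or hand-edited with
#'   the same schema).
#' @return a [triage_rule()].
#' @export
read_rule_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$indicators) || !length(obj$indicators)) {
    stop(sprintf("rule file '%s' has no indicators", path), call. = FALSE)
  }
  inds <- lapply(obj$indicators, function(e) {
    need <- setdiff(c("name", "role", "field", "comparator"), names(e))
    if (length(need)) {
      stop(sprintf("rule file '%s': indicator entry missing field(s) %s",
                   path, paste(need, collapse = ", ")), call. = FALSE)
    }
    th <- e$threshold
    if (is.list(th)) th <- unlist(th)
    indicator(e$name, e$role, e$field, e$comparator, th,
              label = e$label %||% e$name)
  })
  triage_rule(inds, version = obj$version %||% "unversioned")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
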
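# End-to-end orchestration: one configuration in, one evaluation report out,
# deterministic given the seed.

#' Build a run configuration
#'
#' Exactly one input mode: `"synthetic"` (a [cohort_config()] drives the
#' generator) or `"file"` (paths to patient and reference-label CSVs, with
#' optional ratings and SUS CSVs).
#'
#' @param mode `"synthetic"` or `"file"`.
#' @param seed mandatory seed for every stochastic step.
#' @param cohort a [cohort_config()] (synthetic mode; built from `seed` and
#'   defaults when omitted).
#' @param paths named list for file mode: `patients`, `reference`
#'   (CSV with patient_id, stage2_pass, referred), optional `ratings`,
#'   optional `sus`.
#' @param rule_profile passed to [default_triage_rule()]; ignored when
#'   `rule_path` is given.
#' @param rule_path optional YAML rule file (see [read_rule_yaml()]).
#' @param missing_policy passed to [evaluate_stage1_cohort()].
#' @param ci_method passed to [accuracy_metrics()].
#' @param raters list of [rater_model()] objects for the synthetic rating
#'   study (default: four clinicians with distinct error rates).
#' @param n_rating_subjects size of the rating subsample (default 50),
#'   drawn stratified so roughly half the subjects are triage-qualifying.
#' @param sus_item_targets per-item mean targets for the synthetic SUS
#'   responses (default: the reported item means shipped with the package).
#' @param sus_n number of synthetic SUS respondents (default 6).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "file"), seed,
                       cohort = NULL, paths = list(),
                       rule_profile = "table1", rule_path = NULL,
                       missing_policy = "review",
                       ci_method = "clopper_pearson",
                       raters = default_raters(),
                       n_rating_subjects = 50L,
                       sus_item_targets = reference_sus_item_means(),
                       sus_n = 6L) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("`seed` is mandatory in run_config()", call. = FALSE)
  if (mode == "synthetic") {
    if (is.null(cohort)) cohort <- cohort_config(seed = seed)
    stopifnot(inherits(cohort, "cohort_config"))
  } else {
    need <- setdiff(c("patients", "reference"), names(paths))
    if (length(need)) {
      stop(sprintf("file mode needs path(s): %s", paste(need, collapse = ", ")),
           call. = FALSE)
    }
    for (p in unlist(paths)) {
      if (!file.exists(p)) stop(sprintf("input file not found: %s", p), call. = FALSE)
    }
  }
  if (!is.null(rule_path) && !file.exists(rule_path)) {
    stop(sprintf("rule file not found: %s", rule_path), call. = FALSE)
  }
  structure(list(mode = mode, seed = as.integer(seed), cohort = cohort,
                 paths = paths, rule_profile = rule_profile,
                 rule_path = rule_path, missing_policy = missing_policy,
                 ci_method = ci_method, raters = raters,
                 n_rating_subjects = as.integer(n_rating_subjects),
                 sus_item_targets = sus_item_targets, sus_n = as.integer(sus_n)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file holds the scalar fields of [run_config()]; `raters` is a list of
#' `{rater_id, p_correct_positive, p_correct_negative}` entries and `cohort`
#' a mapping of [cohort_config()] arguments.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop(sprintf("config '%s' must be .yaml/.yml or .json", path), call. = FALSE)
  }
  if (is.null(obj$mode)) stop(sprintf("config '%s': field 'mode' is required ('synthetic' or 'file')", path), call. = FALSE)
  if (is.null(obj$seed)) stop(sprintf("config '%s': field 'seed' is required (integer)", path), call. = FALSE)
  cohort <- NULL
  if (!is.null(obj$cohort)) {
    args <- obj$cohort
    if (is.null(args$seed)) args$seed <- obj$seed
    cohort <- do.call(cohort_config, args)
  }
  raters <- if (is.null(obj$raters)) default_raters() else {
    lapply(obj$raters, function(r) do.call(rater_model, r))
  }
  run_config(mode = obj$mode, seed = obj$seed, cohort = cohort,
             paths = obj$paths %||% list(),
             rule_profile = obj$rule_profile %||% "table1",
             rule_path = obj$rule_path,
             missing_policy = obj$missing_policy %||% "review",
             ci_method = obj$ci_method %||% "clopper_pearson",
             raters = raters,
             n_rating_subjects = obj$n_rating_subjects %||% 50L,
             sus_item_targets = obj$sus_item_targets %||% reference_sus_item_means(),
             sus_n = obj$sus_n %||% 6L)
}

#' Default rater panel for the synthetic rating study
#'
#' Four clinicians with distinct sensitivity/specificity against the latent
#' eligibility label, mimicking a mixed panel (two pain specialists, a
#' neurosurgeon, a nurse specialist) whose agreement is substantial but not
#' perfect.
#'
#' @return list of four [rater_model()] objects.
#' @export
default_raters <- function() {
  list(rater_model("pain_specialist_1", 0.97, 0.97),
       rater_model("pain_specialist_2", 0.95, 0.96),
       rater_model("neurosurgeon", 0.88, 0.92),
       rater_model("nurse_specialist", 0.93, 0.94))
}

#' The reported per-item SUS means of the six tool users
#'
#' Shipped as a plain-text fixture (`inst/extdata/sus_item_means.csv`);
#' printed to two decimals, e.g. 4.17 for 25/6.
#'
#' @return numeric vector of 10 item means.
#' @export
reference_sus_item_means <- function() {
  df <- utils::read.csv(system.file("extdata", "sus_item_means.csv",
                                    package = "scstriage"))
  df$mean[order(df$item)]
}

#' The reported triage-vs-referral 2x2 counts
#'
#' The evaluated tool's contingency table of the (stage-2) triage indication
#' against the orthopaedic consult's SCS-referral decision, shipped as a
#' plain-text fixture.
#'
#' @return a [contingency_2x2()] (tp = 8, fp = 12, fn = 0, tn = 1005).
#' @export
reference_2x2 <- function() {
  df <- utils::read.csv(system.file("extdata", "reference_2x2.csv",
                                    package = "scstriage"))
  contingency_2x2(tp = df$tp, fp = df$fp, fn = df$fn, tn = df$tn)
}

#' Run the full evaluation pipeline
#'
#' Synthetic mode: generates the cohort, runs the two-stage funnel, scores
#' diagnostic accuracy of the stage-2 triage indication against the latent
#' referral decision, simulates the rating study (inter-rater panel plus a
#' test-retest pass of the first rater) on a stratified 50-patient
#' subsample, and generates/scores the SUS responses. File mode: reads the
#' patient, reference, and optional ratings/SUS CSVs and evaluates the same
#' battery; sections without inputs are omitted.
#'
#' @param config a [run_config()].
#' @return list of class `evaluation_report`: `funnel`, `accuracy`,
#'   `agreement` (or `NULL`), `intra_rater` (or `NULL`), `sus` (or `NULL`),
#'   `provenance`.
#' @export
run_evaluation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rule <- if (!is.null(config$rule_path)) read_rule_yaml(config$rule_path)
          else default_triage_rule(config$rule_profile)

  agreement <- intra <- sus <- NULL
  if (config$mode == "synthetic") {
    cohort <- generate_cohort(config$cohort)
    funnel <- run_funnel(cohort$patients, cohort$labels, rule,
                         config$missing_policy)
    indicated <- funnel$pathway %in% c("fast_track", "referred")
    tab <- build_table(indicated, cohort$labels$referred)
    accuracy <- accuracy_metrics(tab, config$ci_method)

    sub <- rating_subsample(cohort$labels$stage1_qualifying,
                            config$n_rating_subjects, config$seed + 1L)
    if (length(sub) >= 2L && length(config$raters) >= 2L) {
      ratings <- simulate_ratings(cohort$labels$stage1_qualifying[sub],
                                  config$raters, config$seed + 2L,
                                  subject_ids = cohort$patients$patient_id[sub])
      agreement <- agreement_report(ratings)
      retest <- simulate_ratings(cohort$labels$stage1_qualifying[sub],
                                 config$raters[1], config$seed + 3L)
      intra <- intra_rater(ratings[, 1], retest[, 1])
    }
    if (config$sus_n >= 1L) {
      resp <- generate_sus_responses(config$sus_n, config$sus_item_targets,
                                     config$seed + 4L)
      sus <- sus_summarize(resp)
    }
  } else {
    patients <- read_patients_csv(config$paths$patients)
    reference <- utils::read.csv(config$paths$reference, stringsAsFactors = FALSE)
    need <- setdiff(c("patient_id", "stage2_pass", "referred"), names(reference))
    if (length(need)) {
      stop(sprintf("reference CSV lacks column(s): %s", paste(need, collapse = ", ")),
           call. = FALSE)
    }
    reference$stage2_pass <- parse_bool(as.character(reference$stage2_pass), "stage2_pass")
    reference$referred <- parse_bool(as.character(reference$referred), "referred")
    funnel <- run_funnel(patients, reference, rule, config$missing_policy)
    indicated <- funnel$pathway %in% c("fast_track", "referred")
    i <- match(patients$patient_id, reference$patient_id)
    accuracy <- accuracy_metrics(build_table(indicated, reference$referred[i]),
                                 config$ci_method)
    if (!is.null(config$paths$ratings)) {
      agreement <- agreement_report(read_ratings_csv(config$paths$ratings))
    }
    if (!is.null(config$paths$sus)) {
      sus <- sus_summarize(read_sus_csv(config$paths$sus))
    }
  }
  structure(list(funnel = funnel, accuracy = accuracy, agreement = agreement,
                 intra_rater = intra, sus = sus,
                 provenance = list(
                   mode = config$mode, seed = config$seed,
                   rule_version = rule$version,
                   ci_method = config$ci_method,
                   config_hash = rlang::hash(config),
                   package_version = as.character(utils::packageVersion("scstriage")))),
            class = "evaluation_report")
}

# Stratified subsample for the rating study: up to half triage-qualifying
# subjects (as available), topped up with non-qualifying ones.
rating_subsample <- function(qualifying, n_subjects, seed) {
  n <- length(qualifying)
  if (n_subjects >= n) return(seq_len(n))
  with_seed(seed, {
    pos <- which(qualifying)
    neg <- which(!qualifying)
    n_pos <- min(length(pos), floor(n_subjects / 2))
    take <- c(if (n_pos) sample(pos, n_pos),
              sample(neg, min(length(neg), n_subjects - n_pos)))
    sort(take)
  })
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("== Evaluation report ==\n")
  print(x$funnel)
  print(x$accuracy)
  if (!is.null(x$agreement)) print(x$agreement)
  if (!is.null(x$intra_rater)) {
    cat(sprintf("<intra-rater: kappa %.2f, overall agreement %.0f%%%s>\n",
                x$intra_rater$kappa, 100 * x$intra_rater$agreement[["overall"]],
                if (x$intra_rater$reliable) " (reliable)" else ""))
  }
  if (!is.null(x$sus)) print(x$sus)
  invisible(x)
}

# Flatten an evaluation report into plain lists for JSON serialisation.
report_to_list <- function(report) {
  acc <- as.data.frame(report$accuracy)
  out <- list(
    funnel = as.list(report$funnel$counts),
    accuracy = list(counts = as.list(attr(report$accuracy, "counts")),
                    metrics = acc),
    provenance = report$provenance)
  if (!is.null(report$agreement)) {
    ag <- report$agreement
    out$agreement <- list(fleiss_kappa = ag$fleiss_kappa,
                          pairwise = ag$pairwise,
                          pooled_agreement = as.list(ag$pooled_agreement),
                          threshold = ag$threshold)
  }
  if (!is.null(report$intra_rater)) {
    out$intra_rater <- list(kappa = report$intra_rater$kappa,
                            agreement = as.list(report$intra_rater$agreement),
                            reliable = report$intra_rater$reliable)
  }
  if (!is.null(report$sus)) {
    s <- report$sus
    out$sus <- list(n = s$n, mean = s$mean, sd = s$sd,
                    scores = as.list(s$scores), item_means = s$item_means,
                    benchmarks = s$benchmarks,
                    grade = s$grade[c("adjective", "letter", "meets_average")])
  }
  out
}

#' Write an evaluation report to disk
#'
#' Writes `report.json` (machine-readable, no timestamps, so identical
#' config and seed give a byte-identical file), `decisions.csv` (per-patient
#' stage-1 decisions), and `summary.txt` (the printed report).
#'
#' @param report an `evaluation_report` from [run_evaluation()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  write_decisions_csv(report$funnel$decisions, file.path(dir, "decisions.csv"))
  con <- file(file.path(dir, "summary.txt"), open = "w", encoding = "UTF-8")
  sink(con); print(report); sink()
  close(con)
  invisible(dir)
}

#' Reproduce the reported worked example from shipped fixtures
#'
#' Runs the accuracy and usability calculations on the two in-package
#' fixtures: the reported 2x2 triage-vs-referral counts and the reported
#' per-item SUS means of the six tool users. Deterministic; no cohort is
#' generated.
#'
#' @return list: `accuracy` (an `accuracy_report` with Clopper-Pearson
#'   intervals), `npv_rule_of_three` (the 3/n interval for the reported
#'   1005/1005 negative calls), `sus_mean` (SUS transform of the item
#'   means), `benchmarks`, `grade`.
#' @export
reference_worked_example <- function() {
  tab <- reference_2x2()
  acc <- accuracy_metrics(tab, "clopper_pearson")
  im <- reference_sus_item_means()
  mean_sus <- sus_transform(im)
  list(accuracy = acc,
       npv_rule_of_three = ci_proportion(tab$tn, tab$tn + tab$fn, "rule_of_three"),
       sus_mean = mean_sus,
       benchmarks = benchmark_items(im),
       grade = sus_grade(mean_sus))
}
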
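# Plain-text interchange: CSV readers/writers for patient records, rating
# matrices (long format) and SUS responses.
#
# Dialect: UTF-8, header row, comma separator, booleans written as
# "true"/"false", empty cell = missing value.

.bool_cols <- c("prior_back_surgery", "absolute_contraindication",
                "widespread_pain", "substance_abuse", "responded_conservative",
                "prior_scs", "anatomic_abnormality")

fmt_bool <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))

parse_bool <- function(x, col) {
  x[x == ""] <- NA
  out <- rep(NA, length(x))
  out[tolower(x) %in% "true"] <- TRUE
  out[tolower(x) %in% "false"] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop(sprintf("column '%s': expected 'true'/'false', got '%s'",
                 col, x[which(bad)[1]]), call. = FALSE)
  }
  out
}

#' Write a patient table to CSV
#'
#' @param patients data.frame of patient records.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_patients_csv <- function(patients, path) {
  validate_patients(patients)
  out <- patients
  for (cl in .bool_cols) out[[cl]] <- fmt_bool(out[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a patient table from CSV
#'
#' @param path CSV written by [write_patients_csv()] (or following the same
#'   column contract).
#' @return validated data.frame of patient records.
#' @export
read_patients_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("patient_id", names(.field_registry))
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(sprintf("patient CSV '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df <- data.frame(patient_id = raw$patient_id, stringsAsFactors = FALSE)
  for (f in names(.field_registry)) {
    reg <- .field_registry[[f]]
    v <- raw[[f]]
    df[[f]] <- switch(reg$type,
      logical = parse_bool(v, f),
      categorical = { v[v == ""] <- NA; v },
      integer = { v[v == ""] <- NA; as.integer(v) },
      numeric = { v[v == ""] <- NA; as.numeric(v) })
  }
  validate_patients(df)
  df
}

#' Write a rating matrix to long-format CSV
#'
#' One row per (rater, patient) call: columns `rater_id`, `patient_id`,
#' `call` (0/1).
#'
#' @param ratings subjects x raters matrix of binary calls.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ratings_csv <- function(ratings, path) {
  m <- as.matrix(ratings)
  long <- data.frame(
    rater_id = rep(colnames(m) %||% paste0("rater_", seq_len(ncol(m))),
                   each = nrow(m)),
    patient_id = rep(rownames(m) %||% sprintf("S%04d", seq_len(nrow(m))),
                     times = ncol(m)),
    call = as.integer(as.vector(m)), stringsAsFactors = FALSE)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format ratings CSV into a subjects x raters matrix
#'
#' @param path CSV with columns `rater_id`, `patient_id`, `call`.
#' @return integer matrix (subjects x raters) with dimnames; missing
#'   (rater, subject) combinations become `NA` cells.
#' @export
read_ratings_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("rater_id", "patient_id", "call")
  if (!all(need %in% names(long))) {
    stop(sprintf("ratings CSV '%s' needs columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  subjects <- unique(long$patient_id)
  raters <- unique(long$rater_id)
  m <- matrix(NA_integer_, length(subjects), length(raters),
              dimnames = list(subjects, raters))
  m[cbind(match(long$patient_id, subjects), match(long$rater_id, raters))] <-
    as_binary(long$call, "call")
  m
}

#' Write a SUS response set to CSV
#'
#' Columns: `respondent_id`, `item_1` ... `item_10`.
#'
#' @param responses respondents x 10 matrix of Likert responses.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sus_csv <- function(responses, path) {
  m <- as.matrix(responses)
  df <- data.frame(respondent_id = rownames(m) %||% sprintf("R%02d", seq_len(nrow(m))),
                   m, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("respondent_id", paste0("item_", 1:10))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a SUS response CSV
#'
#' @param path CSV with columns `respondent_id`, `item_1` ... `item_10`.
#' @return integer matrix (respondents x 10) with respondent rownames.
#' @export
read_sus_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  items <- paste0("item_", 1:10)
  if (!all(c("respondent_id", items) %in% names(df))) {
    stop(sprintf("SUS CSV '%s' needs columns respondent_id, item_1..item_10", path),
         call. = FALSE)
  }
  m <- as.matrix(df[, items])
  storage.mode(m) <- "integer"
  rownames(m) <- df$respondent_id
  m
}

#' Write stage-1 decisions to CSV
#'
#' @param decisions data.frame from [evaluate_stage1_cohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_decisions_csv <- function(decisions, path) {
  out <- decisions
  for (cl in names(out)) {
    if (is.logical(out[[cl]])) out[[cl]] <- fmt_bool(out[[cl]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
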
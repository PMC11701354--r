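# System Usability Scale scoring, item-level benchmarks, and grade bands.
#
# Standard Brooke scoring: odd (positively worded) items contribute
# value - 1, even (negatively worded) items contribute 5 - value; the sum of
# the ten contributions is scaled by 2.5 to a 0-100 score. The transform is
# affine in the items, so applying it to per-item means reproduces the mean
# of the per-respondent scores exactly.

.sus_odd <- c(1L, 3L, 5L, 7L, 9L)
.sus_even <- c(2L, 4L, 6L, 8L, 10L)

#' Published per-item SUS benchmarks
#'
#' Item-level benchmark means from the published SUS item-benchmark study
#' (Lewis & Sauro). Odd items must exceed their benchmark, even items must
#' fall below theirs; both comparisons are strict.
#'
#' @return data.frame: `item`, `benchmark`, `direction` (`">"` for odd
#'   items, `"<"` for even items).
#' @export
sus_benchmarks <- function() {
  data.frame(item = 1:10,
             benchmark = c(3.39, 2.44, 3.67, 1.85, 3.55, 2.20, 3.71, 2.25, 3.72, 2.09),
             direction = rep(c(">", "<"), 5),
             stringsAsFactors = FALSE)
}

#' Score one SUS respondent
#'
#' @param items integer vector of 10 Likert responses, each in 1-5.
#' @param respondent label used in error messages.
#' @return score in `[0, 100]`.
#' @examples
#' score_respondent(c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1))  # 100
#' score_respondent(rep(3, 10))                       # 50
#' @export
score_respondent <- function(items, respondent = "respondent") {
  if (length(items) != 10L) {
    stop(sprintf("%s: need exactly 10 items, got %d", respondent, length(items)),
         call. = FALSE)
  }
  bad <- which(is.na(items) | items < 1 | items > 5 | items != floor(items))
  if (length(bad)) {
    stop(sprintf("%s: item %d has invalid value %s (must be an integer 1-5)",
                 respondent, bad[1], format(items[bad[1]])), call. = FALSE)
  }
  sus_transform(items)
}

# The affine SUS transform; accepts non-integer values so it can be applied
# to per-item means as well as to one respondent's items.
sus_transform <- function(items) {
  2.5 * (sum(items[.sus_odd] - 1) + sum(5 - items[.sus_even]))
}

#' Summarise a SUS response set
#'
#' Per-respondent scores, their mean and sample standard deviation
#' (denominator n - 1; `NA` for a single respondent), per-item means with
#' benchmark comparison, and the grade of the mean score.
#'
#' @param responses respondents x 10 matrix or data.frame of Likert
#'   responses (a `sus_response_set` from [generate_sus_responses()] or a
#'   table read with [read_sus_csv()]).
#' @return list of class `sus_report`: `scores`, `mean`, `sd`, `n`,
#'   `item_means`, `benchmarks` (from [benchmark_items()]), `grade`
#'   (from [sus_grade()]).
#' @export
sus_summarize <- function(responses) {
  m <- as.matrix(responses)
  if (nrow(m) < 1L) stop("response set is empty", call. = FALSE)
  if (ncol(m) != 10L) stop("response set must have exactly 10 item columns", call. = FALSE)
  ids <- rownames(m) %||% sprintf("R%02d", seq_len(nrow(m)))
  scores <- vapply(seq_len(nrow(m)), function(i)
    score_respondent(m[i, ], respondent = ids[i]), numeric(1))
  names(scores) <- ids
  item_means <- colMeans(m)
  structure(list(scores = scores,
                 mean = mean(scores),
                 sd = if (length(scores) > 1) stats::sd(scores) else NA_real_,
                 n = length(scores),
                 item_means = unname(item_means),
                 benchmarks = benchmark_items(item_means),
                 grade = sus_grade(mean(scores))),
            class = "sus_report")
}

#' @export
print.sus_report <- function(x, ...) {
  cat(sprintf("<sus_report: n=%d, mean %.1f (SD %s) - '%s' / %s>\n",
              x$n, x$mean, if (is.na(x$sd)) "undefined" else sprintf("%.1f", x$sd),
              x$grade$adjective, x$grade$letter))
  fail <- x$benchmarks$item[!x$benchmarks$pass]
  cat(if (length(fail)) sprintf("  items below benchmark: %s\n",
                                paste(fail, collapse = ", "))
      else "  all items meet their benchmarks\n")
  invisible(x)
}

#' Compare per-item means against the published benchmarks
#'
#' Odd items pass iff mean > benchmark, even items iff mean < benchmark
#' (strict inequalities: an item mean exactly at its benchmark fails).
#'
#' @param item_means numeric vector of 10 per-item means.
#' @return data.frame: `item`, `mean`, `benchmark`, `direction`, `pass`.
#' @export
benchmark_items <- function(item_means) {
  if (length(item_means) != 10L) stop("need 10 item means", call. = FALSE)
  b <- sus_benchmarks()
  b$mean <- as.numeric(item_means)
  b$pass <- ifelse(b$direction == ">", b$mean > b$benchmark, b$mean < b$benchmark)
  b[, c("item", "mean", "benchmark", "direction", "pass")]
}

# Grade band tables, stored as data so they can be inspected or replaced.
# Letter grades: the Sauro-Lewis curved grading scale (lower edges).
.sus_letter_bands <- data.frame(
  letter = c("F", "D", "C-", "C", "C+", "B-", "B", "B+", "A-", "A", "A+"),
  lower = c(0, 51.7, 62.7, 65.0, 71.1, 72.6, 74.1, 77.2, 78.9, 80.8, 84.1),
  stringsAsFactors = FALSE)

# Adjective ratings: published mean SUS per adjective (Bangor et al.);
# a score is classified by the nearest adjective anchor.
.sus_adjective_anchors <- data.frame(
  adjective = c("Worst imaginable", "Awful", "Poor", "OK", "Good",
                "Excellent", "Best imaginable"),
  anchor = c(12.5, 20.3, 35.7, 50.9, 71.4, 85.5, 90.9),
  stringsAsFactors = FALSE)

#' Grade a mean SUS score
#'
#' Maps a score to the published adjective rating (nearest adjective
#' anchor), the curved letter grade (band lower edges checked in as data),
#' and whether it reaches the published all-study average of 68.
#'
#' @param score mean SUS score in `[0, 100]`.
#' @return list: `score`, `adjective`, `letter`, `meets_average`
#'   (score >= 68), `average_benchmark` (68).
#' @export
sus_grade <- function(score) {
  if (!is.numeric(score) || length(score) != 1L || is.na(score) ||
      score < 0 || score > 100) {
    stop("`score` must be a single value in [0, 100]", call. = FALSE)
  }
  letter <- .sus_letter_bands$letter[max(which(score >= .sus_letter_bands$lower))]
  adjective <- .sus_adjective_anchors$adjective[
    which.min(abs(score - .sus_adjective_anchors$anchor))]
  list(score = score, adjective = adjective, letter = letter,
       meets_average = score >= 68, average_benchmark = 68)
}
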
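# Diagnostic accuracy of the triage indication against the reference
# referral decision: 2x2 table, Se/Sp/PPV/NPV, binomial confidence intervals.

#' Build a 2x2 contingency table from paired binary vectors
#'
#' Rows are the triage indication (positive/negative), columns the reference
#' SCS-referral decision (yes/no). `tp` counts indication = yes with
#' referral = yes.
#'
#' @param predictions binary vector of triage indications.
#' @param references binary vector of reference referral decisions, same
#'   length.
#' @return object of class `contingency_2x2` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
build_table <- function(predictions, references) {
  p <- as_binary(predictions, "predictions")
  r <- as_binary(references, "references")
  if (length(p) != length(r)) {
    stop(sprintf("length mismatch: %d predictions vs %d references",
                 length(p), length(r)), call. = FALSE)
  }
  contingency_2x2(tp = sum(p == 1L & r == 1L), fp = sum(p == 1L & r == 0L),
                  fn = sum(p == 0L & r == 1L), tn = sum(p == 0L & r == 0L))
}

#' Construct a 2x2 table from counts
#'
#' @param tp,fp,fn,tn non-negative integer counts (true/false
#'   positives/negatives of the triage indication vs the referral decision).
#' @return object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  counts <- as.integer(counts)
  structure(list(tp = counts[1], fp = counts[2], fn = counts[3], tn = counts[4]),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(indication = c("positive", "negative"),
                              referral = c("yes", "no")))
  print(m)
  invisible(x)
}

#' Binomial proportion confidence interval
#'
#' Two-sided interval for k successes in n trials. `"clopper_pearson"` is
#' the exact beta-quantile interval; `"wilson"` the score interval (no
#' continuity correction); `"rule_of_three"` the 3/n bound, defined only for
#' k = 0 (interval `[0, 3/n]`) or k = n (interval `[1 - 3/n, 1]`).
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `>= 1`.
#' @param method `"clopper_pearson"` (default), `"wilson"`, or
#'   `"rule_of_three"`.
#' @param conf_level confidence level (default 0.95; the rule of three is
#'   an approximate 95% bound and ignores this argument).
#' @return named numeric vector `c(lower, upper)`, clipped to `[0, 1]`.
#' @examples
#' ci_proportion(1005, 1005, "rule_of_three")  # lower = 1 - 3/1005
#' @export
ci_proportion <- function(k, n,
                          method = c("clopper_pearson", "wilson", "rule_of_three"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1", call. = FALSE)
  alpha <- 1 - conf_level
  ci <- switch(method,
    clopper_pearson = c(
      if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1),
      if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)),
    wilson = {
      z <- stats::qnorm(1 - alpha / 2)
      phat <- k / n
      centre <- (phat + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      c(centre - half, centre + half)
    },
    rule_of_three = {
      if (k == 0) c(0, 3 / n)
      else if (k == n) c(1 - 3 / n, 1)
      else stop("rule_of_three applies only when k = 0 or k = n", call. = FALSE)
    })
  ci <- pmin(pmax(ci, 0), 1)
  names(ci) <- c("lower", "upper")
  ci
}

#' Sensitivity, specificity and predictive values with confidence intervals
#'
#' Point estimates are the usual ratios: Se = tp/(tp+fn), Sp = tn/(tn+fp),
#' PPV = tp/(tp+fp), NPV = tn/(tn+fn). A metric whose denominator is zero is
#' reported as undefined (`defined = FALSE`, `NA` estimates) rather than 0
#' or NaN. Percentages are rounded half-up to one decimal for reporting;
#' raw proportions are retained.
#'
#' @param table a [contingency_2x2()].
#' @param ci_method `"clopper_pearson"` (default) or `"wilson"`; every
#'   report names its method, since different interval constructions give
#'   visibly different bounds at these small counts.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame of class `accuracy_report`, one row per metric:
#'   `metric`, `k`, `n`, `estimate` (proportion), `percent` (1-decimal),
#'   `lower`, `upper`, `defined`, `ci_method`.
#' @examples
#' accuracy_metrics(contingency_2x2(tp = 8, fp = 12, fn = 0, tn = 1005))
#' @export
accuracy_metrics <- function(table, ci_method = c("clopper_pearson", "wilson"),
                             conf_level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  ci_method <- match.arg(ci_method)
  total <- table$tp + table$fp + table$fn + table$tn
  if (total < 1) stop("table is empty", call. = FALSE)
  spec <- list(se = c(table$tp, table$tp + table$fn),
               sp = c(table$tn, table$tn + table$fp),
               ppv = c(table$tp, table$tp + table$fp),
               npv = c(table$tn, table$tn + table$fn))
  rows <- lapply(names(spec), function(mname) {
    k <- spec[[mname]][1]; n <- spec[[mname]][2]
    if (n == 0) {
      data.frame(metric = mname, k = k, n = n, estimate = NA_real_,
                 percent = NA_real_, lower = NA_real_, upper = NA_real_,
                 defined = FALSE, ci_method = ci_method, stringsAsFactors = FALSE)
    } else {
      ci <- ci_proportion(k, n, ci_method, conf_level)
      data.frame(metric = mname, k = k, n = n, estimate = k / n,
                 percent = round_half_up(100 * k / n, 1),
                 lower = ci[["lower"]], upper = ci[["upper"]],
                 defined = TRUE, ci_method = ci_method, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "counts") <- c(tp = table$tp, fp = table$fp, fn = table$fn, tn = table$tn)
  class(out) <- c("accuracy_report", class(out))
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("<accuracy_report: tp=%d fp=%d fn=%d tn=%d; %s CIs>\n",
              cnt[["tp"]], cnt[["fp"]], cnt[["fn"]], cnt[["tn"]],
              x$ci_method[1]))
  for (i in seq_len(nrow(x))) {
    if (!x$defined[i]) {
      cat(sprintf("  %-4s undefined (denominator 0)\n", toupper(x$metric[i])))
    } else {
      cat(sprintf("  %-4s %5.1f%%  (95%%CI %.3f-%.3f)  [%d/%d]\n",
                  toupper(x$metric[i]), x$percent[i], x$lower[i], x$upper[i],
                  x$k[i], x$n[i]))
    }
  }
  invisible(x)
}
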
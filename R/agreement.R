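# Inter- and intra-rater reliability: Cohen's kappa (pairwise), Fleiss'
# kappa (multi-rater, pooled marginals), and overall/positive/negative
# specific agreement for binary eligibility calls.

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), with expected
#' agreement p_e from the two raters' own marginal distributions. In the
#' degenerate case p_e = 1 (both raters use a single, identical category),
#' kappa is defined as 1 when observed agreement is also perfect and is
#' otherwise undefined (`NA`).
#'
#' @param x,y binary rating vectors of equal length (>= 1).
#' @return kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohen_kappa <- function(x, y) {
  x <- as_binary(x, "x"); y <- as_binary(y, "y")
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch: %d vs %d ratings", length(x), length(y)),
         call. = FALSE)
  }
  n <- length(x)
  p_o <- mean(x == y)
  px <- c(mean(x == 1L), mean(x == 0L))
  py <- c(mean(y == 1L), mean(y == 0L))
  p_e <- sum(px * py)
  if (abs(1 - p_e) < .Machine$double.eps * 4) {
    return(if (p_o == 1) 1 else NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Fleiss' kappa for a complete multi-rater design
#'
#' Multi-rater chance-corrected agreement with pooled category proportions.
#' With exactly two raters this equals Scott's pi (pooled rather than
#' per-rater marginals), not Cohen's kappa. The same degenerate-case
#' convention as [cohen_kappa()] applies when the pooled expected agreement
#' is 1.
#'
#' @param ratings subjects x raters matrix (or data.frame) of binary calls;
#'   complete (no missing cells), >= 2 raters, >= 2 subjects. A
#'   `rating_matrix` from [simulate_ratings()] works directly.
#' @return kappa value.
#' @export
fleiss_kappa <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) {
    stop("rating matrix has missing cells; Fleiss' kappa needs a complete ",
         "design - compute pairwise Cohen's kappa on complete pairs instead",
         call. = FALSE)
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  }
  v <- as_binary(as.vector(m), "ratings")
  m <- matrix(v, nrow = nrow(m))
  r <- ncol(m)
  n_pos <- rowSums(m)
  n_neg <- r - n_pos
  # per-subject observed agreement: fraction of concordant rater pairs
  p_i <- (n_pos * (n_pos - 1) + n_neg * (n_neg - 1)) / (r * (r - 1))
  p_o <- mean(p_i)
  p1 <- mean(n_pos / r)
  p_e <- p1^2 + (1 - p1)^2
  if (abs(1 - p_e) < .Machine$double.eps * 4) {
    return(if (p_o == 1) 1 else NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Overall, positive and negative specific agreement
#'
#' From the paired 2x2 cross-table with a = both-positive, d =
#' both-negative, b and c the discordant cells: overall = (a + d)/n,
#' positive agreement = 2a / (2a + b + c), negative agreement =
#' 2d / (2d + b + c). A component with denominator 0 is `NA`.
#'
#' @param x,y binary rating vectors of equal length (>= 1).
#' @return named numeric vector `c(overall, positive, negative)`.
#' @export
specific_agreement <- function(x, y) {
  x <- as_binary(x, "x"); y <- as_binary(y, "y")
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch: %d vs %d ratings", length(x), length(y)),
         call. = FALSE)
  }
  a <- sum(x == 1L & y == 1L); d <- sum(x == 0L & y == 0L)
  b <- sum(x == 1L & y == 0L); c_ <- sum(x == 0L & y == 1L)
  n <- length(x)
  c(overall = (a + d) / n,
    positive = if (2 * a + b + c_ > 0) 2 * a / (2 * a + b + c_) else NA_real_,
    negative = if (2 * d + b + c_ > 0) 2 * d / (2 * d + b + c_) else NA_real_)
}

#' Intra-rater (test-retest) reliability for one rater
#'
#' Identical mathematics to [cohen_kappa()] and [specific_agreement()],
#' reported under test-retest labelling.
#'
#' @param test,retest the rater's two rating vectors on the same subjects.
#' @param threshold reliability threshold for the verdict (default 0.70).
#' @return list: `kappa`, `agreement` (overall/positive/negative),
#'   `reliable` (kappa >= threshold).
#' @export
intra_rater <- function(test, retest, threshold = 0.70) {
  k <- cohen_kappa(test, retest)
  list(kappa = k, agreement = specific_agreement(test, retest),
       reliable = !is.na(k) && k >= threshold)
}

#' Full inter-rater agreement report for a rating matrix
#'
#' Computes Fleiss' kappa over all raters, the pairwise Cohen's kappa
#' matrix, and specific agreement pooled as the unweighted mean over all
#' rater pairs (the pooling scheme is a reporting choice and is labelled as
#' such). Each rater pair is flagged reliable iff its kappa meets the
#' threshold.
#'
#' @param ratings subjects x raters matrix of binary calls.
#' @param threshold reliability threshold on kappa (default 0.70).
#' @return list of class `agreement_report`: `fleiss_kappa`,
#'   `cohen_matrix` (raters x raters, `NA` diagonal), `pairwise`
#'   (data.frame: rater_a, rater_b, kappa, overall, positive, negative,
#'   reliable), `pooled_agreement` (mean over pairs), `threshold`.
#' @export
agreement_report <- function(ratings, threshold = 0.70) {
  m <- as.matrix(ratings)
  r <- ncol(m)
  if (r < 2L) stop("need >= 2 raters for an agreement report", call. = FALSE)
  ids <- colnames(m) %||% paste0("rater_", seq_len(r))
  fk <- fleiss_kappa(m)
  km <- matrix(NA_real_, r, r, dimnames = list(ids, ids))
  pairs <- utils::combn(r, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    k <- cohen_kappa(m[, i], m[, j])
    km[i, j] <<- km[j, i] <<- k
    ag <- specific_agreement(m[, i], m[, j])
    data.frame(rater_a = ids[i], rater_b = ids[j], kappa = k,
               overall = ag[["overall"]], positive = ag[["positive"]],
               negative = ag[["negative"]],
               reliable = !is.na(k) && k >= threshold,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  structure(list(fleiss_kappa = fk, cohen_matrix = km, pairwise = pw,
                 pooled_agreement = c(overall = mean(pw$overall),
                                      positive = mean(pw$positive),
                                      negative = mean(pw$negative)),
                 threshold = threshold),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report: %d raters, Fleiss' kappa %.2f>\n",
              ncol(x$cohen_matrix), x$fleiss_kappa))
  cat(sprintf("  pooled agreement: overall %.0f%%, positive %.0f%%, negative %.0f%%\n",
              100 * x$pooled_agreement[["overall"]],
              100 * x$pooled_agreement[["positive"]],
              100 * x$pooled_agreement[["negative"]]))
  for (i in seq_len(nrow(x$pairwise))) {
    cat(sprintf("  %s vs %s: kappa %.2f%s\n", x$pairwise$rater_a[i],
                x$pairwise$rater_b[i], x$pairwise$kappa[i],
                if (x$pairwise$reliable[i]) " (reliable)" else ""))
  }
  invisible(x)
}
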
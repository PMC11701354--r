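test_that("Cohen's kappa handles the textbook cases", {
  x <- c(1, 1, 0, 0, 1, 0)
  expect_equal(cohen_kappa(x, x), 1)

  # independence: cross-counts a=b=c=d=25 give p_o = p_e = 0.5, kappa 0
  x <- rep(c(1, 1, 0, 0), each = 25)
  y <- rep(c(1, 0, 1, 0), each = 25)
  expect_equal(cohen_kappa(x, y), 0)

  # degenerate single-category case: kappa defined as 1 at perfect agreement
  expect_equal(cohen_kappa(rep(1, 10), rep(1, 10)), 1)
  expect_true(is.na(cohen_kappa(c(rep(1, 9), 0), rep(1, 10))) ||
                cohen_kappa(c(rep(1, 9), 0), rep(1, 10)) < 1)
  expect_error(cohen_kappa(c(1, 0), c(1, 0, 1)), "length mismatch")
})

test_that("Cohen's kappa equals the cross-tabulation oracle on random pairs", {
  set.seed(10)
  for (i in 1:500) {
    n <- sample(5:60, 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- ifelse(runif(n) < 0.7, x, rbinom(n, 1, 0.5))
    ko <- oracle_cohen_kappa(x, y)
    if (!is.finite(ko)) next  # degenerate marginals
    expect_equal(cohen_kappa(x, y), ko, tolerance = 1e-12)
  }
})

test_that("Fleiss' kappa: unanimity, two-rater Scott's pi, input contracts", {
  m <- cbind(c(1, 1, 0, 0, 1), c(1, 1, 0, 0, 1), c(1, 1, 0, 0, 1))
  expect_equal(fleiss_kappa(m), 1)

  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- ifelse(runif(n) < 0.7, x, rbinom(n, 1, 0.5))
    po <- oracle_scott_pi(x, y)
    if (!is.finite(po)) next
    expect_equal(fleiss_kappa(cbind(x, y)), po, tolerance = 1e-12)
  }

  expect_error(fleiss_kappa(cbind(c(1, NA), c(0, 1))), "complete")
  expect_error(fleiss_kappa(matrix(1, 5, 1)), "raters")
  expect_error(fleiss_kappa(matrix(1, 1, 3)), "subjects")
})

test_that("simulated four-rater Fleiss' kappa recovers its closed-form expectation", {
  n <- 50000
  pi <- 0.45; s <- 0.88; sp <- 0.91
  set.seed(12)
  lab <- runif(n) < pi
  raters <- lapply(1:4, function(i) rater_model(paste0("r", i), s, sp))
  m <- simulate_ratings(lab, raters, seed = 13)
  k_exp <- expected_fleiss_kappa(mean(lab), s, sp)
  expect_lt(abs(fleiss_kappa(m) - k_exp), 0.02)
})

test_that("specific agreement decomposes the paired 2x2 correctly", {
  # perfect agreement with both categories present
  x <- c(1, 1, 0, 0)
  expect_equal(unname(specific_agreement(x, x)), c(1, 1, 1))

  # pure disagreement: a = d = 0, b = c = 1
  expect_equal(unname(specific_agreement(c(1, 0), c(0, 1))), c(0, 0, 0))

  # undefined components get NA markers
  sa <- specific_agreement(rep(1, 5), rep(1, 5))
  expect_equal(sa[["positive"]], 1)
  expect_true(is.na(sa[["negative"]]))

  set.seed(14)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    x <- rbinom(n, 1, 0.5); y <- rbinom(n, 1, 0.5)
    a <- sum(x & y); d <- sum(!x & !y); bc <- sum(x != y)
    sa <- specific_agreement(x, y)
    expect_equal(sa[["overall"]], (a + d) / n)
    if (2 * a + bc > 0) expect_equal(sa[["positive"]], 2 * a / (2 * a + bc))
    if (2 * d + bc > 0) expect_equal(sa[["negative"]], 2 * d / (2 * d + bc))
  }
})

test_that("agreement statistics are invariant to subject order and category relabelling", {
  set.seed(15)
  m <- matrix(rbinom(200, 1, 0.4), 50, 4)
  perm <- sample(50)
  expect_equal(fleiss_kappa(m), fleiss_kappa(m[perm, ]))
  expect_equal(cohen_kappa(m[, 1], m[, 2]), cohen_kappa(m[perm, 1], m[perm, 2]))

  flipped <- 1 - m
  expect_equal(fleiss_kappa(flipped), fleiss_kappa(m), tolerance = 1e-12)
  expect_equal(cohen_kappa(flipped[, 1], flipped[, 2]),
               cohen_kappa(m[, 1], m[, 2]), tolerance = 1e-12)
  sa <- specific_agreement(m[, 1], m[, 2])
  sa_f <- specific_agreement(flipped[, 1], flipped[, 2])
  expect_equal(sa_f[["overall"]], sa[["overall"]])
  expect_equal(sa_f[["positive"]], sa[["negative"]])
  expect_equal(sa_f[["negative"]], sa[["positive"]])
})

test_that("the agreement report applies the 0.70 reliability verdict per pair", {
  set.seed(16)
  lab <- rbinom(60, 1, 0.5)
  good <- ifelse(runif(60) < 0.97, lab, 1 - lab)
  fair <- ifelse(runif(60) < 0.80, lab, 1 - lab)
  m <- cbind(a = lab, b = good, c = fair)
  rep <- agreement_report(m, threshold = 0.70)
  expect_s3_class(rep, "agreement_report")
  for (i in seq_len(nrow(rep$pairwise))) {
    expect_equal(rep$pairwise$reliable[i], rep$pairwise$kappa[i] >= 0.70)
  }
  expect_equal(unname(rep$pooled_agreement[["overall"]]),
               mean(rep$pairwise$overall))
  expect_true(abs(rep$fleiss_kappa) <= 1)
})

test_that("intra-rater reliability mirrors Cohen's kappa with test-retest labels", {
  x <- c(1, 1, 0, 0, 1, 0, 1, 0)
  res <- intra_rater(x, x)
  expect_equal(res$kappa, 1)
  expect_equal(res$agreement[["overall"]], 1)
  expect_true(res$reliable)

  res <- intra_rater(x, 1 - x)
  expect_equal(res$agreement[["overall"]], 0)
  expect_false(res$reliable)

  # closed form under random flips: retest flips each call with prob f
  n <- 50000; f <- 0.1
  set.seed(17)
  test <- rbinom(n, 1, 0.3)
  retest <- ifelse(runif(n) < f, 1 - test, test)
  m <- mean(test); m2 <- m * (1 - f) + (1 - m) * f
  pe <- m * m2 + (1 - m) * (1 - m2)
  k_exp <- (1 - f - pe) / (1 - pe)
  expect_lt(abs(intra_rater(test, retest)$kappa - k_exp), 0.02)
})
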
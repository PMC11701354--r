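test_that("2x2 tables are built by direct counting", {
  t1 <- build_table(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(t1[c("tp", "fp", "fn", "tn")]), c(tp = 2L, fp = 0L, fn = 0L, tn = 1L))
  t2 <- build_table(c(1, 0, 1), c(0, 1, 0))
  expect_equal(t2$tp + t2$tn, 0L)
  expect_equal(t2$fp, 2L)

  set.seed(1)
  for (i in 1:20) {
    p <- sample(0:1, 500, replace = TRUE)
    r <- sample(0:1, 500, replace = TRUE)
    tab <- build_table(p, r)
    expect_equal(tab$tp, sum(p & r))
    expect_equal(tab$fp, sum(p & !r))
    expect_equal(tab$fn, sum(!p & r))
    expect_equal(tab$tn, sum(!p & !r))
  }
  expect_error(build_table(c(1, 0), c(1, 0, 1)), "length mismatch")
  expect_error(build_table(c(1, 2, 0), c(1, 0, 1)), "binary")
  expect_error(build_table(c(1, NA, 0), c(1, 0, 1)), "binary")
})

test_that("the reported 2x2 yields the printed accuracy percentages", {
  rep <- accuracy_metrics(contingency_2x2(tp = 8, fp = 12, fn = 0, tn = 1005))
  est <- setNames(rep$percent, rep$metric)
  expect_equal(est[["se"]], 100.0)
  expect_equal(est[["sp"]], 98.8)
  expect_equal(est[["ppv"]], 40.0)
  expect_equal(est[["npv"]], 100.0)
  expect_true(all(rep$defined))
  expect_equal(rep$ci_method, rep("clopper_pearson", 4))
})

test_that("zero denominators give an explicit undefined marker, not zero", {
  rep <- accuracy_metrics(contingency_2x2(tp = 0, fp = 0, fn = 0, tn = 5))
  est <- setNames(rep$defined, rep$metric)
  expect_false(est[["se"]])   # tp + fn = 0
  expect_false(est[["ppv"]])  # tp + fp = 0
  expect_true(est[["sp"]])
  expect_equal(rep$estimate[rep$metric == "sp"], 1)
  expect_true(all(is.na(rep$estimate[!rep$defined])))
  expect_error(accuracy_metrics(contingency_2x2(0, 0, 0, 0)), "empty")
})

test_that("metrics equal independent ratio arithmetic on random tables", {
  set.seed(2)
  for (i in 1:50) {
    k <- sample(0:40, 4, replace = TRUE)
    if (sum(k) == 0) next
    rep <- accuracy_metrics(contingency_2x2(k[1], k[2], k[3], k[4]))
    est <- setNames(rep$estimate, rep$metric)
    if (k[1] + k[3] > 0) expect_equal(est[["se"]], k[1] / (k[1] + k[3]), tolerance = 1e-12)
    if (k[4] + k[2] > 0) expect_equal(est[["sp"]], k[4] / (k[4] + k[2]), tolerance = 1e-12)
    if (k[1] + k[2] > 0) expect_equal(est[["ppv"]], k[1] / (k[1] + k[2]), tolerance = 1e-12)
    if (k[4] + k[3] > 0) expect_equal(est[["npv"]], k[4] / (k[4] + k[3]), tolerance = 1e-12)
  }
})

test_that("PPV is Bayes-consistent with Se, Sp and prevalence", {
  set.seed(3)
  for (i in 1:30) {
    k <- sample(1:40, 4, replace = TRUE)
    rep <- accuracy_metrics(contingency_2x2(k[1], k[2], k[3], k[4]))
    est <- setNames(rep$estimate, rep$metric)
    prev <- (k[1] + k[3]) / sum(k)
    bayes <- est[["se"]] * prev /
      (est[["se"]] * prev + (1 - est[["sp"]]) * (1 - prev))
    expect_equal(est[["ppv"]], unname(bayes), tolerance = 1e-10)
  }
})

test_that("transposing the table swaps Se with PPV and Sp with NPV", {
  set.seed(4)
  for (i in 1:20) {
    k <- sample(1:30, 4, replace = TRUE)
    a <- accuracy_metrics(contingency_2x2(k[1], k[2], k[3], k[4]))
    b <- accuracy_metrics(contingency_2x2(k[1], k[3], k[2], k[4]))
    ea <- setNames(a$estimate, a$metric); eb <- setNames(b$estimate, b$metric)
    expect_equal(ea[["se"]], eb[["ppv"]])
    expect_equal(ea[["ppv"]], eb[["se"]])
    expect_equal(ea[["sp"]], eb[["npv"]])
    expect_equal(ea[["npv"]], eb[["sp"]])
  }
})

test_that("Clopper-Pearson and Wilson intervals match their reference constructions", {
  set.seed(5)
  for (i in 1:40) {
    n <- sample(5:200, 1)
    k <- sample(0:n, 1)
    cp <- ci_proportion(k, n, "clopper_pearson")
    ref <- stats::binom.test(k, n)$conf.int
    expect_equal(unname(cp), as.numeric(ref), tolerance = 1e-10)
    if (k > 0 && k < n) {
      w <- ci_proportion(k, n, "wilson")
      # suppress prop.test's small-count chi-squared approximation warning;
      # only its score interval is used here
      refw <- suppressWarnings(stats::prop.test(k, n, correct = FALSE)$conf.int)
      expect_equal(unname(w), as.numeric(refw), tolerance = 1e-10)
    }
  }
})

test_that("interval properties: contain the point estimate, shrink with n", {
  for (meth in c("clopper_pearson", "wilson")) {
    for (k_over_n in c(0.2, 0.5, 0.9)) {
      widths <- sapply(c(10, 40, 160, 640), function(n) {
        k <- round(k_over_n * n)
        ci <- ci_proportion(k, n, meth)
        expect_lte(ci[["lower"]], k / n)
        expect_gte(ci[["upper"]], k / n)
        ci[["upper"]] - ci[["lower"]]
      })
      expect_true(all(diff(widths) < 0))
    }
  }
})

test_that("the rule of three matches the printed NPV lower bound and rejects interior k", {
  ci <- ci_proportion(1005, 1005, "rule_of_three")
  expect_equal(round(100 * ci[["lower"]], 1), 99.7)
  expect_equal(ci[["upper"]], 1)
  ci0 <- ci_proportion(0, 30, "rule_of_three")
  expect_equal(unname(ci0), c(0, 0.1))
  expect_error(ci_proportion(5, 30, "rule_of_three"), "only when")
  # k = n gives upper bound 1 under every method
  for (meth in c("clopper_pearson", "wilson", "rule_of_three")) {
    expect_equal(ci_proportion(20, 20, meth)[["upper"]], 1)
  }
  expect_error(ci_proportion(5, 3), "k <= n")
})
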
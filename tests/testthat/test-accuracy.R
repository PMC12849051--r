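# 2x2 construction, exact intervals, paired McNemar, multiplicity

test_that("2x2 construction applies the missing/inconclusive policies", {
  # published RMI-250 cohort-1 structure: 49 cancers (2 test-missing),
  # 750 non-cancers (125 test-missing)
  f <- states_from_counts(tp = 20, fp = 22, fn = 27, tn = 603,
                          miss_case = 2, miss_ctrl = 125)
  tab <- build_two_by_two(f$states, f$outcomes, test_id = "rmi1@250")
  expect_equal(c(tab$tp, tab$fn, tab$fp, tab$tn), c(20, 27, 22, 603))
  expect_equal(tab$n_missing_test, 127)
  # simple rules: 15 + 105 inconclusives removed before cell filling
  f2 <- states_from_counts(tp = 24, fp = 25, fn = 8, tn = 496,
                           miss_case = 2, miss_ctrl = 124,
                           inc_case = 15, inc_ctrl = 105)
  tab2 <- build_two_by_two(f2$states, f2$outcomes)
  expect_equal(c(tab2$tp, tab2$fn, tab2$fp, tab2$tn), c(24, 8, 25, 496))
  expect_equal(tab2$n_inconclusive, 120)
  # cells + missing + inconclusive account for every non-excluded participant
  expect_equal(tab2$tp + tab2$fp + tab2$fn + tab2$tn + tab2$n_missing_test +
                 tab2$n_inconclusive, length(f2$states))
  # alternative policy: inconclusives as positive move into tp/fp
  tab3 <- build_two_by_two(f2$states, f2$outcomes,
                           inconclusive_policy = "positive")
  expect_equal(c(tab3$tp, tab3$fp), c(39, 130))
  # degenerate all-positive table
  tab4 <- build_two_by_two(rep("positive", 5), rep("positive", 5))
  expect_equal(c(tab4$fn, tab4$fp, tab4$tn), c(0, 0, 0))
  # excluded outcomes dropped first
  tab5 <- build_two_by_two(c("positive", "negative"),
                           c("excluded", "negative"))
  expect_equal(tab5$n_outcome_excluded, 1L)
  expect_error(build_two_by_two("positive", c("positive", "negative")),
               "integrity")
})

test_that("Clopper-Pearson intervals reproduce the published precision", {
  e <- proportion_with_ci(20, 47)
  expect_equal(round(100 * c(e$point, e$ci_low, e$ci_high), 1),
               c(42.6, 28.3, 57.8))
  e2 <- proportion_with_ci(27, 49)
  expect_equal(round(100 * c(e2$point, e2$ci_low, e2$ci_high), 1),
               c(55.1, 40.2, 69.3))
  # boundaries
  e3 <- proportion_with_ci(0, 10)
  expect_equal(c(e3$point, e3$ci_low), c(0, 0))
  e4 <- proportion_with_ci(10, 10)
  expect_equal(e4$ci_high, 1)
  # zero denominator: undefined marker, not an exception
  e5 <- proportion_with_ci(0, 0)
  expect_true(e5$undefined)
  expect_true(is.na(e5$point))
  # interval always contains the point; matches binom.test
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:200, 1); k <- sample(0:n, 1)
    e <- proportion_with_ci(k, n)
    expect_lte(e$ci_low, e$point)
    expect_gte(e$ci_high, e$point)
    bt <- stats::binom.test(k, n)$conf.int
    expect_equal(c(e$ci_low, e$ci_high), as.vector(bt), tolerance = 1e-10)
  }
})

test_that("exact interval coverage is at least nominal on a reduced grid", {
  set.seed(11)
  for (n in c(20, 60)) {
    for (p in c(0.1, 0.5)) {
      ks <- rbinom(400, n, p)
      cover <- vapply(ks, function(k) {
        e <- proportion_with_ci(k, n)
        e$ci_low <= p && p <= e$ci_high
      }, logical(1))
      expect_gte(mean(cover), 0.93)  # CP is conservative; MC slack only
    }
  }
})

test_that("accuracy metrics come from the 2x2 margins, with swap symmetry", {
  tab <- two_by_two(tp = 20, fp = 22, fn = 27, tn = 603)
  m <- accuracy_metrics(tab)
  expect_equal(round(100 * m$ppv$point, 1), 47.6)
  expect_equal(round(100 * m$npv$point, 1), 95.7)
  expect_equal(round(100 * c(m$npv$ci_low, m$npv$ci_high), 1), c(93.8, 97.2))
  # swapping outcome labels (and test polarity) swaps sens<->spec, ppv<->npv
  swapped <- two_by_two(tp = tab$tn, fp = tab$fn, fn = tab$fp, tn = tab$tp)
  ms <- accuracy_metrics(swapped)
  expect_equal(ms$sensitivity$point, m$specificity$point)
  expect_equal(ms$specificity$point, m$sensitivity$point)
  expect_equal(ms$ppv$point, m$npv$point)
  expect_equal(ms$npv$point, m$ppv$point)
  # empty margin: undefined marker
  m0 <- accuracy_metrics(two_by_two(0, 5, 0, 10))
  expect_true(m0$sensitivity$undefined)
})

test_that("exact McNemar p equals the binomial tail sum and is symmetric", {
  expect_equal(mcnemar_exact_p(0, 0), 1)
  expect_equal(mcnemar_exact_p(5, 1), 0.21875)
  for (b in 0:6) for (cc in 0:6) {
    oracle <- if (b + cc == 0) 1 else
      min(1, 2 * sum(stats::dbinom(0:min(b, cc), b + cc, 0.5)))
    expect_equal(mcnemar_exact_p(b, cc), oracle)
    expect_equal(mcnemar_exact_p(b, cc), mcnemar_exact_p(cc, b))
  }
})

test_that("paired comparison reproduces the published RMI 200 vs 250 contrast", {
  # nested thresholds: the cross-classification is determined by marginals
  cases_250 <- c(rep("positive", 20), rep("negative", 27))
  cases_200 <- c(rep("positive", 23), rep("negative", 24))
  ctrl_250 <- c(rep("positive", 22), rep("negative", 603))
  ctrl_200 <- c(rep("positive", 29), rep("negative", 596))
  pc <- mcnemar_paired(
    test_states = c(cases_200, ctrl_200),
    comparator_states = c(cases_250, ctrl_250),
    outcomes = c(rep("positive", 47), rep("negative", 625)),
    test_id = "rmi1@200", comparator_id = "rmi1@250")
  expect_equal(pc$n_common, 672)
  expect_equal(round(100 * pc$sensitivity$delta, 1), -6.4)
  expect_equal(round(100 * c(pc$sensitivity$ci_low, pc$sensitivity$ci_high), 1),
               c(-15.5, 2.7))
  expect_equal(pc$sensitivity$p_value, 0.25)
  expect_equal(round(100 * pc$specificity$delta, 1), 1.1)
  expect_equal(round(100 * c(pc$specificity$ci_low, pc$specificity$ci_high), 1),
               c(0.1, 2.1))
  expect_equal(round(pc$specificity$p_value, 2), 0.02)
  # no discordance: p = 1 and a degenerate interval at 0 (up to the
  # continuity correction, which is switched off here)
  pc0 <- mcnemar_paired(c("positive", "negative"), c("positive", "negative"),
                        c("positive", "negative"), continuity = FALSE)
  expect_equal(pc0$sensitivity$p_value, 1)
  expect_equal(pc0$sensitivity$delta, 0)
  expect_equal(c(pc0$sensitivity$ci_low, pc0$sensitivity$ci_high), c(0, 0))
  # restriction to conclusive-in-both with non-excluded outcome
  pc2 <- mcnemar_paired(c("positive", "missing", "positive"),
                        c("positive", "positive", "inconclusive"),
                        rep("positive", 3))
  expect_equal(pc2$n_common, 1)
  expect_error(mcnemar_paired("missing", "positive", "positive"), "conclusive")
})

test_that("Bonferroni adjustment follows the published rounding at n = 11", {
  a11 <- adjust_multiplicity(c(0.004, 0.006), 11)
  expect_equal(a11$alpha, 0.005)
  expect_equal(a11$significant, c(TRUE, FALSE))
  expect_equal(adjust_multiplicity(0.04, 1)$alpha, 0.05)
  expect_equal(adjust_multiplicity(0.01, 5)$alpha, 0.01)
})
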
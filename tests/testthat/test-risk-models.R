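# index-test scorers: U score, RMI, ROMA, simple rules (+ risk), ADNEX,
# ORADS mapping, dichotomisation

test_that("U score maps feature counts to 0/1/3 and propagates unknowns", {
  expect_equal(compute_u_score(0, 0, 0, 0, 0), 0L)
  expect_equal(compute_u_score(0, 0, 0, 1, 0), 1L)  # only ascites
  expect_equal(compute_u_score(1, 1, 0, 1, 0), 3L)
  expect_equal(compute_u_score(1, 1, 1, 1, 1), 3L)
  expect_true(is.na(compute_u_score(1, NA, 0, 0, 0)))
})

test_that("RMI is the U x M x CA125 product with the premenopausal multiplier", {
  expect_equal(compute_rmi(100, 3L, "premenopausal"), 300)
  expect_equal(compute_rmi(100, 3L, "postmenopausal"), 900)
  expect_equal(compute_rmi(500, 0L, "premenopausal"), 0)
  expect_equal(compute_rmi(84, 1L, "premenopausal"), 84)
  expect_equal(dichotomize_score(84, 250), "negative")
  expect_error(compute_rmi(-1, 1L, "premenopausal"), "nonnegative")
  # nonnegative, zero iff a zero factor, increasing in CA 125 for fixed U >= 1
  ca <- seq(0, 400, by = 25)
  r <- compute_rmi(ca, 1L, "premenopausal")
  expect_true(all(r >= 0))
  expect_true(all(diff(r) > 0))
  expect_identical(r == 0, ca == 0)
})

test_that("ROMA is the logistic of the stratum predictive index", {
  # PI = 0 gives the logistic midpoint
  cf <- toy_roma_coefs(int_pre = -2 * log(10), a_pre = 1, b_pre = 1)
  expect_equal(compute_roma(10, 10, "premenopausal", cf), 50)
  # monotone: doubling HE4 strictly increases the score when a > 0
  set.seed(42)
  he4 <- runif(50, 10, 200); ca <- runif(50, 5, 500)
  cf2 <- toy_roma_coefs(int_pre = -10, a_pre = 2.4, b_pre = 0.06)
  r1 <- compute_roma(ca, he4, rep("premenopausal", 50), cf2)
  r2 <- compute_roma(ca, 2 * he4, rep("premenopausal", 50), cf2)
  expect_true(all(r2 > r1))
  expect_true(all(r1 >= 0 & r1 <= 100))
  # stratum switch with the same markers changes the score
  cfs <- toy_roma_coefs(int_pre = 0, int_post = 1)
  expect_false(compute_roma(10, 10, "premenopausal", cfs) ==
                 compute_roma(10, 10, "postmenopausal", cfs))
  expect_error(compute_roma(0, 10, "premenopausal", cf), "positive")
  expect_error(compute_roma(10, 10, "perimenopausal", cf), "stratum")
})

test_that("ROMA is invariant under reparameterisations preserving the linear predictor", {
  # absorbing a log-scale shift of HE4 into the intercept leaves ROMA unchanged
  he4 <- c(20, 60, 180); ca <- c(15, 80, 300)
  a <- 2.4; b <- 0.06; k <- 3
  cf1 <- toy_roma_coefs(int_pre = -10, a_pre = a, b_pre = b)
  cf2 <- toy_roma_coefs(int_pre = -10 + a * log(k), a_pre = a, b_pre = b)
  expect_equal(compute_roma(ca, he4, rep("premenopausal", 3), cf1),
               compute_roma(ca, he4 / k, rep("premenopausal", 3), cf2),
               tolerance = 1e-12)
})

test_that("simple rules classifier agrees with the exhaustive truth-table oracle", {
  # all 1024 B/M feature combinations; the oracle restates the published rule
  combos <- as.matrix(expand.grid(rep(list(0:1), 10)))
  got <- compute_simple_rules(combos[, 1:5], combos[, 6:10])
  oracle <- apply(combos, 1, function(r) {
    has_b <- sum(r[1:5]) >= 1
    has_m <- sum(r[6:10]) >= 1
    if (has_m && !has_b) "malignant"
    else if (has_b && !has_m) "benign"
    else "inconclusive"
  })
  expect_equal(got, unname(oracle))
  # named examples
  m_only <- matrix(0, 1, 5); m_only[1, 1] <- 1
  none <- matrix(0, 1, 5)
  expect_equal(compute_simple_rules(none, m_only), "malignant")
  expect_equal(compute_simple_rules(m_only, none), "benign")
  expect_equal(compute_simple_rules(m_only, m_only), "inconclusive")
  expect_equal(compute_simple_rules(none, none), "inconclusive")
  # unassessed features give a missing result
  na_b <- none; na_b[1, 2] <- NA
  expect_true(is.na(compute_simple_rules(na_b, none)))
})

test_that("simple rules risk model is a bounded monotone logistic", {
  cf <- toy_srrisk_coefs(intercept = -2)
  zero <- matrix(0, 1, 5)
  expect_equal(compute_simple_rules_risk(zero, zero, "non_oncology", cf),
               100 * plogis(-2))
  # adding a positive-coefficient malignant feature strictly increases risk
  m1 <- zero; m1[1, 1] <- 1
  expect_gt(compute_simple_rules_risk(zero, m1, "non_oncology", cf),
            compute_simple_rules_risk(zero, zero, "non_oncology", cf))
  # oncology centre effect
  expect_gt(compute_simple_rules_risk(zero, zero, "oncology", cf),
            compute_simple_rules_risk(zero, zero, "non_oncology", cf))
  # range over random feature patterns
  set.seed(1)
  b <- matrix(rbinom(250, 1, 0.3), 50, 5)
  m <- matrix(rbinom(250, 1, 0.3), 50, 5)
  r <- compute_simple_rules_risk(b, m, rep("oncology", 50), cf)
  expect_true(all(r >= 0 & r <= 100))
})

test_that("ADNEX produces normalised class probabilities and monotone CA 125 risk", {
  cf0 <- toy_adnex_coefs(zero = TRUE)
  out <- compute_adnex(age = 45, ca125 = 50, max_lesion_diameter = 60,
                       max_solid_diameter = 20, more_than_10_locules = 0,
                       papillation_count = 1, acoustic_shadows = 0,
                       ascites = 0, centre_type = "oncology",
                       coefficients = cf0)
  # zeroed linear predictors with benign reference: all five classes at 1/5
  expect_equal(unname(out$probabilities[1, ]), rep(0.2, 5))
  expect_equal(out$risk, 80)
  cf <- toy_adnex_coefs()
  grid <- seq(10, 1000, length.out = 30)
  risks <- compute_adnex(rep(45, 30), grid, rep(60, 30), rep(20, 30),
                         rep(0, 30), rep(1, 30), rep(0, 30), rep(0, 30),
                         rep("oncology", 30), cf)$risk
  expect_true(all(diff(risks) > 0))  # positive CA 125 coefficients
  expect_true(all(rowSums(compute_adnex(rep(45, 3), c(10, 50, 500),
    rep(60, 3), rep(20, 3), rep(0, 3), rep(0, 3), rep(0, 3), rep(0, 3),
    rep("oncology", 3), cf)$probabilities) - 1 < 1e-12))
  # proportion solid outside [0,1] is clipped with a warning
  expect_warning(
    compute_adnex(45, 50, 60, 80, 0, 0, 0, 0, "oncology", cf), "clipped")
  # missing CA 125: missing result by default, usable under the omit policy
  expect_true(is.na(compute_adnex(45, NA, 60, 20, 0, 0, 0, 0,
                                  "oncology", cf)$risk))
  expect_false(is.na(compute_adnex(45, NA, 60, 20, 0, 0, 0, 0, "oncology",
                                   cf, ca125_policy = "omit")$risk))
})

test_that("ORADS mapping follows the shipped rule table", {
  co <- make_mini_cohort()
  map <- default_orads_mapping()
  cat <- map_orads(co, map)
  # no lesion present -> category 1 -> negative
  expect_equal(cat[4], 1L)
  expect_equal(dichotomize_category(cat, "orads")[4], "negative")
  # ascites + solid lesion with many papillations -> category 5 -> positive
  expect_equal(cat[5], 5L)
  expect_equal(dichotomize_category(cat, "orads")[5], "positive")
  # small smooth unilocular cyst -> category <= 3 -> negative
  expect_lte(cat[6], 3L)
  expect_equal(dichotomize_category(cat, "orads")[6], "negative")
  # every mapped category is the one its first matching table row prescribes
  for (i in seq_len(nrow(map))) {
    hit <- ovatriage:::.orads_rule_matches(map$rule_id[i], co)
    expect_type(hit, "logical")
  }
})

test_that("dichotomisation uses a strict tie rule and nests across thresholds", {
  expect_equal(dichotomize_score(300, 250), "positive")
  expect_equal(dichotomize_score(87, 87), "negative")   # boundary: strict >
  expect_equal(dichotomize_score(87, 87, strict = FALSE), "positive")
  expect_equal(dichotomize_score(NA, 87), "missing")
  expect_equal(dichotomize_category("inconclusive", "simple_rules"),
               "inconclusive")
  # positives at a higher threshold are a subset of positives at a lower one
  set.seed(5)
  s <- c(runif(200, 0, 500), rep(c(200, 250), 5))
  p1 <- dichotomize_score(s, 200) == "positive"
  p2 <- dichotomize_score(s, 250) == "positive"
  expect_true(all(p1[p2]))
})

test_that("coefficient sets are validated and the shipped registry loads", {
  expect_error(
    coefficient_set("roma", "v", strata = list(premenopausal =
      c(intercept = 0, log_he4 = 1)), transforms = c()),
    "log_ca125")
  expect_error(
    coefficient_set("roma", "", strata = list(premenopausal =
      c(intercept = 0, log_he4 = 1, log_ca125 = 1)), transforms = c()))
  reg <- default_coefficients()
  expect_setequal(names(reg), c("roma", "adnex", "simple_rules_risk"))
  for (cs in reg) expect_s3_class(cs, "coefficient_set")
  # synthetic defaults are labelled as such
  expect_match(reg$adnex$source_citation, "SYNTHETIC")
  expect_match(reg$simple_rules_risk$source_citation, "SYNTHETIC")
})

test_that("scorers never silently impute: missing predictors give missing states", {
  co <- make_mini_cohort()
  co$ca125[5] <- NA      # breaks RMI, ROMA, ADNEX, CA 125 for that row
  co$us_scan_available[6] <- 0L
  sc <- score_cohort(co)
  expect_true(is.na(sc$rmi1[5]))
  expect_true(is.na(sc$roma[5]))
  expect_true(is.na(sc$adnex[5]))
  expect_true(is.na(sc$srrisk[6]))
  expect_true(is.na(sc$sr_category[6]))
  st <- apply_thresholds(sc)
  expect_true(all(st$state[st$participant_id == "W5" &
                             st$test_id %in%
                             c("rmi1@250", "roma@11.4", "adnex@10",
                               "ca125@87")] == "missing"))
})
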
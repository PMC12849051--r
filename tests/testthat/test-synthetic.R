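# synthetic cohort generator

test_that("generation is reproducible and respects the configured sizes", {
  cfg <- synthetic_config(seed = 42)
  a <- suppressMessages(generate_cohort(cfg))
  b <- suppressMessages(generate_cohort(cfg))
  expect_identical(a, b)
  expect_equal(nrow(a), 857 + 354)
  expect_equal(sum(a$cohort_tag == "pre_change"), 857)
  # valid against the documented schema
  expect_silent(suppressWarnings(validate_cohort(a)))
  # round trip through the CSV schema
  path <- tempfile(fileext = ".csv")
  write_cohort(a, path)
  back <- read_cohort(path)
  expect_equal(back$ca125, a$ca125)
  expect_equal(back$ref_histology_category, a$ref_histology_category)
})

test_that("configured prevalences are recovered up to binomial error", {
  prev_pre <- prev_post <- numeric(10)
  for (i in seq_len(10)) {
    co <- suppressMessages(generate_cohort(synthetic_config(seed = 100 + i)))
    pre <- co$cohort_tag == "pre_change"
    prev_pre[i] <- mean(co$ref_histology_category[pre] == "primary_invasive")
    prev_post[i] <- mean(co$ref_histology_category[!pre] == "primary_invasive")
  }
  se_pre <- sqrt(0.057 * 0.943 / (857 * 10))
  se_post <- sqrt(0.110 * 0.890 / (354 * 10))
  expect_lt(abs(mean(prev_pre) - 0.057), 4 * se_pre)
  expect_lt(abs(mean(prev_post) - 0.110), 4 * se_post)
  # zero prevalence: no positives, sensitivity undefined downstream
  cfg0 <- synthetic_config(seed = 1)
  cfg0$prevalence_pre <- 0; cfg0$prevalence_post <- 0
  co0 <- suppressMessages(generate_cohort(cfg0))
  expect_equal(sum(co0$ref_histology_category == "primary_invasive"), 0)
  oc <- derive_outcome(co0, "primary")
  sc <- score_cohort(co0)
  st <- apply_thresholds(sc)
  tab <- build_two_by_two(st$state[st$test_id == "ca125@87"], oc)
  expect_true(accuracy_metrics(tab)$sensitivity$undefined)
})

test_that("class-conditional marker locations match the configuration", {
  cfg <- synthetic_config(seed = 77)
  co <- suppressMessages(generate_cohort(cfg))
  case <- co$ref_histology_category == "primary_invasive" & !is.na(co$ca125)
  benign <- co$ref_histology_category %in% c("benign", "normal") &
    !is.na(co$ca125)
  for (grp in list(list(case, "case"), list(benign, "control"))) {
    idx <- grp[[1]]; cl <- grp[[2]]
    mu <- cfg$marker_params[[cl]]$ca125[1]
    sd_ <- cfg$marker_params[[cl]]$ca125[2]
    se <- sd_ / sqrt(sum(idx))
    expect_lt(abs(mean(log(co$ca125[idx])) - mu), 3 * se)
  }
  # log-scale marker correlation has the configured sign and rough size
  both <- benign & !is.na(co$he4)
  expect_gt(cor(log(co$ca125[both]), log(co$he4[both])), 0.1)
})

test_that("missingness punching follows its mechanism and rates", {
  cfg <- synthetic_config(seed = 5)
  cfg$missing_rates <- list()
  co <- suppressMessages(generate_cohort(cfg))
  # rate zero / empty rates: unchanged cohort
  same <- suppressMessages(punch_missingness(co, list(ca125 = 0), "mcar", 1))
  expect_identical(same, co)
  # MCAR 0.2: binomial count check
  p1 <- suppressMessages(punch_missingness(co, list(ca125 = 0.2), "mcar", 2))
  n_miss <- sum(is.na(p1$ca125))
  expect_gt(n_miss, qbinom(0.001, nrow(co), 0.2))
  expect_lt(n_miss, qbinom(0.999, nrow(co), 0.2))
  # MAR-on-class: class-specific ultrasound missingness
  p2 <- suppressMessages(punch_missingness(
    co, list(ultrasound = list(case = 0.06, control = 0.24)),
    "mar_on_class", 3))
  is_case <- co$ref_histology_category == "primary_invasive"
  f_case <- mean(p2$us_scan_available[is_case] == 0)
  f_ctrl <- mean(p2$us_scan_available[!is_case] == 0)
  expect_lt(abs(f_ctrl - 0.24), 3 * sqrt(0.24 * 0.76 / sum(!is_case)))
  expect_lt(abs(f_case - 0.06), 3 * sqrt(0.06 * 0.94 / sum(is_case)))
  expect_gt(f_ctrl, f_case)
})

test_that("simple-rules inconclusive fraction sits near its target", {
  fracs <- vapply(1:5, function(i) {
    co <- suppressMessages(generate_cohort(synthetic_config(seed = 200 + i)))
    pre <- co[co$cohort_tag == "pre_change", ]
    oc <- derive_outcome(pre, "primary")
    sc <- score_cohort(pre)
    st <- apply_thresholds(sc)
    s <- st$state[st$test_id == "simple_rules"][oc != "excluded"]
    mean(s == "inconclusive")
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.15), 0.05)
})

test_that("an embedded true risk model has known downstream behaviour", {
  cfg <- synthetic_config(seed = 9)
  co <- suppressMessages(generate_cohort(cfg))
  # constant risk: prevalence ~ p, C index ~ 1/2
  co1 <- embed_true_model(co, rep(0.2, nrow(co)), seed = 1)
  prev <- mean(co1$ref_histology_category == "primary_invasive")
  expect_lt(abs(prev - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(co)))
  ci <- c_index(runif(nrow(co1)),
                as.integer(co1$ref_histology_category == "primary_invasive"))
  expect_lt(abs(ci$estimate - 0.5), 4 * ci$se)
  # two-point risk mixture: C index approaches the analytic pair probability
  set.seed(2)
  risks <- sample(c(0.01, 0.9), 20000, replace = TRUE)
  y <- as.integer(runif(20000) < risks)
  # analytic: P(risk=.9 | case), P(risk=.9 | control)
  p1 <- 0.9 * 0.5 / (0.5 * (0.9 + 0.01))
  p0 <- 0.1 * 0.5 / (1 - 0.5 * (0.9 + 0.01))
  analytic <- p1 * (1 - p0) + 0.5 * (p1 * p0 + (1 - p1) * (1 - p0))
  got <- c_index(risks, y)$estimate
  expect_lt(abs(got - analytic), 0.02)
})
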
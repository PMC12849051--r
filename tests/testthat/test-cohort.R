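# cohort data model: CSV round trip, menopausal rule table, outcome labels

test_that("cohort CSV round trip preserves values and missingness conventions", {
  co <- make_mini_cohort()
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), nrow(co))
  expect_equal(back$participant_id, co$participant_id)
  expect_equal(back$ca125, co$ca125)          # NA cell stays missing
  expect_equal(back$us_max_lesion_diameter, co$us_max_lesion_diameter)
  expect_equal(back$ref_histology_category, co$ref_histology_category)
  expect_true(is.na(back$ca125[3]))
})

test_that("schema and integrity errors name the problem", {
  co <- make_mini_cohort()
  path <- tempfile(fileext = ".csv")
  write_cohort(co[, setdiff(names(co), "age")], path)
  expect_error(read_cohort(path), "age")
  co2 <- co
  co2$participant_id[2] <- co2$participant_id[1]
  write_cohort(co2, path)
  expect_error(read_cohort(path), "duplicate")
  # unparseable numeric cell becomes missing with a warning, rows preserved
  co3 <- co
  co3$ca125 <- as.character(co3$ca125)
  co3$ca125[1] <- "not-a-number"
  utils::write.csv(co3, path, row.names = FALSE, na = "NA")
  expect_warning(back <- read_cohort(path), "ca125")
  expect_equal(nrow(back), nrow(co))
  expect_true(is.na(back$ca125[1]))
})

test_that("cohort invariants are enforced", {
  co <- make_mini_cohort()
  co$age[1] <- -1
  expect_error(validate_cohort(co), "age")
  co <- make_mini_cohort()
  co$ca125[1] <- -5
  expect_error(validate_cohort(co), "ca125")
  co <- make_mini_cohort()
  co$cohort_tag[1] <- NA
  expect_error(validate_cohort(co), "cohort_tag")
  co <- make_mini_cohort()
  co$us_max_solid_diameter[1] <- 999
  expect_warning(validate_cohort(co), "clipped")
})

test_that("menopausal classification follows the documented rule table", {
  expect_equal(classify_menopause(44, "yes", "unknown"), "premenopausal")
  expect_equal(classify_menopause(70, "no", "unknown"), "postmenopausal")
  # perimenopausal re-categorisation by bleeding history
  expect_equal(classify_menopause(50, "unknown", "yes"), "premenopausal")
  expect_equal(classify_menopause(50, "unknown", "no"), "postmenopausal")
  expect_error(classify_menopause(NA, "unknown", "unknown"), "unknown")

  # exhaustive cross-check of the rule table over the full input grid:
  # an independent oracle restates the five ordered rules one case at a time
  oracle <- function(age, menst, bleed) {
    if (age < 50 && menst == "yes") return("premenopausal")
    if (age >= 51 && menst == "no") return("postmenopausal")
    if (bleed == "yes") return("premenopausal")
    if (bleed == "no") return("postmenopausal")
    if (menst == "yes") return("premenopausal")
    if (menst == "no") return("postmenopausal")
    if (age < 50) "premenopausal" else "postmenopausal"
  }
  grid <- expand.grid(age = c(30, 49.9, 50, 50.5, 51, 70),
                      menst = c("yes", "no", "unknown"),
                      bleed = c("yes", "no", "unknown"),
                      stringsAsFactors = FALSE)
  got <- classify_menopause(grid$age, grid$menst, grid$bleed)
  want <- mapply(oracle, grid$age, grid$menst, grid$bleed)
  expect_equal(got, unname(want))
})

test_that("outcome labels follow the three definitions", {
  hist <- c("primary_invasive", "borderline", "secondary_metastatic",
            "benign", "normal", "uncertain_behaviour", "no_histology",
            "missing")
  co <- data.frame(ref_histology_category = hist,
                   ref_followup_cancer = "unknown",
                   stringsAsFactors = FALSE)
  expect_equal(derive_outcome(co, "primary"),
               c("positive", "excluded", "excluded", "negative", "negative",
                 "excluded", "excluded", "excluded"))
  expect_equal(derive_outcome(co, "secondary_any_cancer"),
               c("positive", "positive", "positive", "negative", "negative",
                 "positive", "excluded", "excluded"))
  # borderline grouped with benign in the sensitivity-analysis definition
  expect_equal(derive_outcome(co, "secondary_borderline_as_benign")[2],
               "negative")
  # completed negative surveillance resolves missing histology to negative
  co$ref_followup_cancer <- "no"
  expect_equal(derive_outcome(co, "primary")[7:8], rep("negative", 2))
  # unknown category is a data error
  co2 <- data.frame(ref_histology_category = "weird",
                    ref_followup_cancer = "unknown")
  expect_error(derive_outcome(co2, "primary"), "histology")
})

test_that("outcome labels partition every cohort and nest across definitions", {
  co <- suppressMessages(generate_cohort(synthetic_config(seed = 7)))
  for (def in c("primary", "secondary_any_cancer",
                "secondary_borderline_as_benign")) {
    oc <- derive_outcome(co, def)
    expect_equal(sum(oc == "positive") + sum(oc == "negative") +
                   sum(oc == "excluded"), nrow(co))
  }
  prim <- derive_outcome(co, "primary")
  sec <- derive_outcome(co, "secondary_any_cancer")
  expect_true(all(sec[prim == "positive"] == "positive"))
})

test_that("cohort filtering subsets by protocol tag", {
  co <- suppressMessages(generate_cohort(synthetic_config(seed = 3)))
  expect_equal(nrow(suppressMessages(filter_cohort(co, "combined"))), 1211)
  expect_equal(nrow(suppressMessages(filter_cohort(co, "pre_change"))), 857)
  expect_equal(nrow(suppressMessages(filter_cohort(co, "post_change"))), 354)
  pre <- co[co$cohort_tag == "pre_change", ]
  expect_warning(suppressMessages(filter_cohort(pre, "post_change")),
                 "no records")
})

test_that("data quality report counts missingness per column", {
  co <- make_mini_cohort()
  rep <- data_quality_report(co)
  expect_equal(rep$n_records, 6)
  expect_equal(rep$missingness$n_missing[rep$missingness$column == "ca125"], 1L)
})
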
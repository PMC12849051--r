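# Fixtures built in code: a small hand-written cohort, synthetic coefficient
# sets with known values, and a builder that expands 2x2 counts into
# per-participant records whose scores reproduce those counts end to end.

# a 6-row cohort exercising all column types
make_mini_cohort <- function() {
  co <- data.frame(
    participant_id = paste0("W", 1:6),
    age = c(44, 70, 50, 38, 47, 52),
    menstruated_last_12m = c("yes", "no", "unknown", "yes", "yes", "no"),
    vaginal_bleeding_history = c("unknown", "no", "yes", "unknown", "yes", "no"),
    ca125 = c(100, 84, NA, 30, 500, 60),
    he4 = c(60, 45, 80, 40, 300, 50),
    centre_type = c("oncology", "non_oncology", "oncology", "non_oncology",
                    "oncology", "oncology"),
    cohort_tag = c(rep("pre_change", 4), rep("post_change", 2)),
    stringsAsFactors = FALSE
  )
  co$menopausal_status <- classify_menopause(
    co$age, co$menstruated_last_12m, co$vaginal_bleeding_history)
  us <- data.frame(
    us_lesion_present = c(1, 1, 1, 0, 1, 1),
    us_multilocular = c(1, 0, 1, 0, 1, 0),
    us_solid_areas = c(0, 0, 1, 0, 1, 0),
    us_bilateral = c(0, 0, 0, 0, 1, 0),
    us_ascites = c(0, 1, 0, 0, 1, 0),
    us_metastases = c(0, 0, 0, 0, 1, 0),
    us_more_than_10_locules = c(0, 0, 1, 0, 0, 0),
    us_acoustic_shadows = c(0, 1, 0, 0, 0, 0)
  )
  for (j in 1:5) us[[paste0("us_b", j)]] <- 0L
  for (j in 1:5) us[[paste0("us_m", j)]] <- 0L
  us$us_b1 <- c(1, 1, 0, 1, 0, 1)
  us$us_m1 <- c(0, 0, 1, 0, 1, 0)
  us$us_scan_available <- 1L
  us$us_max_lesion_diameter <- c(60, 40, 90, NA, 120, 35)
  us$us_max_solid_diameter <- c(0, 0, 30, NA, 80, 0)
  us$us_papillation_count <- c(0L, 0L, 2L, 0L, 5L, 0L)
  co <- cbind(co, us)
  co$ref_source <- c("surgery", "surgery", "surgery", "follow_up",
                     "surgery", "surgery")
  co$ref_histology_category <- c("benign", "normal", "borderline",
                                 "no_histology", "primary_invasive", "benign")
  co$ref_figo_stage <- c(NA, NA, NA, NA, 3L, NA)
  co$ref_followup_cancer <- c("unknown", "unknown", "unknown", "no",
                              "unknown", "unknown")
  co
}

# synthetic coefficient sets with simple, known values
toy_roma_coefs <- function(int_pre = 0, a_pre = 1, b_pre = 1,
                           int_post = 1, a_post = 1, b_post = 1) {
  coefficient_set("roma", "toy",
    strata = list(
      premenopausal = c(intercept = int_pre, log_he4 = a_pre,
                        log_ca125 = b_pre),
      postmenopausal = c(intercept = int_post, log_he4 = a_post,
                         log_ca125 = b_post)),
    transforms = c(log_he4 = "log", log_ca125 = "log"),
    source_citation = "synthetic test set")
}

toy_srrisk_coefs <- function(intercept = -2, b = rep(-1, 5), m = rep(1, 5),
                             onc = 0.5) {
  cf <- c(intercept = intercept, stats::setNames(b, paste0("b", 1:5)),
          stats::setNames(m, paste0("m", 1:5)), oncology_centre = onc)
  coefficient_set("simple_rules_risk", "toy", strata = list(all = cf),
                  transforms = c(oncology_centre = "identity"),
                  source_citation = "synthetic test set")
}

toy_adnex_coefs <- function(zero = FALSE) {
  base <- c(intercept = 0, age = 0, log_ca125 = 0, log_max_diameter = 0,
            prop_solid = 0, more_than_10_locules = 0, papillation_count = 0,
            acoustic_shadows = 0, ascites = 0, oncology_centre = 0)
  mk <- function(int, ca) { v <- base; v["intercept"] <- int;
                            v["log_ca125"] <- ca; v }
  strata <- if (zero) {
    list(borderline = base, stage1 = base, stage2_4 = base, metastatic = base)
  } else {
    list(borderline = mk(-2, 0.3), stage1 = mk(-3, 0.5),
         stage2_4 = mk(-5, 1.0), metastatic = mk(-4, 0.4))
  }
  coefficient_set("adnex", "toy", strata = strata,
                  transforms = c(log_ca125 = "log"),
                  source_citation = "synthetic test set")
}

# expand a 2x2 (plus missing counts) into aligned state/outcome vectors
states_from_counts <- function(tp, fp, fn, tn, miss_case = 0, miss_ctrl = 0,
                               inc_case = 0, inc_ctrl = 0) {
  states <- c(rep("positive", tp), rep("negative", fn),
              rep("inconclusive", inc_case), rep("missing", miss_case),
              rep("positive", fp), rep("negative", tn),
              rep("inconclusive", inc_ctrl), rep("missing", miss_ctrl))
  outcomes <- c(rep("positive", tp + fn + inc_case + miss_case),
                rep("negative", fp + tn + inc_ctrl + miss_ctrl))
  list(states = states, outcomes = outcomes)
}

# brute-force all-pairs concordance oracle (ties count one half)
pair_count_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
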
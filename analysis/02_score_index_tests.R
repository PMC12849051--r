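#!/usr/bin/env Rscript
# Stage 2: compute the six index-test scores plus the ORADS category for
# every participant: RMI 1 (U score x menopausal multiplier x CA 125), ROMA
# (menopause-stratified logistic on ln HE4, ln CA 125), IOTA ADNEX total
# malignancy risk, IOTA simple rules category and its risk model, serum
# CA 125, and the mapped ORADS category. Missing required predictors give
# missing scores -- nothing is imputed at this stage.

suppressMessages(library(ovatriage))

cohort <- read_cohort("results/cohort_synthetic.csv")
scores <- score_cohort(cohort)
utils::write.csv(scores, "results/scores.csv", row.names = FALSE)

states <- apply_thresholds(scores)
utils::write.csv(states, "results/test_states.csv", row.names = FALSE)

cat(sprintf("scored %d participants on %d test/threshold combinations\n",
            nrow(scores), length(unique(states$test_id))))
for (m in c("rmi1", "roma", "adnex", "srrisk")) {
  cat(sprintf("  %-7s available for %d participants\n", m,
              sum(!is.na(scores[[m]]))))
}
cat(sprintf("  simple rules: %d conclusive, %d inconclusive, %d missing\n",
            sum(scores$sr_category %in% c("benign", "malignant")),
            sum(scores$sr_category == "inconclusive", na.rm = TRUE),
            sum(is.na(scores$sr_category))))
cat("wrote results/scores.csv and results/test_states.csv\n")
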
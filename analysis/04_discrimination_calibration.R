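#!/usr/bin/env Rscript
# Stage 4: global accuracy. C index (with DeLong intervals) per continuous
# score, ROC point files for plotting, decile calibration tables and the
# logistic recalibration slope for the probability-scale models, plus a
# known-truth recovery check: outcomes re-simulated from the ADNEX model's
# own risks must give calibration slope ~ 1 and calibration-in-the-large ~ 0.

suppressMessages(library(ovatriage))

cohort <- read_cohort("results/cohort_synthetic.csv")
cohort <- suppressMessages(filter_cohort(cohort, "pre_change"))
outcome <- derive_outcome(cohort, "primary")
scores <- score_cohort(cohort)
y <- ifelse(outcome == "positive", 1L,
            ifelse(outcome == "negative", 0L, NA_integer_))

cat("discrimination (primary outcome, pre-change cohort):\n")
cindex_rows <- list()
for (m in c("rmi1", "roma", "adnex", "srrisk", "ca125")) {
  s <- scores[[m]]
  keep <- !is.na(s) & !is.na(y)
  ci <- c_index(s[keep], y[keep])
  cat(sprintf("  %-7s C index %.2f (%.2f to %.2f), n=%d\n", m, ci$estimate,
              ci$ci_low, ci$ci_high, sum(keep)))
  cindex_rows[[m]] <- data.frame(model = m, c_index = ci$estimate,
                                 ci_low = ci$ci_low, ci_high = ci$ci_high,
                                 n = sum(keep))
  roc <- roc_points(s[keep], y[keep])
  utils::write.csv(data.frame(threshold = roc$thresholds, tpr = roc$tpr,
                              fpr = roc$fpr),
                   sprintf("results/roc_%s.csv", m), row.names = FALSE)
}
utils::write.csv(do.call(rbind, cindex_rows), "results/c_index.csv",
                 row.names = FALSE)

cat("calibration of the probability models against the synthetic outcome:\n")
for (m in c("roma", "adnex", "srrisk")) {
  s <- scores[[m]] / 100
  keep <- !is.na(s) & !is.na(y)
  cal <- calibration_slope(s[keep], y[keep])
  cat(sprintf("  %-7s slope %.2f (%.2f to %.2f), in-the-large %.2f\n", m,
              cal$slope, cal$slope_ci[1], cal$slope_ci[2], cal$intercept))
  utils::write.csv(calibration_deciles(s[keep], y[keep]),
                   sprintf("results/calibration_deciles_%s.csv", m),
                   row.names = FALSE)
}

# recovery check with outcomes drawn from the model's own risks
risks <- scores$adnex / 100
keep <- !is.na(risks)
embedded <- embed_true_model(cohort[keep, ], risks[keep], seed = 20260104)
ye <- as.integer(embedded$ref_histology_category == "primary_invasive")
cal <- calibration_slope(embedded$true_risk, ye)
cat(sprintf("recovery check (outcomes ~ Bernoulli(model risk)): slope %.2f (%.2f to %.2f), in-the-large %.2f\n",
            cal$slope, cal$slope_ci[1], cal$slope_ci[2], cal$intercept))
cat("ROC and calibration tables written under results/\n")
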
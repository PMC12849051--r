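#!/usr/bin/env Rscript
# Stage 3: the head-to-head accuracy comparison on the pre-protocol-change
# cohort. For the primary outcome (primary invasive cancer vs benign/normal)
# and the secondary outcome (any cancer), every test is dichotomised at its
# pre-stated thresholds, 2x2 tables are built under the default policy
# (missing and inconclusive results excluded), and each test is compared
# with the standard-of-care comparator (RMI 1 at 250) by exact McNemar with
# Bonferroni-adjusted significance over the eleven pre-stated comparisons.

suppressMessages(library(ovatriage))

cfg <- pipeline_config(input = "results/cohort_synthetic.csv",
                       cohort_selector = "pre_change",
                       outcomes = c("primary", "secondary_any_cancer"),
                       output_dir = "results/accuracy_run")
res <- run_pipeline(cfg)

rep <- res$reports$primary
cat("primary outcome, pre-change cohort (complete-case):\n")
for (i in seq_len(nrow(rep))) {
  cat(sprintf("  %-13s sens %5.1f%%  spec %5.1f%%  ppv %5.1f%%  npv %5.1f%%",
              rep$test_id[i], rep$sensitivity[i], rep$specificity[i],
              rep$ppv[i], rep$npv[i]))
  if (!is.na(rep$delta_sens[i])) {
    cat(sprintf("  d_sens %+5.1f pp (P=%.3g%s)", rep$delta_sens[i],
                rep$p_sens[i],
                ifelse(isTRUE(rep$sens_significant[i]), " *", "")))
  }
  cat("\n")
}
cat(sprintf("Bonferroni-adjusted alpha: %.3f\n", rep$alpha_adjusted[1]))
cat("full tables in results/accuracy_run/\n")
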
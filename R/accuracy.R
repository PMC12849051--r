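# 2x2 accuracy tables with explicit missing/inconclusive policies,
# exact binomial confidence intervals, paired McNemar comparisons,
# Bonferroni multiplicity handling.

#' Construct a 2x2 accuracy table
#'
#' @param tp,fp,fn,tn Nonnegative integer cell counts.
#' @param n_missing_test,n_inconclusive Participants (with non-excluded
#'   outcome) whose test result was missing or inconclusive; excluded from
#'   the four cells under the default policy.
#' @param n_outcome_excluded Participants dropped because their outcome label
#'   was `"excluded"`.
#' @param test_id,outcome_definition Labels carried for reporting.
#' @return Object of class `two_by_two`.
#' @export
two_by_two <- function(tp, fp, fn, tn, n_missing_test = 0L,
                       n_inconclusive = 0L, n_outcome_excluded = 0L,
                       test_id = NA_character_,
                       outcome_definition = NA_character_) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn,
              n_missing_test = n_missing_test,
              n_inconclusive = n_inconclusive,
              n_outcome_excluded = n_outcome_excluded)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("two_by_two: all counts must be nonnegative integers")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n_missing_test = as.integer(n_missing_test),
                 n_inconclusive = as.integer(n_inconclusive),
                 n_outcome_excluded = as.integer(n_outcome_excluded),
                 test_id = test_id, outcome_definition = outcome_definition),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("2x2 table [%s vs %s outcome]\n", x$test_id,
              x$outcome_definition))
  cat(sprintf("  tp=%d fp=%d fn=%d tn=%d (missing=%d, inconclusive=%d, outcome-excluded=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n_missing_test, x$n_inconclusive,
              x$n_outcome_excluded))
  invisible(x)
}

#' Build a 2x2 table from per-participant test states and outcome labels
#'
#' Participants with an excluded outcome are dropped first; among the
#' remainder, missing and inconclusive test states are counted separately and
#' excluded from the four cells (the default policy, matching an analysis in
#' which women with missing index tests are excluded and inconclusive results
#' are classified neither positive nor negative). Alternative inconclusive
#' policies (`"positive"`, `"negative"`) are provided for sensitivity
#' analyses only.
#'
#' @param states Character vector per participant:
#'   positive/negative/inconclusive/missing.
#' @param outcomes Character vector per participant:
#'   positive/negative/excluded. Must be the same length (same participant
#'   order) as `states`.
#' @param inconclusive_policy `"exclude"` (default), `"positive"`,
#'   `"negative"`.
#' @param test_id,outcome_definition Labels for the table.
#' @return A [two_by_two()] object.
#' @export
build_two_by_two <- function(states, outcomes,
                             inconclusive_policy = c("exclude", "positive",
                                                     "negative"),
                             test_id = NA_character_,
                             outcome_definition = NA_character_) {
  inconclusive_policy <- match.arg(inconclusive_policy)
  if (length(states) != length(outcomes)) {
    stop("integrity error: test states and outcomes must be keyed by the ",
         "same participants (lengths differ)")
  }
  keep <- outcomes != "excluded"
  n_outcome_excluded <- sum(!keep)
  states <- states[keep]
  outcomes <- outcomes[keep]
  states[is.na(states)] <- "missing"
  if (inconclusive_policy != "exclude") {
    states[states == "inconclusive"] <- inconclusive_policy
  }
  n_missing <- sum(states == "missing")
  n_inconclusive <- sum(states == "inconclusive")
  conclusive <- states %in% c("positive", "negative")
  s <- states[conclusive]
  o <- outcomes[conclusive]
  two_by_two(tp = sum(s == "positive" & o == "positive"),
             fp = sum(s == "positive" & o == "negative"),
             fn = sum(s == "negative" & o == "positive"),
             tn = sum(s == "negative" & o == "negative"),
             n_missing_test = n_missing, n_inconclusive = n_inconclusive,
             n_outcome_excluded = n_outcome_excluded,
             test_id = test_id, outcome_definition = outcome_definition)
}

#' Binomial proportion with confidence interval
#'
#' Default method is the Clopper-Pearson exact interval (the method that
#' reproduces the published intervals, e.g. 20/47 gives 28.3-57.8\%); the
#' Wilson score interval is available as an option.
#'
#' @param numerator,denominator Counts, `0 <= numerator <= denominator`.
#' @param method `"clopper-pearson"` or `"wilson"`.
#' @param level Confidence level (default 0.95).
#' @param metric Optional metric label carried through.
#' @return List of class `accuracy_estimate`: `metric`, `point`, `ci_low`,
#'   `ci_high` (proportions), `numerator`, `denominator`, `ci_method`.
#'   A zero denominator returns an undefined-estimate marker (all NA) rather
#'   than an error.
#' @export
proportion_with_ci <- function(numerator, denominator,
                               method = c("clopper-pearson", "wilson"),
                               level = 0.95, metric = NA_character_) {
  method <- match.arg(method)
  if (denominator == 0) {
    return(structure(list(metric = metric, point = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          numerator = 0L, denominator = 0L,
                          ci_method = method, undefined = TRUE),
                     class = "accuracy_estimate"))
  }
  stopifnot(numerator >= 0, numerator <= denominator)
  k <- numerator; n <- denominator
  alpha <- 1 - level
  if (method == "clopper-pearson") {
    lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    p <- k / n
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- max(0, centre - half); hi <- min(1, centre + half)
  }
  structure(list(metric = metric, point = k / n, ci_low = lo, ci_high = hi,
                 numerator = as.integer(k), denominator = as.integer(n),
                 ci_method = method, undefined = FALSE),
            class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat(sprintf("%s: undefined (denominator 0)\n", x$metric))
  } else {
    cat(sprintf("%s: %.1f%% (95%% CI %.1f to %.1f; %d/%d, %s)\n", x$metric,
                100 * x$point, 100 * x$ci_low, 100 * x$ci_high,
                x$numerator, x$denominator, x$ci_method))
  }
  invisible(x)
}

#' Accuracy metrics for a 2x2 table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive predictive value
#' tp/(tp+fp), negative predictive value tn/(tn+fn), each with a CI from
#' [proportion_with_ci()]. Empty margins give undefined-estimate markers.
#'
#' @param table A [two_by_two()] object.
#' @param method,level Passed to [proportion_with_ci()].
#' @return Named list of `accuracy_estimate`s:
#'   `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
accuracy_metrics <- function(table, method = "clopper-pearson", level = 0.95) {
  stopifnot(inherits(table, "two_by_two"))
  list(
    sensitivity = proportion_with_ci(table$tp, table$tp + table$fn,
                                     method, level, "sensitivity"),
    specificity = proportion_with_ci(table$tn, table$tn + table$fp,
                                     method, level, "specificity"),
    ppv = proportion_with_ci(table$tp, table$tp + table$fp,
                             method, level, "ppv"),
    npv = proportion_with_ci(table$tn, table$tn + table$fn,
                             method, level, "npv")
  )
}

#' Exact two-sided binomial McNemar p value
#'
#' p = min(1, 2 P(X <= min(b, c))) with X ~ Binomial(b + c, 1/2); equals 1
#' when b = c = 0. Symmetric in (b, c).
#'
#' @param b,c Discordant pair counts.
#' @return p value in \[0, 1\].
#' @export
mcnemar_exact_p <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
}

# paired-difference estimate for one stratum (cases or controls):
# delta = comparator minus alternative, Wald CI with optional 1/n continuity
# correction, exact McNemar p from the discordant counts.
.paired_stratum <- function(comp_pos, test_pos, level, continuity) {
  n <- length(comp_pos)
  b <- sum(comp_pos & !test_pos)   # comparator positive only
  c <- sum(!comp_pos & test_pos)   # alternative positive only
  delta <- (b - c) / n
  se <- sqrt(max(0, (b + c) - (b - c)^2 / n)) / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  cc <- if (continuity) 1 / n else 0
  list(n = n, b = b, c = c, delta = delta,
       ci_low = delta - z * se - cc, ci_high = delta + z * se + cc,
       p_value = mcnemar_exact_p(b, c))
}

#' Paired comparison of two index tests (exact McNemar)
#'
#' Restricts to participants with a non-excluded outcome and conclusive
#' (positive/negative) results on both tests, then compares sensitivity
#' within cases and specificity within non-cases. The difference is reported
#' as comparator minus alternative (the published sign convention), with an
#' asymptotic Wald interval on the paired difference (1/n continuity
#' correction on by default, which is what reproduces the published
#' intervals) and the exact two-sided binomial McNemar p value.
#'
#' @param test_states Character states of the test under evaluation.
#' @param comparator_states Character states of the comparator test, same
#'   participant order.
#' @param outcomes Outcome labels (positive/negative/excluded).
#' @param test_id,comparator_id Labels.
#' @param level Confidence level.
#' @param continuity Logical: apply the 1/n continuity correction to the
#'   delta CIs (default TRUE).
#' @return Object of class `paired_comparison` with `n_common`, and per
#'   stratum (`sensitivity`, `specificity`): discordant counts, `delta`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
mcnemar_paired <- function(test_states, comparator_states, outcomes,
                           test_id = "test", comparator_id = "comparator",
                           level = 0.95, continuity = TRUE) {
  stopifnot(length(test_states) == length(comparator_states),
            length(test_states) == length(outcomes))
  conclusive <- function(s) !is.na(s) & s %in% c("positive", "negative")
  keep <- outcomes != "excluded" & conclusive(test_states) &
    conclusive(comparator_states)
  if (sum(keep) == 0) {
    stop("paired comparison error: no common participants with conclusive ",
         "results on both tests")
  }
  ts <- test_states[keep] == "positive"
  cs <- comparator_states[keep] == "positive"
  oc <- outcomes[keep]
  res <- list(test_id = test_id, comparator_id = comparator_id,
              n_common = sum(keep),
              sensitivity = .paired_stratum(cs[oc == "positive"],
                                            ts[oc == "positive"],
                                            level, continuity),
              specificity = .paired_stratum(!cs[oc == "negative"],
                                            !ts[oc == "negative"],
                                            level, continuity))
  structure(res, class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison: %s vs comparator %s (n=%d common)\n",
              x$test_id, x$comparator_id, x$n_common))
  for (m in c("sensitivity", "specificity")) {
    s <- x[[m]]
    cat(sprintf("  delta %s = %.1f pp (%.1f to %.1f), P=%.3g [b=%d, c=%d, n=%d]\n",
                m, 100 * s$delta, 100 * s$ci_low, 100 * s$ci_high,
                s$p_value, s$b, s$c, s$n))
  }
  invisible(x)
}

#' Bonferroni multiplicity adjustment
#'
#' The adjusted alpha is 0.05/n, except n = 11 where the published rounded
#' value 0.005 is used verbatim (0.05/11 = 0.00455 rounds up in the source
#' analysis). Flags are `p < alpha`.
#'
#' @param p_values Numeric p values.
#' @param n_comparisons Number of pairwise comparisons (>= 1).
#' @return List with `alpha` and logical `significant` flags.
#' @export
adjust_multiplicity <- function(p_values, n_comparisons) {
  stopifnot(n_comparisons >= 1)
  alpha <- if (n_comparisons == 11) 0.005 else 0.05 / n_comparisons
  list(alpha = alpha, significant = p_values < alpha)
}
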
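# Discrimination (ROC points, C index with DeLong interval) and calibration
# (decile agreement table, logistic recalibration slope and intercept).

#' Concordance index (AUC) with confidence interval
#'
#' Probability that a randomly chosen case receives a higher score than a
#' randomly chosen non-case, ties counted one half (equivalent to the area
#' under the ROC curve). Computed from midranks; the default CI uses the
#' DeLong variance estimate.
#'
#' @param scores Continuous risk scores (higher = more suspicious).
#' @param outcomes Binary outcomes: logical, 0/1, or
#'   `"positive"`/`"negative"` labels; other labels (e.g. `"excluded"`) and
#'   missing scores are dropped.
#' @param level Confidence level.
#' @param ci_method `"delong"` (only method implemented).
#' @return List of class `c_index`: `estimate`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`, `se`. Single-class input returns an
#'   undefined-estimate marker (`estimate = NA`).
#' @export
c_index <- function(scores, outcomes, level = 0.95, ci_method = "delong") {
  y <- .as_binary_outcome(outcomes)
  keep <- !is.na(scores) & !is.na(y)
  s <- scores[keep]; y <- y[keep]
  m <- sum(y == 1); n <- sum(y == 0)
  if (m == 0 || n == 0) {
    return(structure(list(estimate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, n_pos = m, n_neg = n,
                          se = NA_real_, undefined = TRUE),
                     class = "c_index"))
  }
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n)
  # DeLong: placement values of cases among controls and vice versa
  r_pos <- rank(s[y == 1], ties.method = "average")
  r_neg <- rank(s[y == 0], ties.method = "average")
  v10 <- (r[y == 1] - r_pos) / n          # P(score_neg < case), ties half
  v01 <- 1 - (r[y == 0] - r_neg) / m      # P(case > score_neg seen from controls)
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  se <- sqrt(var_auc)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(estimate = auc,
                 ci_low = max(0, auc - z * se),
                 ci_high = min(1, auc + z * se),
                 n_pos = m, n_neg = n, se = se, undefined = FALSE),
            class = "c_index")
}

#' @export
print.c_index <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("C index: undefined (single-class input)\n")
  } else {
    cat(sprintf("C index %.3f (95%% CI %.3f to %.3f; %d cases, %d non-cases)\n",
                x$estimate, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  }
  invisible(x)
}

.as_binary_outcome <- function(outcomes) {
  if (is.logical(outcomes)) return(as.integer(outcomes))
  if (is.numeric(outcomes)) {
    stopifnot(all(outcomes %in% c(0, 1, NA)))
    return(as.integer(outcomes))
  }
  ifelse(outcomes == "positive", 1L,
         ifelse(outcomes == "negative", 0L, NA_integer_))
}

#' Empirical ROC curve points
#'
#' One point per distinct score value plus the (0,0) and (1,1) endpoints,
#' ordered from the strictest threshold down. The trapezoidal area under
#' these points equals the midrank C index exactly.
#'
#' @inheritParams c_index
#' @return List of class `roc_curve`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_points <- function(scores, outcomes) {
  y <- .as_binary_outcome(outcomes)
  keep <- !is.na(scores) & !is.na(y)
  s <- scores[keep]; y <- y[keep]
  m <- sum(y == 1); n <- sum(y == 0)
  if (m == 0 || n == 0) stop("roc_points: need both classes present")
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  distinct <- !duplicated(s)
  # cumulative counts at each distinct threshold (score >= threshold positive)
  ctp <- cumsum(y == 1)
  cfp <- cumsum(y == 0)
  idx <- which(c(distinct[-1], TRUE))  # last index of each distinct score block
  tpr <- c(0, ctp[idx] / m)
  fpr <- c(0, cfp[idx] / n)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[distinct]), tpr = tpr, fpr = fpr,
                 auc = auc),
            class = "roc_curve")
}

#' Decile calibration table
#'
#' Participants are sorted by predicted risk and split into ten near-equal
#' groups; ties on risk stay in the same group, with sizes rebalanced
#' greedily (groups absorb whole tie blocks; a tie block is assigned to the
#' group its midpoint falls in). For fewer than 10 observations the split
#' falls back to quintiles with a warning.
#'
#' @param risks Predicted risks as probabilities in \[0, 1\].
#' @param outcomes Binary outcomes (see [c_index()]).
#' @param groups Number of groups (default 10).
#' @return Data frame: `group`, `n`, `mean_predicted`, `observed`.
#' @export
calibration_deciles <- function(risks, outcomes, groups = 10) {
  y <- .as_binary_outcome(outcomes)
  keep <- !is.na(risks) & !is.na(y)
  r <- risks[keep]; y <- y[keep]
  stopifnot(all(r >= 0 & r <= 1))
  if (length(r) < groups) {
    warning("fewer observations than groups; falling back to quintiles",
            call. = FALSE)
    groups <- 5
  }
  ord <- order(r)
  r <- r[ord]; y <- y[ord]
  n <- length(r)
  # nominal group of each sorted position, then force ties into one group
  g <- ceiling(seq_len(n) / n * groups)
  blocks <- split(seq_len(n), match(r, unique(r)))
  for (b in blocks) {
    g[b] <- g[b[ceiling(length(b) / 2)]]
  }
  agg <- lapply(split(seq_len(n), g), function(i) {
    data.frame(n = length(i), mean_predicted = mean(r[i]),
               observed = mean(y[i]))
  })
  out <- do.call(rbind, agg)
  out <- cbind(group = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Logistic recalibration slope and calibration-in-the-large
#'
#' Fits `outcome ~ logit(risk)` by logistic regression: the slope is the
#' calibration slope (1 = agreement between predicted and observed risks on
#' the logit scale). Calibration-in-the-large is the intercept of an
#' intercept-only logistic model with `logit(risk)` as offset (0 = mean
#' predicted risk matches observed prevalence). Risks are clipped into
#' (epsilon, 1 - epsilon) before the logit.
#'
#' @param risks Predicted probabilities.
#' @param outcomes Binary outcomes.
#' @param level Confidence level for the slope interval.
#' @param epsilon Clipping bound before the logit (default 1e-6).
#' @return List of class `calibration_report`: `slope`, `slope_ci`,
#'   `intercept` (calibration-in-the-large), `intercept_ci`, `converged`,
#'   `flagged` (TRUE when the predictor is degenerate or the fit did not
#'   converge).
#' @export
calibration_slope <- function(risks, outcomes, level = 0.95,
                              epsilon = 1e-6) {
  y <- .as_binary_outcome(outcomes)
  keep <- !is.na(risks) & !is.na(y)
  r <- pmin(pmax(risks[keep], epsilon), 1 - epsilon)
  y <- y[keep]
  lp <- stats::qlogis(r)
  if (stats::var(lp) == 0) {
    return(structure(list(slope = NA_real_, slope_ci = c(NA_real_, NA_real_),
                          intercept = NA_real_,
                          intercept_ci = c(NA_real_, NA_real_),
                          converged = FALSE, flagged = TRUE),
                     class = "calibration_report"))
  }
  fit <- stats::glm(y ~ lp, family = stats::binomial())
  citl_fit <- stats::glm(y ~ 1 + offset(lp), family = stats::binomial())
  z <- stats::qnorm(1 - (1 - level) / 2)
  sl <- unname(stats::coef(fit)["lp"])
  sl_se <- sqrt(stats::vcov(fit)["lp", "lp"])
  ci <- unname(stats::coef(citl_fit)[1])
  ci_se <- sqrt(stats::vcov(citl_fit)[1, 1])
  structure(list(slope = sl, slope_ci = c(sl - z * sl_se, sl + z * sl_se),
                 intercept = ci,
                 intercept_ci = c(ci - z * ci_se, ci + z * ci_se),
                 converged = fit$converged && citl_fit$converged,
                 flagged = !(fit$converged && citl_fit$converged)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  if (isTRUE(x$flagged)) {
    cat("Calibration: flagged (degenerate predictor or non-convergence)\n")
  } else {
    cat(sprintf("Calibration slope %.2f (%.2f to %.2f); calibration-in-the-large %.2f (%.2f to %.2f)\n",
                x$slope, x$slope_ci[1], x$slope_ci[2],
                x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  }
  invisible(x)
}
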
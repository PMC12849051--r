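# Multiple imputation by chained equations for index-test predictors,
# and Rubin-rules pooling of accuracy estimates across imputations.
# Conditional models: predictive mean matching (k nearest donors) for
# continuous variables, Bayesian-draw logistic regression for binary flags.

#' Specify a chained-equations imputation run
#'
#' @param variables Character vector of cohort columns to impute. Each must
#'   have a conditional model: continuous columns use predictive mean
#'   matching, 0/1 flag columns use logistic regression (auto-detected unless
#'   given in `models`).
#' @param m Number of imputed datasets (>= 2; default 10).
#' @param iterations Chained-equation cycles per dataset (default 10).
#' @param predictors Character vector of fully observed columns used as
#'   predictors in every conditional model. The outcome label is included by
#'   default (standard practice for imputation in accuracy studies); pass a
#'   predictor set without it to switch that off.
#' @param models Optional named character vector overriding the per-variable
#'   model (`"pmm"` or `"logistic"`).
#' @param donors Number of donors for predictive mean matching (default 5).
#' @param seed Integer seed; the run is reproducible given the seed.
#' @return List of class `imputation_spec`.
#' @export
imputation_spec <- function(variables, m = 10, iterations = 10,
                            predictors = character(), models = NULL,
                            donors = 5, seed = 1L) {
  stopifnot(m >= 2, iterations >= 1, length(variables) >= 1)
  structure(list(variables = variables, m = m, iterations = iterations,
                 predictors = predictors, models = models, donors = donors,
                 seed = as.integer(seed)),
            class = "imputation_spec")
}

.impute_model_for <- function(x, name, override) {
  if (!is.null(override) && name %in% names(override)) return(override[[name]])
  obs <- x[!is.na(x)]
  if (all(obs %in% c(0, 1))) "logistic" else "pmm"
}

# Bayesian-ish parameter draw for a fitted lm: beta* ~ N(beta, sigma*^2 (X'X)^-1),
# sigma*^2 = sigma^2 * df / chi2(df)
.draw_lm <- function(fit) {
  beta <- stats::coef(fit)
  V <- stats::vcov(fit) / stats::sigma(fit)^2
  df <- fit$df.residual
  sigma_star <- stats::sigma(fit) * sqrt(df / stats::rchisq(1, df))
  ch <- chol(V * sigma_star^2)
  list(beta = beta + as.vector(t(ch) %*% stats::rnorm(length(beta))),
       sigma = sigma_star)
}

.draw_glm <- function(fit) {
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(beta)
  beta + as.vector(t(ch) %*% stats::rnorm(length(beta)))
}

# one conditional-model update of variable `v` given current completed data
.impute_one <- function(data, v, predictors, model, donors) {
  mis <- is.na(data[[paste0(".orig_", v)]])
  if (!any(mis)) return(data)
  rhs <- if (length(predictors) > 0) {
    paste(predictors, collapse = " + ")
  } else "1"
  fml <- stats::as.formula(paste(v, "~", rhs))
  obs_idx <- which(!mis)
  if (model == "pmm") {
    fit <- stats::lm(fml, data = data[obs_idx, , drop = FALSE])
    dr <- .draw_lm(fit)
    X <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                             data = data)
    yhat_obs <- as.vector(X[obs_idx, , drop = FALSE] %*% stats::coef(fit))
    yhat_mis <- as.vector(X[mis, , drop = FALSE] %*% dr$beta)
    obs_vals <- data[[v]][obs_idx]
    filled <- vapply(yhat_mis, function(p) {
      d <- abs(yhat_obs - p)
      pool <- order(d)[seq_len(min(donors, length(d)))]
      obs_vals[sample(pool, 1)]
    }, numeric(1))
    data[[v]][mis] <- filled
  } else {
    fit <- suppressWarnings(
      stats::glm(fml, family = stats::binomial(),
                 data = data[obs_idx, , drop = FALSE]))
    beta <- .draw_glm(fit)
    X <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                             data = data)
    p <- stats::plogis(as.vector(X[mis, , drop = FALSE] %*% beta))
    data[[v]][mis] <- as.numeric(stats::runif(sum(mis)) < p)
  }
  data
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of the cohort in which every covered
#' variable has its missing cells filled by iterated conditional draws;
#' observed cells are never altered. Derived risk scores are *not* imputed:
#' recompute them per completed dataset with [score_cohort()].
#'
#' @param cohort Cohort data frame.
#' @param spec An [imputation_spec()].
#' @return List of `m` completed data frames.
#' @export
mice_impute <- function(cohort, spec) {
  stopifnot(inherits(spec, "imputation_spec"))
  vars <- spec$variables
  absent <- setdiff(vars, names(cohort))
  if (length(absent) > 0) {
    stop("imputation error: variable(s) not in cohort: ",
         paste(absent, collapse = ", "))
  }
  for (v in vars) {
    if (all(is.na(cohort[[v]]))) {
      stop("imputation error: variable '", v, "' is 100% missing")
    }
  }
  other_missing <- setdiff(names(which(vapply(cohort, anyNA, logical(1)))),
                           c(vars, "menopausal_status"))
  preds <- setdiff(spec$predictors, vars)
  bad_pred <- preds[vapply(preds, function(p) anyNA(cohort[[p]]), logical(1))]
  if (length(bad_pred) > 0) {
    stop("imputation error: predictor(s) with missing values: ",
         paste(bad_pred, collapse = ", "))
  }
  models <- vapply(vars, function(v)
    .impute_model_for(cohort[[v]], v, spec$models), character(1))
  set.seed(spec$seed)
  no_missing <- !any(vapply(vars, function(v) anyNA(cohort[[v]]), logical(1)))
  out <- vector("list", spec$m)
  for (i in seq_len(spec$m)) {
    data <- cohort
    for (v in vars) data[[paste0(".orig_", v)]] <- cohort[[v]]
    # initial fill: random draw from the observed margin
    for (v in vars) {
      mis <- is.na(data[[v]])
      if (any(mis)) {
        data[[v]][mis] <- sample(data[[v]][!mis], sum(mis), replace = TRUE)
      }
    }
    if (!no_missing) {
      for (it in seq_len(spec$iterations)) {
        for (v in vars) {
          data <- .impute_one(data, v,
                              predictors = c(preds, setdiff(vars, v)),
                              model = models[[v]], donors = spec$donors)
        }
      }
    }
    data <- data[, !startsWith(names(data), ".orig_"), drop = FALSE]
    out[[i]] <- data
  }
  out
}

#' Pool accuracy proportions across imputations with Rubin's rules
#'
#' Pools on the logit scale: each per-imputation proportion k/n becomes
#' logit(p) with variance 1/k + 1/(n - k); degenerate proportions (0 or 1)
#' are continuity-adjusted to (k + 0.5)/(n + 1) and flagged. The pooled
#' total variance is W + (1 + 1/m) B; the CI is back-transformed.
#'
#' @param estimates List of `accuracy_estimate`s (same metric), or a data
#'   frame with columns `numerator` and `denominator`.
#' @param level Confidence level.
#' @return List of class `pooled_estimate`: `metric`, `pooled_point`,
#'   `ci_low`, `ci_high`, `within_var`, `between_var`, `total_var`,
#'   `m_used`, `flagged`.
#' @export
pool_accuracy <- function(estimates, level = 0.95) {
  if (is.data.frame(estimates)) {
    ks <- estimates$numerator; ns <- estimates$denominator
    metric <- NA_character_
  } else {
    stopifnot(length(estimates) >= 2)
    ks <- vapply(estimates, function(e) e$numerator, numeric(1))
    ns <- vapply(estimates, function(e) e$denominator, numeric(1))
    metric <- estimates[[1]]$metric
  }
  m <- length(ks)
  stopifnot(m >= 2)
  degenerate <- ks == 0 | ks == ns
  p <- ifelse(degenerate, (ks + 0.5) / (ns + 1), ks / ns)
  theta <- stats::qlogis(p)
  u <- ifelse(degenerate,
              1 / (ns * p * (1 - p)),
              1 / ks + 1 / (ns - ks))
  qbar <- mean(theta)
  w <- mean(u)
  b <- if (m > 1) stats::var(theta) else 0
  total <- w + (1 + 1 / m) * b
  # Rubin degrees of freedom; infinite when between-variance is zero
  df <- if (b > 0) (m - 1) * (1 + w / ((1 + 1 / m) * b))^2 else Inf
  tq <- if (is.finite(df)) stats::qt(1 - (1 - level) / 2, df) else
    stats::qnorm(1 - (1 - level) / 2)
  structure(list(metric = metric,
                 pooled_point = stats::plogis(qbar),
                 ci_low = stats::plogis(qbar - tq * sqrt(total)),
                 ci_high = stats::plogis(qbar + tq * sqrt(total)),
                 within_var = w, between_var = b, total_var = total,
                 m_used = m, flagged = any(degenerate)),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled %s: %.1f%% (%.1f to %.1f) over m=%d imputations%s\n",
              x$metric, 100 * x$pooled_point, 100 * x$ci_low,
              100 * x$ci_high, x$m_used,
              if (x$flagged) " [degenerate proportions adjusted]" else ""))
  invisible(x)
}
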
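# Index-test scorers: RMI 1, ROMA, IOTA simple rules (+ risk model),
# IOTA ADNEX, serum CA 125, and the post hoc ORADS category mapping.
# Model coefficients live in versioned JSON files (see coefficient_set);
# scorers never impute -- any missing required predictor gives a missing score.

#' Construct a versioned coefficient set for a risk model
#'
#' A coefficient set carries the parameters of a published (or synthetic)
#' logistic / multinomial-logistic risk model: per-stratum named coefficients,
#' per-predictor transform tags, and a source citation. The ROMA set is
#' stratified by menopausal status; the ADNEX set's "strata" are the four
#' malignant outcome classes of its multinomial model (benign is the
#' reference class).
#'
#' @param model_id One of `"roma"`, `"adnex"`, `"simple_rules_risk"`.
#' @param version_label Nonempty version string.
#' @param strata Named list of strata; each stratum is a named numeric vector
#'   of coefficients including `"intercept"`.
#' @param transforms Named character vector mapping predictor names to
#'   transform tags (`"identity"`, `"log"`); logs are natural and taken on the
#'   raw measurement scale (IU/mL, pmol/L, mm).
#' @param source_citation Provenance string; synthetic sets say so.
#' @return Object of class `coefficient_set`.
#' @export
coefficient_set <- function(model_id, version_label, strata, transforms,
                            source_citation = "unspecified") {
  stopifnot(model_id %in% c("roma", "adnex", "simple_rules_risk"),
            is.character(version_label), nzchar(version_label),
            is.list(strata), length(strata) >= 1)
  required <- .model_predictors(model_id)
  for (st in names(strata)) {
    coefs <- strata[[st]]
    if (!is.numeric(coefs) || is.null(names(coefs))) {
      stop("coefficient configuration error: stratum '", st,
           "' must be a named numeric vector")
    }
    miss <- setdiff(c("intercept", required), names(coefs))
    if (length(miss) > 0) {
      stop("coefficient configuration error: model '", model_id,
           "' stratum '", st, "' lacks coefficient(s): ",
           paste(miss, collapse = ", "))
    }
    if (anyDuplicated(names(coefs))) {
      stop("coefficient configuration error: duplicated coefficient names in '",
           st, "'")
    }
  }
  structure(list(model_id = model_id, version_label = version_label,
                 strata = strata, transforms = transforms,
                 source_citation = source_citation),
            class = "coefficient_set")
}

# predictors each model's functional form requires (besides the intercept)
.model_predictors <- function(model_id) {
  switch(model_id,
    roma = c("log_he4", "log_ca125"),
    simple_rules_risk = c(paste0("b", 1:5), paste0("m", 1:5), "oncology_centre"),
    adnex = c("age", "log_ca125", "log_max_diameter", "prop_solid",
              "more_than_10_locules", "papillation_count", "acoustic_shadows",
              "ascites", "oncology_centre"))
}

#' Load a coefficient set from a JSON file
#'
#' @param path Path to a JSON file with fields `model_id`, `version_label`,
#'   `strata`, `transforms`, `source_citation`.
#' @return A [coefficient_set()].
#' @export
load_coefficient_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  strata <- lapply(obj$strata, function(s) unlist(s))
  coefficient_set(obj$model_id, obj$version_label, strata,
                  unlist(obj$transforms), obj$source_citation)
}

#' Default coefficient registry shipped with the package
#'
#' ROMA coefficients are transcribed from the original publication
#' (Moore et al. 2009). No comparable transcription is shipped for ADNEX or
#' the simple rules risk model: their defaults are synthetic coefficient sets
#' (filenames and citations say so) calibrated once to give qualitatively
#' realistic behaviour on the synthetic cohort. Swap in transcribed sets via
#' [load_coefficient_set()] when licensed model parameters are available.
#'
#' @return Named list of [coefficient_set()] objects
#'   (`roma`, `adnex`, `simple_rules_risk`).
#' @export
default_coefficients <- function() {
  dir <- system.file("extdata", "coefficients", package = "ovatriage")
  list(
    roma = load_coefficient_set(file.path(dir, "roma_moore2009_v1.json")),
    adnex = load_coefficient_set(file.path(dir, "adnex_synthetic_v1.json")),
    simple_rules_risk =
      load_coefficient_set(file.path(dir, "srrisk_synthetic_v1.json"))
  )
}

#' Ultrasound U score for the Risk of Malignancy Index
#'
#' One point for each of: multilocular cysts, solid areas, metastases,
#' ascites, bilateral lesions. U = 0 for a raw count of 0, U = 1 for a count
#' of 1, U = 3 for counts 2 to 5. Any unknown flag gives a missing score.
#'
#' @param multilocular,solid_areas,metastases,ascites,bilateral 0/1 flags.
#' @return Integer vector with values 0, 1, 3 or NA.
#' @export
compute_u_score <- function(multilocular, solid_areas, metastases, ascites,
                            bilateral) {
  count <- multilocular + solid_areas + metastases + ascites + bilateral
  u <- ifelse(count == 0L, 0L, ifelse(count == 1L, 1L, 3L))
  as.integer(u)
}

#' Risk of Malignancy Index 1
#'
#' RMI = U x M x CA125, where U is the ultrasound score
#' ([compute_u_score()]) and M = 1 for premenopausal, 3 for postmenopausal
#' women. Unitless product; commonly dichotomised at 200 or 250.
#'
#' @param ca125 Serum CA 125 in IU/mL (>= 0).
#' @param u U score (0, 1 or 3).
#' @param menopausal_status `"premenopausal"` or `"postmenopausal"`.
#' @return Numeric RMI scores (NA where any input is missing).
#' @export
compute_rmi <- function(ca125, u, menopausal_status) {
  if (any(!is.na(ca125) & ca125 < 0)) stop("ca125 must be nonnegative")
  m <- ifelse(menopausal_status == "premenopausal", 1,
       ifelse(menopausal_status == "postmenopausal", 3, NA_real_))
  u * m * ca125
}

#' Risk of Malignancy Algorithm (ROMA)
#'
#' Menopause-stratified logistic index on the natural logs of HE4 and CA 125:
#' PI = intercept + a ln(HE4) + b ln(CA125) for the participant's stratum,
#' reported as ROMA\% = 100 exp(PI) / (1 + exp(PI)).
#'
#' @param ca125 Serum CA 125, IU/mL (> 0; the log is undefined otherwise).
#' @param he4 Serum HE4, pmol/L (> 0).
#' @param menopausal_status `"premenopausal"` or `"postmenopausal"` per row.
#' @param coefficients A [coefficient_set()] with strata `premenopausal` and
#'   `postmenopausal`.
#' @return Numeric vector of risks in percent (0-100), NA where markers are
#'   missing.
#' @export
compute_roma <- function(ca125, he4, menopausal_status,
                         coefficients = default_coefficients()$roma) {
  stopifnot(inherits(coefficients, "coefficient_set"),
            coefficients$model_id == "roma")
  if (any(!is.na(ca125) & ca125 <= 0) || any(!is.na(he4) & he4 <= 0)) {
    stop("ROMA domain error: markers must be strictly positive (log scale)")
  }
  need <- setdiff(unique(menopausal_status[!is.na(ca125) & !is.na(he4)]),
                  names(coefficients$strata))
  if (length(need) > 0) {
    stop("ROMA configuration error: no coefficient stratum for ",
         paste(need, collapse = ", "))
  }
  pi_ <- rep(NA_real_, length(ca125))
  for (st in names(coefficients$strata)) {
    cf <- coefficients$strata[[st]]
    idx <- which(menopausal_status == st)
    pi_[idx] <- cf[["intercept"]] + cf[["log_he4"]] * log(he4[idx]) +
      cf[["log_ca125"]] * log(ca125[idx])
  }
  100 * stats::plogis(pi_)
}

#' IOTA simple rules classifier
#'
#' Ternary ultrasound classifier from five benign (B1-B5) and five malignant
#' (M1-M5) features: one or more M features and no B feature gives
#' `"malignant"`; one or more B features and no M feature gives `"benign"`;
#' both present, or neither, gives `"inconclusive"`. Any unassessed feature
#' flag gives a missing result.
#'
#' @param b_features n x 5 matrix (or data frame) of 0/1 B-feature flags.
#' @param m_features n x 5 matrix of 0/1 M-feature flags.
#' @return Character vector with levels `"benign"`, `"malignant"`,
#'   `"inconclusive"`, or NA.
#' @export
compute_simple_rules <- function(b_features, m_features) {
  b_features <- as.matrix(b_features)
  m_features <- as.matrix(m_features)
  stopifnot(ncol(b_features) == 5, ncol(m_features) == 5)
  any_b <- rowSums(b_features) >= 1
  any_m <- rowSums(m_features) >= 1
  out <- ifelse(any_m & !any_b, "malignant",
         ifelse(any_b & !any_m, "benign", "inconclusive"))
  out[is.na(any_b) | is.na(any_m)] <- NA_character_
  out
}

#' IOTA simple rules risk model
#'
#' Logistic regression on the ten simple rules ultrasound features plus the
#' type of centre: risk\% = 100 logistic(intercept + sum coefficient x
#' indicator).
#'
#' @param b_features,m_features As in [compute_simple_rules()].
#' @param centre_type `"oncology"` or `"non_oncology"` per row.
#' @param coefficients A [coefficient_set()] with a single `all` stratum.
#' @return Numeric risks in percent (0-100), NA where any input is missing.
#' @export
compute_simple_rules_risk <- function(b_features, m_features, centre_type,
    coefficients = default_coefficients()$simple_rules_risk) {
  stopifnot(inherits(coefficients, "coefficient_set"),
            coefficients$model_id == "simple_rules_risk")
  cf <- coefficients$strata[[1]]
  b_features <- as.matrix(b_features)
  m_features <- as.matrix(m_features)
  onc <- ifelse(centre_type == "oncology", 1,
         ifelse(centre_type == "non_oncology", 0, NA_real_))
  lp <- cf[["intercept"]] +
    as.vector(b_features %*% cf[paste0("b", 1:5)]) +
    as.vector(m_features %*% cf[paste0("m", 1:5)]) +
    cf[["oncology_centre"]] * onc
  100 * stats::plogis(lp)
}

#' IOTA ADNEX multinomial risk model
#'
#' Multinomial logistic model over five outcome classes (benign = reference;
#' borderline, stage 1, stage 2-4, secondary metastatic) from three clinical
#' predictors (age, serum CA 125, centre type) and six ultrasound predictors
#' (maximal lesion diameter, proportion solid tissue, more than 10 locules,
#' number of papillary projections, acoustic shadows, ascites). The total
#' risk of malignancy, 100 (1 - P(benign)), is what gets dichotomised at the
#' 3\% and 10\% thresholds.
#'
#' The proportion solid is `max_solid_diameter / max_lesion_diameter`,
#' clipped into \[0, 1\] with a warning if outside. By default a missing
#' CA 125 gives a missing score (`ca125_policy = "missing"`); the source
#' model's CA 125-optional variant (`"omit"`, dropping the CA 125 term from
#' every class) is available as a configuration option.
#'
#' @param age Years.
#' @param ca125 IU/mL.
#' @param max_lesion_diameter,max_solid_diameter mm.
#' @param more_than_10_locules,acoustic_shadows,ascites 0/1 flags.
#' @param papillation_count Integer >= 0.
#' @param centre_type `"oncology"` or `"non_oncology"`.
#' @param coefficients A [coefficient_set()] whose strata are the four
#'   malignant classes.
#' @param ca125_policy `"missing"` or `"omit"`.
#' @return List with `risk` (percent, 0-100) and `probabilities` (n x 5
#'   matrix over benign/borderline/stage1/stage2_4/metastatic, rows sum to 1).
#' @export
compute_adnex <- function(age, ca125, max_lesion_diameter, max_solid_diameter,
                          more_than_10_locules, papillation_count,
                          acoustic_shadows, ascites, centre_type,
                          coefficients = default_coefficients()$adnex,
                          ca125_policy = c("missing", "omit")) {
  ca125_policy <- match.arg(ca125_policy)
  stopifnot(inherits(coefficients, "coefficient_set"),
            coefficients$model_id == "adnex")
  n <- length(age)
  prop_solid <- max_solid_diameter / max_lesion_diameter
  out_of_range <- !is.na(prop_solid) & (prop_solid < 0 | prop_solid > 1)
  if (any(out_of_range)) {
    warning(sprintf("proportion solid outside [0, 1] for %d record(s); clipped",
                    sum(out_of_range)), call. = FALSE)
    prop_solid <- pmin(pmax(prop_solid, 0), 1)
  }
  if (any(!is.na(ca125) & ca125 <= 0)) {
    stop("ADNEX domain error: CA 125 must be strictly positive (log scale)")
  }
  onc <- ifelse(centre_type == "oncology", 1,
         ifelse(centre_type == "non_oncology", 0, NA_real_))
  log_ca125 <- log(ca125)
  if (ca125_policy == "omit") log_ca125 <- rep(0, n)
  x <- cbind(age = age,
             log_ca125 = log_ca125,
             log_max_diameter = log(max_lesion_diameter),
             prop_solid = prop_solid,
             more_than_10_locules = more_than_10_locules,
             papillation_count = papillation_count,
             acoustic_shadows = acoustic_shadows,
             ascites = ascites,
             oncology_centre = onc)
  classes <- names(coefficients$strata)
  z <- matrix(NA_real_, n, length(classes), dimnames = list(NULL, classes))
  for (cl in classes) {
    cf <- coefficients$strata[[cl]]
    nm <- .model_predictors("adnex")
    cfv <- cf[nm]
    if (ca125_policy == "omit") cfv["log_ca125"] <- 0
    z[, cl] <- cf[["intercept"]] + as.vector(x[, nm, drop = FALSE] %*% cfv)
  }
  denom <- 1 + rowSums(exp(z))
  probs <- cbind(benign = 1 / denom, exp(z) / denom)
  risk <- 100 * (1 - probs[, "benign"])
  list(risk = as.vector(risk), probabilities = probs)
}

#' Default IOTA-to-ORADS mapping table
#'
#' Ordered first-match rule table mapping IOTA ultrasound descriptors to
#' ORADS categories 1-5. The study's own lexicon mapping is not published;
#' this shipped table is a synthetic, approximate reconstruction (see
#' `inst/extdata/orads_mapping_synthetic_v1.csv`, documented row by row) and
#' is swappable: any data frame with columns `order`, `rule_id`, `category`,
#' `description` whose `rule_id`s are implemented in [map_orads()] works.
#'
#' @return Data frame of ordered mapping rules.
#' @export
default_orads_mapping <- function() {
  path <- system.file("extdata", "orads_mapping_synthetic_v1.csv",
                      package = "ovatriage")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab[order(tab$order), , drop = FALSE]
}

# predicate for one ORADS mapping rule, vectorised over cohort rows
.orads_rule_matches <- function(rule_id, cohort) {
  with(cohort, switch(rule_id,
    no_lesion = us_lesion_present == 0,
    metastases = us_metastases == 1,
    ascites_with_solid = us_ascites == 1 & us_solid_areas == 1,
    many_papillations = us_papillation_count >= 4,
    irregular_solid = us_solid_areas == 1 & us_m1 == 1,
    solid_component = us_solid_areas == 1,
    papillations_1_3 = us_papillation_count >= 1 & us_papillation_count <= 3,
    large_multilocular = us_multilocular == 1 & us_max_lesion_diameter >= 100,
    multilocular = us_multilocular == 1,
    large_unilocular = us_multilocular == 0 & us_max_lesion_diameter >= 100,
    simple_small = us_lesion_present == 1,
    stop("ORADS mapping error: unimplemented rule_id '", rule_id, "'")))
}

#' Map IOTA ultrasound descriptors to ORADS categories
#'
#' Applies the ordered mapping table: each participant receives the category
#' of the first rule whose predicate matches. Participants whose lesion
#' features cannot be evaluated for any matching rule get a missing category.
#'
#' @param cohort Cohort data frame with ultrasound columns.
#' @param mapping Mapping table, default [default_orads_mapping()].
#' @return Integer ORADS categories 1-5 (NA when unmappable). Binary use:
#'   positive iff category 4 or 5.
#' @export
map_orads <- function(cohort, mapping = default_orads_mapping()) {
  n <- nrow(cohort)
  cat <- rep(NA_integer_, n)
  decided <- rep(FALSE, n)
  for (i in seq_len(nrow(mapping))) {
    hit <- .orads_rule_matches(mapping$rule_id[i], cohort)
    hit[is.na(hit)] <- FALSE
    take <- hit & !decided
    cat[take] <- mapping$category[i]
    decided <- decided | hit
  }
  cat
}

#' Registry of index tests and their dichotomisation thresholds
#'
#' One row per evaluated test: the pre-stated thresholds for each model
#' (RMI 1 at 200 and 250; ROMA at 7.4, 11.4, 12.5, 13.1 percent; ADNEX and
#' the simple rules risk model at 3 and 10 percent; CA 125 at 87 IU/mL), the
#' ternary simple rules classifier, and the post hoc ORADS 1-3 vs 4-5 split.
#'
#' @return Data frame with columns `test_id`, `model`, `threshold`,
#'   `score_type` (`"numeric"` or `"category"`).
#' @export
default_test_registry <- function() {
  data.frame(
    test_id = c("rmi1@200", "rmi1@250", "roma@7.4", "roma@11.4", "roma@12.5",
                "roma@13.1", "adnex@3", "adnex@10", "srrisk@3", "srrisk@10",
                "simple_rules", "ca125@87", "orads@4"),
    model = c("rmi1", "rmi1", "roma", "roma", "roma", "roma", "adnex",
              "adnex", "srrisk", "srrisk", "simple_rules", "ca125", "orads"),
    threshold = c(200, 250, 7.4, 11.4, 12.5, 13.1, 3, 10, 3, 10, NA, 87, 4),
    score_type = c(rep("numeric", 10), "category", "numeric", "category"),
    stringsAsFactors = FALSE
  )
}

#' Dichotomise a continuous score at a threshold
#'
#' Positive iff score strictly greater than the threshold (matching the
#' published "> t" / "< t" row labelling); missing scores give
#' `"missing"`. The tie rule is configurable via `strict`.
#'
#' @param score Numeric scores.
#' @param threshold Threshold in the score's own units.
#' @param strict Logical; `TRUE` (default) uses `>`, `FALSE` uses `>=`.
#' @return Character vector in `"positive"`, `"negative"`, `"missing"`.
#' @export
dichotomize_score <- function(score, threshold, strict = TRUE) {
  pos <- if (strict) score > threshold else score >= threshold
  out <- ifelse(pos, "positive", "negative")
  out[is.na(score)] <- "missing"
  out
}

#' Dichotomise a ternary/category result
#'
#' Simple rules: malignant is positive, benign negative, inconclusive stays
#' inconclusive. ORADS: categories 4-5 positive, 1-3 negative.
#'
#' @param category Character (simple rules) or integer (ORADS) categories.
#' @param model `"simple_rules"` or `"orads"`.
#' @return Character vector in `"positive"`, `"negative"`, `"inconclusive"`,
#'   `"missing"`.
#' @export
dichotomize_category <- function(category, model = c("simple_rules", "orads")) {
  model <- match.arg(model)
  if (model == "simple_rules") {
    out <- ifelse(category == "malignant", "positive",
           ifelse(category == "benign", "negative", "inconclusive"))
  } else {
    out <- ifelse(category >= 4, "positive", "negative")
  }
  out[is.na(category)] <- "missing"
  out
}

#' Score every index test for a cohort
#'
#' Computes all continuous scores and categories for each participant.
#' Scorers never impute: any missing required predictor yields a missing
#' score. The IOTA-based scores additionally require `us_scan_available`.
#'
#' @param cohort Cohort data frame using the documented schema.
#' @param coefficients Named list of [coefficient_set()] objects, as
#'   [default_coefficients()].
#' @param orads_mapping ORADS mapping table, default
#'   [default_orads_mapping()].
#' @return Data frame: `participant_id`, `u_score`, `rmi1`, `roma`, `adnex`,
#'   `srrisk`, `ca125` (numeric scores), `sr_category`, `orads_category`.
#' @export
score_cohort <- function(cohort, coefficients = default_coefficients(),
                         orads_mapping = default_orads_mapping()) {
  scan <- !is.na(cohort$us_scan_available) & cohort$us_scan_available == 1
  u <- compute_u_score(cohort$us_multilocular, cohort$us_solid_areas,
                       cohort$us_metastases, cohort$us_ascites,
                       cohort$us_bilateral)
  u[!scan] <- NA_integer_
  rmi1 <- compute_rmi(cohort$ca125, u, cohort$menopausal_status)
  roma <- compute_roma(cohort$ca125, cohort$he4, cohort$menopausal_status,
                       coefficients$roma)
  b <- as.matrix(cohort[, paste0("us_b", 1:5)])
  m <- as.matrix(cohort[, paste0("us_m", 1:5)])
  sr <- compute_simple_rules(b, m)
  sr[!scan] <- NA_character_
  srrisk <- compute_simple_rules_risk(b, m, cohort$centre_type,
                                      coefficients$simple_rules_risk)
  srrisk[!scan] <- NA_real_
  adnex <- compute_adnex(cohort$age, cohort$ca125,
                         cohort$us_max_lesion_diameter,
                         cohort$us_max_solid_diameter,
                         cohort$us_more_than_10_locules,
                         cohort$us_papillation_count,
                         cohort$us_acoustic_shadows, cohort$us_ascites,
                         cohort$centre_type, coefficients$adnex)$risk
  adnex[!scan] <- NA_real_
  orads <- map_orads(cohort, orads_mapping)
  orads[!scan] <- NA_integer_
  data.frame(participant_id = cohort$participant_id,
             u_score = u, rmi1 = rmi1, roma = roma, adnex = adnex,
             srrisk = srrisk, ca125 = cohort$ca125,
             sr_category = sr, orads_category = orads,
             stringsAsFactors = FALSE)
}

#' Apply the threshold registry to cohort scores
#'
#' @param scores Output of [score_cohort()].
#' @param registry Test registry, default [default_test_registry()].
#' @param strict Tie rule passed to [dichotomize_score()].
#' @return Long data frame: `participant_id`, `test_id`, `state`
#'   (positive/negative/inconclusive/missing).
#' @export
apply_thresholds <- function(scores, registry = default_test_registry(),
                             strict = TRUE) {
  out <- vector("list", nrow(registry))
  for (i in seq_len(nrow(registry))) {
    reg <- registry[i, ]
    state <- if (reg$model == "simple_rules") {
      dichotomize_category(scores$sr_category, "simple_rules")
    } else if (reg$model == "orads") {
      dichotomize_category(scores$orads_category, "orads")
    } else {
      col <- switch(reg$model, rmi1 = "rmi1", roma = "roma", adnex = "adnex",
                    srrisk = "srrisk", ca125 = "ca125",
                    stop("threshold registry error: unknown model '",
                         reg$model, "'"))
      dichotomize_score(scores[[col]], reg$threshold, strict = strict)
    }
    out[[i]] <- data.frame(participant_id = scores$participant_id,
                           test_id = reg$test_id, state = state,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
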
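# Synthetic cohort generator: emulates the statistical structure the
# analysis assumes (two protocol cohorts, class-conditional marker and
# ultrasound feature distributions, class-dependent missingness, a realistic
# simple-rules inconclusive fraction) so that every downstream stage is
# testable without patient data. Defaults are emulation, not estimation:
# the true class-conditional distributions of the study are unpublished.

#' Default configuration of the synthetic cohort generator
#'
#' The defaults encode the study conditions: a pre-protocol-change cohort of
#' 857 women at 5.7\% prevalence of primary invasive ovarian cancer and a
#' post-change cohort of 354 at 11.0\%; a non-case class mix echoing the
#' published histology spectrum (borderline, secondary metastatic, uncertain,
#' benign, normal, unresolved); class-conditional log-normal CA 125 / HE4
#' with correlation (calibrated once so CA 125 > 87 IU/mL has sensitivity and
#' specificity near 55\% / 89\%); per-class ultrasound feature rates tuned
#' once so the simple rules split is roughly malignant/benign/inconclusive as
#' published (inconclusive about 15\% overall); class-dependent missingness
#' (ultrasound much more often missing in non-cases); and a share of
#' pre-change non-cases resolved by negative 12-month surveillance instead of
#' surgery.
#'
#' @param seed Integer seed for [generate_cohort()].
#' @return Nested list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    n_pre = 857L, n_post = 354L,
    prevalence_pre = 0.057, prevalence_post = 0.110,
    # histology class mix among non-primary participants (must sum to 1)
    class_mix = c(benign = 0.845, normal = 0.058, borderline = 0.027,
                  secondary_metastatic = 0.012, uncertain_behaviour = 0.002,
                  no_histology = 0.056),
    # per-class log-scale (meanlog, sdlog) for CA 125 and HE4, and their
    # log-scale correlation; non-case classes share the benign parameters
    # except borderline/secondary which sit between
    marker_params = list(
      case    = list(ca125 = c(4.65, 1.60), he4 = c(4.50, 0.70), rho = 0.50),
      elevated = list(ca125 = c(3.60, 1.30), he4 = c(4.00, 0.50), rho = 0.40),
      control = list(ca125 = c(3.00, 1.20), he4 = c(3.80, 0.35), rho = 0.30)
    ),
    ultrasound_params = list(
      # per-class Bernoulli rates of the 5 RMI U-score features
      rmi_features = list(
        case    = c(multilocular = 0.45, solid = 0.60, bilateral = 0.25,
                    ascites = 0.30, metastases = 0.15),
        elevated = c(multilocular = 0.50, solid = 0.35, bilateral = 0.18,
                     ascites = 0.10, metastases = 0.02),
        control = c(multilocular = 0.25, solid = 0.14, bilateral = 0.10,
                    ascites = 0.04, metastases = 0.005)
      ),
      # simple-rules pattern mix: P(M-dominant, B-dominant, mixed, featureless)
      sr_pattern = list(
        case    = c(m_dom = 0.51, b_dom = 0.17, mixed = 0.17, none = 0.15),
        elevated = c(m_dom = 0.25, b_dom = 0.45, mixed = 0.15, none = 0.15),
        control = c(m_dom = 0.04, b_dom = 0.79, mixed = 0.06, none = 0.11)
      ),
      sr_extra_rate = 0.25,  # rate of additional features within a pattern
      # lesion geometry: log-scale diameter, Beta proportion solid
      diameter = list(case = c(4.50, 0.45), elevated = c(4.40, 0.45),
                      control = c(4.00, 0.55)),
      prop_solid_beta = list(case = c(2.0, 2.0), elevated = c(1.2, 4.0),
                             control = c(1.0, 8.0)),
      papillation_lambda = c(case = 1.2, elevated = 0.8, control = 0.15),
      locules10_rate = c(case = 0.20, elevated = 0.25, control = 0.08),
      shadows_rate = c(case = 0.08, elevated = 0.15, control = 0.18),
      lesion_rate = c(case = 0.99, elevated = 0.97, control = 0.90)
    ),
    # per-variable missingness; ultrasound is missing-at-random on class
    # (non-cases skip the research scan far more often, as observed)
    missing_rates = list(
      ca125 = 0.005,
      he4 = list(case = 0.02, control = 0.064),
      ultrasound = list(case = 0.05, control = 0.17)
    ),
    inconclusive_target = 0.15,
    followup_fraction = 0.30,  # share of pre-change non-surgical negatives
    centre_oncology_rate = 0.50
  )
  stopifnot(abs(sum(cfg$class_mix) - 1) < 1e-8)
  structure(cfg, class = "synthetic_config")
}

# marker class for a histology class: cases and invasive-like classes have
# elevated markers, benign/normal/unresolved look like controls
.marker_class <- function(histology) {
  ifelse(histology == "primary_invasive", "case",
  ifelse(histology %in% c("borderline", "secondary_metastatic",
                          "uncertain_behaviour"), "elevated", "control"))
}

.rbvlnorm <- function(n, p1, p2, rho) {
  # correlated bivariate log-normal on the log scale
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(exp(p1[1] + p1[2] * z1), exp(p2[1] + p2[2] * z2))
}

# sample one row of simple-rules B/M flags given the latent pattern
.sr_flags <- function(pattern, extra_rate) {
  b <- m <- integer(5)
  draw_set <- function() {
    v <- stats::rbinom(5, 1, extra_rate)
    v[sample.int(5, 1)] <- 1L  # guarantee at least one feature
    v
  }
  if (pattern == "m_dom") m <- draw_set()
  if (pattern == "b_dom") b <- draw_set()
  if (pattern == "mixed") { m <- draw_set(); b <- draw_set() }
  c(b, m)
}

#' Generate a synthetic participant cohort
#'
#' Draws the disease class first, then correlated log-normal markers per
#' class, then ultrasound features per class, assigns the reference standard
#' (surgical histology for cases and most non-cases; a configured share of
#' pre-change non-cases resolved by negative 12-month surveillance;
#' post-change records all surgical), and finally applies class-dependent
#' missingness via [punch_missingness()]. Reproducible given
#' `config$seed`: the generator draws per-stage sub-seeds from one global
#' stream so adding a stage never perturbs earlier draws.
#'
#' @param config A [synthetic_config()].
#' @return Cohort data frame in the documented CSV schema
#'   ([cohort_schema()]).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (abs(sum(config$class_mix) - 1) > 1e-8) {
    stop("synthetic config error: class_mix must sum to 1")
  }
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1, 6)

  n <- config$n_pre + config$n_post
  cohort_tag <- rep(c("pre_change", "post_change"),
                    c(config$n_pre, config$n_post))

  # stage 1: disease class
  set.seed(stage_seeds[1])
  prev <- ifelse(cohort_tag == "pre_change", config$prevalence_pre,
                 config$prevalence_post)
  is_case <- stats::runif(n) < prev
  histology <- rep(NA_character_, n)
  histology[is_case] <- "primary_invasive"
  k <- sum(!is_case)
  histology[!is_case] <- sample(names(config$class_mix), k, replace = TRUE,
                                prob = config$class_mix)
  mclass <- .marker_class(histology)

  # stage 2: age and markers
  set.seed(stage_seeds[2])
  # premenopausal referral population: median about 44, IQR about 35-49
  age <- pmin(pmax(stats::rnorm(n, 42, 8.5), 18), 55)
  ca125 <- he4 <- numeric(n)
  for (cl in c("case", "elevated", "control")) {
    idx <- which(mclass == cl)
    mp <- config$marker_params[[cl]]
    mk <- .rbvlnorm(length(idx), mp$ca125, mp$he4, mp$rho)
    ca125[idx] <- mk[, 1]; he4[idx] <- mk[, 2]
  }

  # stage 3: ultrasound features
  set.seed(stage_seeds[3])
  up <- config$ultrasound_params
  lesion <- stats::rbinom(n, 1, up$lesion_rate[mclass])
  rmi_f <- matrix(0L, n, 5,
                  dimnames = list(NULL, c("multilocular", "solid", "bilateral",
                                          "ascites", "metastases")))
  srbm <- matrix(0L, n, 10)
  diam <- rep(NA_real_, n)
  solid_diam <- rep(NA_real_, n)
  papill <- integer(n)
  locules10 <- integer(n)
  shadows <- integer(n)
  for (cl in c("case", "elevated", "control")) {
    idx <- which(mclass == cl)
    ni <- length(idx)
    rates <- up$rmi_features[[cl]]
    for (j in seq_along(rates)) {
      rmi_f[idx, j] <- stats::rbinom(ni, 1, rates[j])
    }
    pat <- sample(c("m_dom", "b_dom", "mixed", "none"), ni, replace = TRUE,
                  prob = up$sr_pattern[[cl]])
    srbm[idx, ] <- t(vapply(pat, .sr_flags, integer(10),
                            extra_rate = up$sr_extra_rate))
    diam[idx] <- exp(stats::rnorm(ni, up$diameter[[cl]][1],
                                  up$diameter[[cl]][2]))
    ps <- stats::rbeta(ni, up$prop_solid_beta[[cl]][1],
                       up$prop_solid_beta[[cl]][2])
    papill[idx] <- stats::rpois(ni, up$papillation_lambda[[cl]])
    locules10[idx] <- stats::rbinom(ni, 1, up$locules10_rate[[cl]])
    shadows[idx] <- stats::rbinom(ni, 1, up$shadows_rate[[cl]])
    # solid tissue only when solid areas are present
    solid_diam[idx] <- ifelse(rmi_f[idx, "solid"] == 1, ps * diam[idx], 0)
  }
  # no lesion: zero geometry, no malignant features; the scan of a normal
  # ovary classifies as benign under simple rules (unilocular-equivalent B1)
  rmi_f[lesion == 0, ] <- 0L
  srbm[lesion == 0, ] <- 0L
  srbm[lesion == 0, 1] <- 1L
  diam[lesion == 0] <- 0
  solid_diam[lesion == 0] <- 0
  papill[lesion == 0] <- 0L
  locules10[lesion == 0] <- 0L
  shadows[lesion == 0] <- 0L

  # stage 4: reference standard
  set.seed(stage_seeds[4])
  ref_source <- rep("surgery", n)
  followup <- rep("unknown", n)
  pre_noncase <- cohort_tag == "pre_change" & !is_case
  surveil <- pre_noncase & stats::runif(n) < config$followup_fraction
  # surveillance resolves benign/normal non-cases without histology
  surveil <- surveil & histology %in% c("benign", "normal", "no_histology")
  histology[surveil] <- "no_histology"
  ref_source[surveil] <- "follow_up"
  followup[surveil] <- "no"
  # post-change: all surgical, unresolved class becomes benign histology
  post_nohist <- cohort_tag == "post_change" & histology == "no_histology"
  histology[post_nohist] <- "benign"
  # remaining pre-change no-histology without surveillance: unresolved
  ref_source[histology == "no_histology" & !surveil] <- "none"

  stage <- rep(NA_integer_, n)
  stage[is_case] <- sample(1:4, sum(is_case), replace = TRUE,
                           prob = c(0.53, 0.07, 0.34, 0.06))

  # stage 5: administrative fields
  set.seed(stage_seeds[5])
  centre <- ifelse(stats::runif(n) < config$centre_oncology_rate,
                   "oncology", "non_oncology")
  menstruated <- rep("yes", n)  # premenopausal cohort by construction

  cohort <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    age = round(age, 1),
    menstruated_last_12m = menstruated,
    vaginal_bleeding_history = "unknown",
    menopausal_status = "premenopausal",
    ca125 = round(ca125, 1),
    he4 = round(he4, 1),
    centre_type = centre,
    cohort_tag = cohort_tag,
    us_lesion_present = lesion,
    us_multilocular = rmi_f[, "multilocular"],
    us_solid_areas = rmi_f[, "solid"],
    us_bilateral = rmi_f[, "bilateral"],
    us_ascites = rmi_f[, "ascites"],
    us_metastases = rmi_f[, "metastases"],
    us_more_than_10_locules = locules10,
    us_acoustic_shadows = shadows,
    stringsAsFactors = FALSE
  )
  for (j in 1:5) cohort[[paste0("us_b", j)]] <- srbm[, j]
  for (j in 1:5) cohort[[paste0("us_m", j)]] <- srbm[, j + 5]
  cohort$us_scan_available <- 1L
  cohort$us_max_lesion_diameter <- round(diam, 1)
  cohort$us_max_solid_diameter <- round(solid_diam, 1)
  cohort$us_papillation_count <- papill
  cohort$ref_source <- ref_source
  cohort$ref_histology_category <- histology
  cohort$ref_figo_stage <- stage
  cohort$ref_followup_cancer <- followup

  # stage 6: class-dependent missingness
  punch_missingness(cohort, rates = config$missing_rates,
                    mechanism = "mar_on_class", seed = stage_seeds[6])
}

#' Punch missing values into a cohort
#'
#' Applies per-variable missingness: MCAR (one rate per variable) or
#' MAR-on-class, where the rate depends on case status (non-cases can have
#' much higher ultrasound missingness, as observed in practice). The
#' `ultrasound` rate blanks the whole scan (all ultrasound columns and the
#' `us_scan_available` flag). Counts of punched cells are reported via a
#' message.
#'
#' @param cohort Cohort data frame.
#' @param rates Named list. For MCAR, numbers; for MAR-on-class, either a
#'   number (applied to all) or `list(case = r1, control = r0)`.
#' @param mechanism `"mcar"` or `"mar_on_class"`.
#' @param seed Integer seed.
#' @return The cohort with missing values punched in.
#' @export
punch_missingness <- function(cohort, rates,
                              mechanism = c("mcar", "mar_on_class"),
                              seed = 1L) {
  mechanism <- match.arg(mechanism)
  set.seed(as.integer(seed))
  is_case <- cohort$ref_histology_category == "primary_invasive"
  n <- nrow(cohort)
  n_punched <- 0L
  rate_vec <- function(r) {
    if (is.list(r)) {
      if (mechanism == "mcar") {
        stop("punch_missingness: class-specific rates require mar_on_class")
      }
      ifelse(is_case, r$case, r$control)
    } else rep(r, n)
  }
  us_cols <- grep("^us_", names(cohort), value = TRUE)
  for (v in names(rates)) {
    rv <- rate_vec(rates[[v]])
    stopifnot(all(rv >= 0 & rv <= 1))
    hit <- stats::runif(n) < rv
    if (v == "ultrasound") {
      for (cl in us_cols) cohort[[cl]][hit] <- NA
      cohort$us_scan_available[hit] <- 0L
      n_punched <- n_punched + sum(hit) * length(us_cols)
    } else {
      cohort[[v]][hit] <- NA
      n_punched <- n_punched + sum(hit)
    }
  }
  message(sprintf("punch_missingness: %d cell(s) set to missing (%s)",
                  n_punched, mechanism))
  cohort
}

#' Embed a known true risk model into a cohort
#'
#' Replaces the reference-standard outcome with a Bernoulli draw from a
#' supplied per-participant risk, so that downstream calibration and
#' discrimination estimates have known truth: the recalibration slope should
#' recover 1 and calibration-in-the-large 0, and the C index approaches the
#' value implied by the risk distribution.
#'
#' @param cohort Cohort data frame.
#' @param risks Per-participant true risks in \[0, 1\] (e.g. a model's own
#'   predicted risks divided by 100).
#' @param seed Integer seed.
#' @return The cohort with `ref_histology_category` set to
#'   `primary_invasive`/`benign` per the Bernoulli draw, `ref_source`
#'   `"surgery"`, and a `true_risk` column appended.
#' @export
embed_true_model <- function(cohort, risks, seed = 1L) {
  stopifnot(length(risks) == nrow(cohort), all(risks >= 0 & risks <= 1))
  set.seed(as.integer(seed))
  y <- stats::runif(nrow(cohort)) < risks
  cohort$ref_histology_category <- ifelse(y, "primary_invasive", "benign")
  cohort$ref_source <- "surgery"
  cohort$ref_followup_cancer <- "unknown"
  cohort$true_risk <- risks
  cohort
}
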
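# Participant-level data model: schema, CSV I/O, menopausal classification,
# outcome labels derived from the reference standard.

#' Histology categories recognised by the reference standard
#'
#' @return Character vector of the eight histology categories a participant's
#'   reference standard can take.
#' @export
histology_categories <- function() {
  c("primary_invasive", "secondary_metastatic", "borderline",
    "uncertain_behaviour", "benign", "normal", "no_histology", "missing")
}

# enumerations used by schema validation
.enum_levels <- list(
  menstruated_last_12m     = c("yes", "no", "unknown"),
  vaginal_bleeding_history = c("yes", "no", "unknown"),
  menopausal_status        = c("premenopausal", "postmenopausal"),
  centre_type              = c("oncology", "non_oncology"),
  cohort_tag               = c("pre_change", "post_change"),
  ref_source               = c("surgery", "biopsy", "cytology", "follow_up", "none"),
  ref_followup_cancer      = c("yes", "no", "unknown")
)

.flag_columns <- c(
  "us_lesion_present", "us_multilocular", "us_solid_areas", "us_bilateral",
  "us_ascites", "us_metastases", "us_more_than_10_locules",
  "us_acoustic_shadows", paste0("us_b", 1:5), paste0("us_m", 1:5),
  "us_scan_available"
)

.numeric_columns <- c("age", "ca125", "he4",
                      "us_max_lesion_diameter", "us_max_solid_diameter")

.integer_columns <- c("us_papillation_count", "ref_figo_stage")

#' Column dictionary for the cohort CSV schema
#'
#' One row per column of the participant CSV. Units are fixed: CA 125 in
#' IU/mL, HE4 in pmol/L, diameters in mm, age in years. Flags are 0/1.
#' Missing values are written as empty cells or `NA`.
#'
#' @param schema_version Schema label; only `"1"` is defined.
#' @return Data frame with columns `column`, `type`, `required`, `description`.
#' @export
cohort_schema <- function(schema_version = "1") {
  if (!identical(schema_version, "1")) {
    stop("unknown cohort schema version: ", schema_version)
  }
  cols <- data.frame(
    column = c("participant_id", "age", "menstruated_last_12m",
               "vaginal_bleeding_history", "menopausal_status",
               "ca125", "he4", "centre_type", "cohort_tag",
               .flag_columns[.flag_columns != "us_scan_available"],
               "us_scan_available",
               "us_max_lesion_diameter", "us_max_solid_diameter",
               "us_papillation_count",
               "ref_source", "ref_histology_category", "ref_figo_stage",
               "ref_followup_cancer"),
    stringsAsFactors = FALSE
  )
  cols$type <- ifelse(cols$column %in% .numeric_columns, "numeric",
               ifelse(cols$column %in% .flag_columns, "flag",
               ifelse(cols$column %in% .integer_columns, "integer",
                      "character")))
  # menopausal_status is derived at load time when absent
  cols$required <- !(cols$column %in% c("menopausal_status"))
  desc <- c(
    participant_id = "opaque unique identifier",
    age = "age at recruitment, years",
    menstruated_last_12m = "menstruated in the past 12 months (yes/no/unknown)",
    vaginal_bleeding_history = "self-reported vaginal bleeding history (yes/no/unknown)",
    menopausal_status = "derived label (premenopausal/postmenopausal)",
    ca125 = "serum CA 125, IU/mL",
    he4 = "serum HE4, pmol/L",
    centre_type = "recruiting centre type (oncology/non_oncology)",
    cohort_tag = "protocol cohort (pre_change/post_change)",
    us_lesion_present = "adnexal lesion seen on ultrasound",
    us_multilocular = "multilocular cyst (RMI U feature)",
    us_solid_areas = "solid areas (RMI U feature)",
    us_bilateral = "bilateral lesions (RMI U feature)",
    us_ascites = "ascites (RMI U feature / ADNEX predictor)",
    us_metastases = "metastases (RMI U feature)",
    us_more_than_10_locules = "more than 10 locules (ADNEX predictor)",
    us_acoustic_shadows = "acoustic shadows (ADNEX predictor)",
    us_b1 = "simple rules benign feature B1 (unilocular cyst)",
    us_b2 = "simple rules benign feature B2 (solid components <7 mm)",
    us_b3 = "simple rules benign feature B3 (acoustic shadows)",
    us_b4 = "simple rules benign feature B4 (smooth multilocular <100 mm)",
    us_b5 = "simple rules benign feature B5 (no blood flow)",
    us_m1 = "simple rules malignant feature M1 (irregular solid tumour)",
    us_m2 = "simple rules malignant feature M2 (ascites)",
    us_m3 = "simple rules malignant feature M3 (>=4 papillary structures)",
    us_m4 = "simple rules malignant feature M4 (irregular multilocular-solid >=100 mm)",
    us_m5 = "simple rules malignant feature M5 (very strong blood flow)",
    us_scan_available = "IOTA ultrasound scan performed",
    us_max_lesion_diameter = "maximal lesion diameter, mm",
    us_max_solid_diameter = "maximal diameter of largest solid component, mm",
    us_papillation_count = "number of papillary projections (integer >= 0)",
    ref_source = "reference standard source (surgery/biopsy/cytology/follow_up/none)",
    ref_histology_category = "reference histology category",
    ref_figo_stage = "FIGO stage 1-4 (metadata only)",
    ref_followup_cancer = "cancer diagnosis during 12-month surveillance (yes/no/unknown)"
  )
  cols$description <- unname(desc[cols$column])
  cols
}

#' Read a participant cohort from CSV
#'
#' Reads one participant per row using the documented column dictionary
#' ([cohort_schema()]). Empty cells and the literal string `NA` are missing.
#' Numeric cells that do not parse become missing with a warning naming the
#' column; row count is always preserved.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param schema_version Schema label (see [cohort_schema()]).
#' @return Data frame of participant records (one row per participant).
#' @export
read_cohort <- function(path, schema_version = "1") {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  schema <- cohort_schema(schema_version)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), stringsAsFactors = FALSE)
  required <- schema$column[schema$required]
  absent <- setdiff(required, names(raw))
  if (length(absent) > 0) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  }
  if (anyDuplicated(raw$participant_id)) {
    dup <- unique(raw$participant_id[duplicated(raw$participant_id)])
    stop("cohort integrity error: duplicate participant_id: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  num_cols <- intersect(c(.numeric_columns, .integer_columns, .flag_columns),
                        names(raw))
  for (cl in num_cols) {
    parsed <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- !is.na(raw[[cl]]) & is.na(parsed)
    if (any(bad)) {
      warning(sprintf("column '%s': %d unparseable numeric cell(s) set to missing",
                      cl, sum(bad)), call. = FALSE)
    }
    raw[[cl]] <- if (cl %in% c(.flag_columns, .integer_columns)) {
      as.integer(parsed)
    } else {
      parsed
    }
  }
  if (!"menopausal_status" %in% names(raw)) {
    raw$menopausal_status <- classify_menopause(
      raw$age, raw$menstruated_last_12m, raw$vaginal_bleeding_history)
  }
  validate_cohort(raw)
  raw
}

#' Write a cohort back to CSV using the documented schema conventions
#'
#' @param cohort Data frame of participant records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate cohort invariants
#'
#' Errors on hard invariant violations (non-positive age, negative markers,
#' unknown enumeration levels, missing cohort tag); warns when a solid
#' diameter exceeds the lesion diameter (downstream scorers clip the
#' proportion solid).
#'
#' @param cohort Data frame of participant records.
#' @return `cohort`, invisibly.
#' @export
validate_cohort <- function(cohort) {
  if (any(!is.na(cohort$age) & cohort$age <= 0)) {
    stop("cohort invariant violated: age must be > 0")
  }
  for (mk in c("ca125", "he4")) {
    if (mk %in% names(cohort) && any(!is.na(cohort[[mk]]) & cohort[[mk]] < 0)) {
      stop("cohort invariant violated: ", mk, " must be nonnegative")
    }
  }
  if ("cohort_tag" %in% names(cohort) && anyNA(cohort$cohort_tag)) {
    stop("cohort invariant violated: cohort_tag must always be set")
  }
  for (cl in names(.enum_levels)) {
    if (!cl %in% names(cohort)) next
    vals <- cohort[[cl]]
    bad <- !is.na(vals) & !(vals %in% .enum_levels[[cl]])
    if (any(bad)) {
      stop(sprintf("cohort invariant violated: column '%s' has value(s) %s",
                   cl, paste(unique(vals[bad]), collapse = ", ")))
    }
  }
  if ("ref_histology_category" %in% names(cohort)) {
    vals <- cohort$ref_histology_category
    bad <- !is.na(vals) & !(vals %in% histology_categories())
    if (any(bad)) {
      stop("cohort invariant violated: unknown histology category: ",
           paste(unique(vals[bad]), collapse = ", "))
    }
  }
  if (all(c("us_max_solid_diameter", "us_max_lesion_diameter") %in% names(cohort))) {
    both <- !is.na(cohort$us_max_solid_diameter) &
      !is.na(cohort$us_max_lesion_diameter)
    if (any(both & cohort$us_max_solid_diameter > cohort$us_max_lesion_diameter)) {
      warning("solid diameter exceeds lesion diameter for some records; ",
              "proportion solid will be clipped to [0, 1]", call. = FALSE)
    }
  }
  invisible(cohort)
}

#' Classify menopausal status
#'
#' Participants are categorised at recruitment by age (<50 vs >=51 years) and
#' whether they menstruated in the past 12 months. The perimenopausal band --
#' age in \[50, 51) or unknown menstruation, or disagreement between the age
#' and menstruation criteria -- is re-categorised from the self-reported
#' vaginal bleeding history. The full rule table, applied in order:
#'
#' 1. age < 50 and menstruated in the last 12 months: premenopausal;
#' 2. age >= 51 and did not menstruate: postmenopausal;
#' 3. otherwise, bleeding history known: bleeding in the past 12 months gives
#'    premenopausal, none gives postmenopausal;
#' 4. otherwise, menstruation known: yes gives premenopausal, no gives
#'    postmenopausal;
#' 5. otherwise, the age cutpoint alone: < 50 premenopausal, >= 50
#'    postmenopausal.
#'
#' @param age Age in years (must be present).
#' @param menstruated_last_12m `"yes"`, `"no"` or `"unknown"` (NA treated as
#'   unknown).
#' @param vaginal_bleeding_history `"yes"`, `"no"` or `"unknown"`.
#' @return Character vector, `"premenopausal"` or `"postmenopausal"`.
#' @export
classify_menopause <- function(age, menstruated_last_12m,
                               vaginal_bleeding_history) {
  n <- length(age)
  menst <- rep_len(ifelse(is.na(menstruated_last_12m), "unknown",
                          menstruated_last_12m), n)
  bleed <- rep_len(ifelse(is.na(vaginal_bleeding_history), "unknown",
                          vaginal_bleeding_history), n)
  if (any(is.na(age) & menst == "unknown" & bleed == "unknown")) {
    stop("menopausal classification error: all inputs unknown for some records")
  }
  if (anyNA(age)) {
    stop("menopausal classification error: age must be present")
  }
  out <- rep(NA_character_, n)
  rule1 <- age < 50 & menst == "yes"
  rule2 <- age >= 51 & menst == "no"
  out[rule1] <- "premenopausal"
  out[rule2 & is.na(out)] <- "postmenopausal"
  amb <- is.na(out)
  out[amb & bleed == "yes"] <- "premenopausal"
  out[amb & bleed == "no"] <- "postmenopausal"
  amb <- is.na(out)
  out[amb & menst == "yes"] <- "premenopausal"
  out[amb & menst == "no"] <- "postmenopausal"
  amb <- is.na(out)
  out[amb] <- ifelse(age[amb] < 50, "premenopausal", "postmenopausal")
  out
}

#' Outcome definitions
#'
#' Three named outcome definitions partition the histology categories into
#' positive, negative and excluded sets:
#'
#' * `primary`: primary invasive ovarian cancer versus benign or normal;
#'   borderline tumours, secondary metastatic cancers, neoplasms of uncertain
#'   behaviour and unresolved reference standards are excluded.
#' * `secondary_any_cancer`: any cancer (primary invasive, secondary
#'   metastatic, borderline, uncertain behaviour) versus benign or normal.
#' * `secondary_borderline_as_benign`: as the secondary definition but with
#'   borderline tumours grouped with the benign/normal negatives.
#'
#' Participants with no histology but a completed negative 12-month
#' surveillance are negative under every definition; no histology and no
#' follow-up information leaves the participant excluded.
#'
#' @param name One of `"primary"`, `"secondary_any_cancer"`,
#'   `"secondary_borderline_as_benign"`.
#' @return An object of class `outcome_definition` with elements `name`,
#'   `positive`, `negative`, `excluded`.
#' @export
outcome_definition <- function(name = c("primary", "secondary_any_cancer",
                                        "secondary_borderline_as_benign")) {
  name <- match.arg(name)
  sets <- switch(name,
    primary = list(
      positive = "primary_invasive",
      negative = c("benign", "normal"),
      excluded = c("secondary_metastatic", "borderline", "uncertain_behaviour",
                   "no_histology", "missing")),
    secondary_any_cancer = list(
      positive = c("primary_invasive", "secondary_metastatic", "borderline",
                   "uncertain_behaviour"),
      negative = c("benign", "normal"),
      excluded = c("no_histology", "missing")),
    secondary_borderline_as_benign = list(
      positive = c("primary_invasive", "secondary_metastatic",
                   "uncertain_behaviour"),
      negative = c("benign", "normal", "borderline"),
      excluded = c("no_histology", "missing")))
  stopifnot(setequal(c(sets$positive, sets$negative, sets$excluded),
                     histology_categories()))
  structure(c(list(name = name), sets), class = "outcome_definition")
}

#' Derive outcome labels from the reference standard
#'
#' Applies an [outcome_definition()] to each participant's reference-standard
#' fields. Histology categories map through the definition's sets, with one
#' runtime resolution for unresolved histology (`no_histology` or `missing`):
#' a completed negative 12-month surveillance (`ref_followup_cancer == "no"`)
#' makes the participant negative; a follow-up cancer flag without ovarian
#' histology leaves the participant excluded (the diagnosis cannot be
#' attributed to the ovary), as does absent follow-up information.
#'
#' @param cohort Data frame with `ref_histology_category` and
#'   `ref_followup_cancer` columns (and optionally `ref_source`).
#' @param definition An [outcome_definition()] object or its name.
#' @return Character vector with levels `"positive"`, `"negative"`,
#'   `"excluded"`, one per participant.
#' @export
derive_outcome <- function(cohort, definition = "primary") {
  if (is.character(definition)) definition <- outcome_definition(definition)
  stopifnot(inherits(definition, "outcome_definition"))
  cat <- cohort$ref_histology_category
  cat[is.na(cat)] <- "missing"
  unknown <- !(cat %in% histology_categories())
  if (any(unknown)) {
    stop("outcome data error: unknown histology category: ",
         paste(unique(cat[unknown]), collapse = ", "))
  }
  out <- rep("excluded", length(cat))
  out[cat %in% definition$positive] <- "positive"
  out[cat %in% definition$negative] <- "negative"
  out[cat %in% definition$excluded] <- "excluded"
  unresolved <- cat %in% c("no_histology", "missing")
  fup <- cohort$ref_followup_cancer
  if (is.null(fup)) fup <- rep("unknown", length(cat))
  fup[is.na(fup)] <- "unknown"
  out[unresolved & fup == "no"] <- "negative"
  out
}

#' Subset a cohort by protocol cohort tag
#'
#' @param cohort Data frame of participant records with a `cohort_tag` column.
#' @param selector `"pre_change"`, `"post_change"` or `"combined"`.
#' @return The selected subset (a warning, not an error, if empty).
#' @export
filter_cohort <- function(cohort,
                          selector = c("combined", "pre_change", "post_change")) {
  selector <- match.arg(selector)
  out <- if (selector == "combined") cohort else
    cohort[cohort$cohort_tag == selector, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("filter_cohort: selector '", selector, "' matched no records",
            call. = FALSE)
  }
  message(sprintf("filter_cohort: %d of %d records selected (%s)",
                  nrow(out), nrow(cohort), selector))
  out
}

#' Per-column missingness summary
#'
#' @param cohort Data frame of participant records.
#' @return List with `n_records` and a data frame `missingness` (column,
#'   n_missing, prop_missing), suitable for JSON serialisation.
#' @export
data_quality_report <- function(cohort) {
  miss <- vapply(cohort, function(x) sum(is.na(x)), integer(1))
  list(
    n_records = nrow(cohort),
    missingness = data.frame(
      column = names(miss),
      n_missing = unname(miss),
      prop_missing = unname(round(miss / nrow(cohort), 4)),
      stringsAsFactors = FALSE
    )
  )
}
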
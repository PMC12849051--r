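---
title: "Methods: head-to-head accuracy of ovarian cancer triage tests"
author: "ovatriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: head-to-head accuracy of ovarian cancer triage tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovatriage)
```

## The problem

Premenopausal women referred to secondary care with non-specific symptoms
and an abnormal CA 125 or ultrasound result have a low prevalence of
primary invasive ovarian cancer (around 5-6% in a representative referral
population). The triage question -- who should be referred onward to a
specialist gynaecological cancer centre -- is answered in practice by
dichotomising a risk score. This package implements the full comparative
machinery for that question: six risk prediction scores, a common
reference-standard outcome, paired accuracy comparison, discrimination and
calibration, missing-data handling, and a synthetic cohort generator so
that every stage is testable without access to patient-level study data
(which are not publicly available for this study design).

## Data model and outcome definitions

A cohort is one CSV row per participant (`cohort_schema()` documents every
column and unit: CA 125 in IU/mL, HE4 in pmol/L, diameters in mm). The
reference standard is surgical/biopsy/cytology histology where an operation
took place, or 12-month surveillance for conservatively managed women in
the pre-protocol-change cohort.

Menopausal status is assigned from age (<50 vs >=51 years) and menstruation
in the past 12 months; the perimenopausal band (age in [50, 51), unknown
menstruation, or disagreement of the two criteria) is re-categorised from
the self-reported vaginal bleeding history. The residual tie-breaks (use
menstruation if known, else the age cutpoint at 50) are this package's own
documented completion of the rule table; they are exercised exhaustively in
the tests.

Three outcome definitions partition the histology categories
(`outcome_definition()`):

* **primary** -- primary invasive cancer vs benign/normal; borderline
  tumours, secondary metastatic cancers, uncertain-behaviour neoplasms and
  unresolved reference standards are excluded;
* **secondary_any_cancer** -- any cancer vs benign/normal;
* **secondary_borderline_as_benign** -- the sensitivity analysis grouping
  borderline tumours with the negatives.

Participants with no histology but a completed negative 12-month
surveillance are negatives under all definitions. A follow-up cancer
diagnosis without ovarian histology is excluded from the primary outcome:
the diagnosis cannot be attributed to the ovary. Inconclusive cytology is
treated as an unresolved reference standard (excluded); FIGO stage is
carried as metadata only.

## Index tests

* **RMI 1** = U x M x CA125. U counts multilocular cysts, solid areas,
  metastases, ascites and bilateral lesions, mapped 0 -> 0, 1 -> 1,
  2-5 -> 3; M is 1 for premenopausal, 3 for postmenopausal women.
  Thresholds 200 and 250; 250 is the standard-of-care comparator.
* **ROMA** uses a menopause-stratified predictive index
  PI = b0 + b1 ln(HE4) + b2 ln(CA125), reported as
  100 exp(PI)/(1 + exp(PI)). Thresholds 7.4, 11.4 (manufacturer
  recommendation for premenopausal women), 12.5 and 13.1 percent.
* **IOTA simple rules** is a ternary classifier from five benign (B) and
  five malignant (M) ultrasound features: only-M = malignant, only-B =
  benign, both or neither = inconclusive.
* **The simple rules risk model** is a logistic model on the ten features
  plus centre type (oncology vs non-oncology); thresholds 3% and 10%.
* **IOTA ADNEX** is a multinomial logistic model (benign is the reference
  class; borderline, stage 1, stage 2-4, secondary metastatic are the
  malignant classes) on age, CA 125, centre type, lesion diameter,
  proportion solid, >10 locules, papillation count, acoustic shadows and
  ascites. The dichotomised quantity is the total malignancy risk
  100(1 - P(benign)); thresholds 3% and 10%.
* **CA 125** alone at 87 IU/mL, a threshold associated with a 3% positive
  predictive value in primary care.
* **ORADS** (post hoc) maps the IOTA descriptors onto categories 1-5 via an
  ordered first-match rule table; categories 4-5 are test-positive.

### Coefficients are configuration, not code

ROMA ships with the original published coefficients (premenopausal
PI = -12.0 + 2.38 ln HE4 + 0.0626 ln CA125; postmenopausal
PI = -8.09 + 1.04 ln HE4 + 0.732 ln CA125). The ADNEX and simple-rules-risk
parameters are licensed model content that this package does not
redistribute: the shipped defaults are **synthetic coefficient sets**
(`adnex_synthetic_v1.json`, `srrisk_synthetic_v1.json`, marked as such in
their `source_citation`) calibrated once to produce qualitatively realistic
risks on the synthetic cohort, and swappable via `load_coefficient_set()`.
The ORADS mapping table is likewise a synthetic, documented approximation
(`orads_mapping_synthetic_v1.csv`). Every correctness test therefore uses
toy coefficient sets with known values, so the scorers' algebra is verified
independently of any particular published parameterisation. Natural
logarithms are used throughout, on the raw measurement scales.

Design decisions worth stating: ties at a threshold are negative (strictly
greater-than is positive, matching the ">t" / "<t" convention of published
accuracy tables); a missing CA 125 makes ADNEX missing by default (the
CA 125-omitting variant is a config option); the proportion solid is
clipped into [0, 1] with a warning; scorers never impute -- a missing
required predictor always yields a missing result.

## Accuracy statistics

2x2 tables are built after excluding participants with an excluded outcome;
missing and inconclusive test results are then counted separately and
removed from the four cells. Counting inconclusives as positive would
overstate sensitivity, so the alternative policies
(`inconclusive_policy = "positive"`/`"negative"`) exist for sensitivity
analyses only and are never the default.

Proportions get **Clopper-Pearson exact** intervals by default. The choice
was forced by replication: the exact interval reproduces the published
intervals cell for cell (e.g. 20/47 gives 28.3-57.8%), which Wilson does
not; Wilson remains available as an option.

Paired comparisons use the **exact McNemar test**,
p = min(1, 2 P(X <= min(b, c))) with X ~ Binomial(b + c, 1/2) over the
discordant pairs within cases (sensitivity) and non-cases (specificity),
restricted to participants conclusive on both tests. Differences are
reported as comparator minus alternative. The asymptotic interval on the
difference is a paired Wald interval **with a 1/n continuity correction**;
again the decision was made by replication -- only the
continuity-corrected interval reproduces the published -15.5 to 2.7 and
0.1 to 2.1 intervals for the RMI 200-vs-250 contrast. Multiplicity uses
Bonferroni over the eleven pre-stated comparisons with the published
rounded alpha of 0.005 (0.05/11 = 0.00455); for any other number of
comparisons the unrounded 0.05/n applies. The post hoc ORADS comparison is
excluded from the count.

The replication entry point, `replicate_table3()`, recomputes every cell
that is derivable from the printed classification counts. The paired
deltas of non-nested test pairs depend on common-subset joint counts that
printed marginals do not determine; these are marked `not derivable` rather
than approximated. One published row (ROMA at 12.5%) has internally
inconsistent control counts; the replication uses the printed counts as-is,
which reproduces the printed metrics exactly.

## Discrimination and calibration

The C index is the midrank AUC (ties count one half), with a DeLong
variance for the interval (the reference implementation in `pROC` is used
as a cross-check in the tests, never as the implementation). `roc_points()`
returns the empirical staircase whose trapezoidal area equals the pair-count
C index to 1e-12 -- an identity the tests enforce on random fixtures.

Calibration follows the standard logistic recalibration framework: the
**calibration slope** is the coefficient of logit(risk) in a logistic
regression of the outcome (1 = agreement), and **calibration-in-the-large**
is the intercept of the offset model (0 = mean predicted risk equals
observed prevalence). Risks are clipped to (1e-6, 1 - 1e-6) before the
logit. Decile plots group participants into ten near-equal groups ordered
by predicted risk; ties stay in one group (a tie block goes to the group of
its midpoint), and fewer than ten observations fall back to quintiles with
a warning. One published figure caption describes a slope below one as
"overprediction" while its neighbouring sentence implies the opposite
direction; this package uses the standard definition above and reports the
direction of miscalibration through calibration-in-the-large.

## Missing data

`mice_impute()` is a self-contained chained-equations imputer: predictive
mean matching (Bayesian parameter draw, 5 donors) for continuous variables
and Bayesian-draw logistic conditionals for 0/1 flags, m = 10 datasets and
10 cycles by default (the source analysis states the use of chained
equations but not its settings; these defaults are the field's usual
choice). Observed cells are never altered; derived scores are never imputed
directly but recomputed per completed dataset; the outcome label is
included as a predictor by default, as is standard for accuracy studies.
Pooling is by Rubin's rules on the logit scale with total variance
W + (1 + 1/m)B; degenerate proportions are continuity-adjusted and
flagged.

## The synthetic cohort

`generate_cohort()` draws, in order: protocol cohort and disease class
(857 pre-change at 5.7% prevalence, 354 post-change at 11.0% -- the
post-change cohort restricts to surgical patients, hence the higher
prevalence); correlated class-conditional log-normal CA 125/HE4; ultrasound
features from per-class rates, with the simple-rules B/M features driven by
a latent four-way pattern (malignant-dominant / benign-dominant / mixed /
featureless) so the malignant : benign : inconclusive split can be
controlled directly; the reference standard (surgery for cases and most
non-cases, negative 12-month surveillance for about 30% of pre-change
non-cases, all-surgical post-change); then class-dependent missingness
(ultrasound missing in about 17% of non-cases vs 5% of cases, mirroring
the observed pattern in which conservatively managed women skip the
research scan). One global seed spawns per-stage sub-seeds, so adding a
stage never perturbs earlier draws.

The marker parameters were chosen so that CA 125 > 87 IU/mL sits near
55% sensitivity / 89% specificity, and the feature rates so the
simple-rules inconclusive fraction lands near 15%; both were calibrated
once against those published operating points and then frozen. This is
emulation, not estimation: the generator reproduces prevalences, realistic
marker overlap, class-dependent missingness and an inconclusive
classifier -- it does **not** reproduce centre-level clustering, referral
routes, sonographer variability, or the true joint distribution of
ultrasound features, so passing tests on synthetic data demonstrate the
correctness of the statistical machinery, not the real-world operating
points of the tests. The published C index and calibration values of the
real cohort cannot be recomputed without the individual-level data; what is
verified instead is exactness of the machinery (oracle identities) and
recovery of known truths when outcomes are simulated from a model's own
risks (`embed_true_model()`: slope near 1, calibration-in-the-large near
0).

## Problem sizes and numerical choices

The test-suite simulations use the design cohort sizes (857/354), 2000
observations for calibration-recovery checks, 20 generator seeds for
prevalence checks, and reduced grids for coverage simulations -- sizes
chosen to make Monte-Carlo error a small fraction of the tolerances being
asserted. Tolerances in stochastic tests are stated in sampling-error units
(3-4 standard errors) rather than absolute fudge factors. Degenerate
inputs are handled by marker objects, not exceptions, wherever a downstream
table should still render: zero denominators give undefined-estimate
markers, single-class C indices are undefined, constant risks flag the
calibration report.

## Known limitations

* ADNEX, simple-rules-risk and ORADS defaults are synthetic stand-ins; any
  absolute risk they output is meaningful only within the synthetic world.
* The paired-difference interval is Wald-type; it can degenerate when
  discordant counts are zero (the continuity correction keeps it
  non-empty).
* No decision-curve analysis, likelihood ratios, hierarchical meta-analysis
  across centres, or MNAR sensitivity modelling; imputation is
  single-level.
* The 12-month surveillance arm of the reference standard is modelled as
  error-free; verification bias is out of scope.

## Reproducing the analysis

The numbered scripts under `analysis/` run the whole pipeline on the
synthetic cohort (simulate, score, compare, discriminate/calibrate, impute,
replicate). `scripts/acceptance.R --seed <int> --out <path>` recomputes the
headline quantities from scratch and writes them as JSON.
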
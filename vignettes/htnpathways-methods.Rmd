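---
title: "Methods: anti-hypertensive treatment pathways and change-factor analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anti-hypertensive treatment pathways and change-factor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(htnpathways)
```

## The problem

Frequent changes to a patient's anti-hypertensive regimen are associated
with reduced adherence, so identifying baseline factors that predict a
coming medication change is clinically useful. Estimating those factors
from routinely collected data requires a chain of operational decisions:
who counts as continuously treated, what counts as "the regimen", what
counts as "a change", and how confounding between patients whose
medications were and were not changed is controlled. `htnpathways`
implements this chain end to end on a four-table OMOP-CDM-style extract
(persons, drug exposures, condition occurrences, measurements), and ships
a synthetic-data generator with a ground-truth log so that every stage can
be validated without access to protected health records.

## Cohort definition

* **Index date.** The first anti-hypertensive prescription start preceded
  by at least 365 days of recorded clinical history. History is anchored
  at the person's earliest record of any kind (drug, condition or
  measurement). Whether "prior history" should be anchored at an
  observation-period start or at a first visit is genuinely open in
  routine extracts; the earliest-record reading is the conventional
  observation-period interpretation and is the package's choice.
* **Follow-up.** Exactly 1,095 days (3 years); the exit date is
  `index + 1095`.
* **Continuity.** A person is continuously treated when the union of
  their exposure intervals clipped to the follow-up window covers at
  least 875 days (80% of 1,095) *and* no drug holiday between adjacent
  covered intervals exceeds 30 days. Coverage is computed on a day-grid
  union, so overlapping prescriptions are not double-counted, and the
  holiday between two refills is `next start − previous end − 1`: a
  refill on the day after exhaustion is a 0-day holiday.
* **Exclusions**, applied in a fixed order so attrition counts are
  deterministic: age < 18 at index; major surgery in `[index, exit]`;
  pregnancy in `[index, exit]`; any human chorionic gonadotropin
  measurement strictly greater than 5 mIU/mL in `[index, exit]`; no blood
  pressure measurement before the index date.
* **Baseline window.** Covariates are collected over the half-open window
  `[index − 365, index)`; index-day records belong to follow-up, which
  keeps the index prescription itself out of baseline. The sensitivity
  analysis re-runs everything with a 183-day window (6 months is not a
  defined day count; 183 is the package's fixed choice).

## Regimens and the change taxonomy

Prescription records are first collapsed into **drug eras** per
(ingredient, daily dose): refills separated by at most the same 30-day
gap tolerance are stitched into maximal eras. Using one persistence
constant for eligibility and era stitching avoids incoherent windows; the
tolerance is an argument everywhere it is used. The follow-up window is
then partitioned at every era boundary into **regimens** — maximal
intervals with a constant (ingredient, dose) member set. Full drug
holidays are bridged by carrying the previous member set forward, so the
regimens tile the window exactly. A regimen is a combination therapy when
it holds two or more distinct ingredients or classes.

Regimens persisting fewer than 30 days are deleted and absorbed into the
preceding persisted regimen (the first regimen is always kept), so a
transient excursion — a two-week add-on that is reverted — is not a
change. The filter is a fixpoint: filtering twice changes nothing.

Each transition between consecutive persisted regimens is classified into
exactly one of six modes by the first matching rule:

1. identical ingredient set, at least one total daily dose differs:
   **dose increased** if every differing dose rises, **dose reduced** if
   every differing dose falls;
2. previous ingredients a strict subset of the next: **medication added**;
3. next a strict subset of the previous: **medication removed**;
4. identical class multiset, different ingredients: **changed within
   class**;
5. otherwise: **changed to a different class**.

The source descriptions allow a change to be "any combination" of these
situations, but the published change table assigns each event one mode;
a fixed precedence is the only way to reproduce that deterministically.
Two consequences are worth flagging. Mixed dose moves (one ingredient up,
another down) fail rule 1's directionality and fall through to rule 5.
And a simultaneous one-for-one substitution across classes is treated as
a cross-class change rather than an add plus a remove; published tables
do not disambiguate this, so the package picks one reading and documents
it rather than asserting it as the original authors' rule. Similarly,
each regimen transition counts as one event regardless of how many drugs
it touches.

Dose comparison uses exact equality of total daily dose (mg/day) per
ingredient; no cross-ingredient dose-equivalence conversion is attempted,
and fixed-dose combination pills must arrive pre-split into ingredient
rows — the engine never parses product names.

The class-level view of the persisted sequence (classes sorted
ACEi < ARB < BB < CCB < DU < OTHER, joined with `+`) yields the pathway
labels used for the initial-regimen table, the change-mode table and the
Sankey node/link export. A dose-only change is invisible at class level,
so consecutive identical labels collapse. Sequences are truncated to five
steps; truncation never alters earlier labels.

## Phenotyping

Three comorbidities are operationally defined from labs and diagnosis
categories (each rule is an OR over clauses; comparator strictness
follows the definitions exactly):

* **dyslipidemia**: TC ≥ 240, LDL ≥ 160, TG ≥ 200, HDL < 40 mg/dL, or a
  dyslipidemia diagnosis;
* **liver disease**: AST or ALT ≥ 120 IU/L (3 × the upper limit of
  normal), or steatosis/cirrhosis/hepatitis;
* **renal disease**: serum creatinine > 1.4 mg/dL, MDRD eGFR
  < 60 mL/min/1.73 m², or renal failure / chronic kidney disease.

The MDRD equation is the 4-variable IDMS-traceable variant
(coefficient 175); the legacy 186 coefficient is available through an
argument because which re-expression a laboratory used is often unknown.
All other history flags are plain category-token lookups: the package
deliberately carries no ICD/SNOMED code lists, so the `condition_category`
token is the interface. Concomitant-medication categories ride on the
same token stream with an `rx:` prefix and become `rx_*` covariates;
hospitalization is a reserved token. Note that a diagnosis token such as
`chronic_kidney_disease` also surfaces as its own covariate column next
to the composite lab phenotype — both views are kept because they answer
different questions.

## Association analysis

Baseline comparisons use Student's t-test for continuous covariates and
Pearson's chi-square for categorical ones, switching to Fisher's exact
test when any expected cell is below 5 (the conventional criterion; the
switch rule is not stated in the source descriptions).

The propensity model is a main-effects logistic regression of group
membership on index year, age, sex, the concomitant-medication count and
the general medical-history flags. "Prescription records" as a matching
covariate is ambiguous in the source; the package reads it as the count
of distinct baseline medication categories, and the covariate list is an
argument. Matching is greedy 1:1 nearest-neighbour without replacement on
the logit scale with a caliper of 0.2 SD of the logit scores — the
field-standard default, chosen because the original procedure is not
specified beyond "1:1 propensity score matching". The smaller group
drives the matching (consistent with published cohort sizes shrinking on
both sides), candidates are processed in descending score order, and ties
are broken by a seeded shuffle so results are reproducible.

Univariate and multivariate associations are logistic regressions on the
matched cohort. Multivariate selection starts from the main-effects model
and steps in both directions within the scope of all second-order
interactions, minimising AIC (`MASS::stepAIC`, which also enforces model
hierarchy). Confidence intervals are profile-likelihood by default with a
Wald fallback; the characteristic asymmetric rare-event intervals only
arise from profile CIs, while point estimates are method-invariant.
α = 0.05 throughout, with no multiplicity correction (none is applied in
the source analysis). Binary covariates need at least 5 positives and 5
negatives to enter the regressions; (quasi-)separation is detected and
reported as an error naming the term rather than silently returning a
divergent estimate.

## The synthetic-data generator

`sim_config()` defaults *are* the study conditions the pipeline targets:
age 62.8 ± 10.8 years, 55.5% male, 63.2/27.5/9.3% mono/dual/triple-plus
initial regimens, an ARB- and CCB-dominated class mix, 30-day refills,
and baseline comorbidity prevalences matching the published baseline
table. The probability of belonging to the changed group follows
`plogis(intercept + Σ β·covariate)`; the default effects are 0.02 per
mmHg of diastolic blood pressure and ln 10 for arrhythmia, the two
dominant published adjusted effects, with the intercept set so that
roughly half the cohort is changed. For changed persons, 1 + Poisson(1.5)
regimen edits (capped at 7) of randomly chosen applicable modes are
written into the refill stream at days at least 61 days apart, so every
planted regimen persists beyond the 30-day filter. Where the source
states no value — the refill-interval distribution of the original
hospital's pharmacy, for instance — the defaults (30-day refills, short
occasional gaps) are what the package considers realistic for a
tertiary-care refill stream, stated here once and not asserted as
faithful to any particular institution.

Eligibility violations are planted at most one per person, each
constructed to fail exactly its own rule: a truncated prescription chain
(no qualifying index), one forced > 30-day holiday, age 15–17, a
surgery/pregnancy condition or an hCG > 5 measurement inside follow-up,
or missing pre-index blood pressure. The last pre-index blood-pressure
measurement carries the exact covariate value used by the change model
(an earlier reading adds measurement noise), so downstream regressions
see the same covariate the truth was generated from. Routine labs are
clamped clear of the phenotype thresholds unless the phenotype is
planted, and routine creatinine sits outside the baseline window, so
planted flags are recovered exactly rather than approximately.

Every stage draws from its own RNG stream derived from the single config
seed, so adding a table never perturbs another table's draws, and
identical configs produce byte-identical bundles.

What the generator does *not* emulate: visit/provider structure beyond
tokens, real product strengths or concept-ID vocabularies, dose
titration trajectories, informative missingness in labs, or correlation
between comorbidities. Passing tests on synthetic data therefore
demonstrate the *logic* of the pipeline — interval algebra, rule
boundaries, estimator calibration — not the clinical realism of any
particular dataset. One visible consequence: the overall median number
of changes per eligible person is about 1 under the defaults, whereas
the published cohort reports a median of 2; the published figure's
denominator (all subjects vs. changed subjects) is ambiguous, so the
generator was not tuned to it.

## Numerical choices and degenerate inputs

* Dates are integer day offsets from an anchor date; all intervals are
  closed `[start, end]`. ISO-8601 appears only at the CSV boundary, and
  refill records carry an explicit end day (`start + supply − 1`), the
  CDM-conventional encoding.
* An exposure set that never covers the window yields coverage 0 and
  "not continuous", not an error; an empty regimen list yields zero
  change events and the "unchanged" label.
* `classify_change` on identical member sets is a contract violation and
  errors; zero cells in a 2×2 table error unless the Haldane–Anscombe
  0.5 correction is requested explicitly.
* Matching with an empty group errors; a caliper that cannot be computed
  (zero score variance) is treated as infinite.
* Tables are written with stable row ordering (person, then day) so
  repeated writes are byte-identical.

## Problem sizes used by the test-suite

The bundled tests run the full pipeline on simulated cohorts of 120–800
persons, recover planted effects on a 5,000-person cohort, check
confidence-interval coverage over 500 null replicates of 300
observations, and compare the interval algebra against brute-force
day-grid oracles on 1,000+ random exposure sets over 2,000-day horizons —
sizes chosen as the smallest at which the binomial/logistic standard
errors make the checks sharp.

## Known limitations

* Category tokens are trusted as given; no vocabulary mapping or
  ingredient-to-class assignment is performed (the ingredient→class map
  of the original study is not public, so `drug_class` must arrive
  pre-assigned).
* The continuity requirement selects adherent patients by construction;
  estimates generalise to continuously treated populations only.
* Greedy matching is order-dependent by design (deterministic given the
  seed); optimal matching is out of scope.
* The stepwise-AIC endpoint is a local minimum; the tests verify
  agreement with exhaustive enumeration on small candidate sets, not
  global optimality in general.
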
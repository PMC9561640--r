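# htnpathways

Treatment-pathway analysis of anti-hypertensive prescribing in
OMOP-CDM-style observational data, for pharmacoepidemiologists who need a
reproducible chain from raw prescription/diagnosis/measurement tables to
"which baseline factors are associated with a medication change".

From a four-table extract (persons, drug exposures, condition
occurrences, measurements) the package:

1. **builds the eligible cohort** — index date = first anti-hypertensive
   prescription with ≥ 365 days of prior history, a fixed 1,095-day
   follow-up, continuity defined as ≥ 875 covered days with no > 30-day
   drug holiday, and ordered exclusions (age < 18, surgery, pregnancy,
   hCG > 5 mIU/mL, missing pre-index blood pressure);
2. **reconstructs regimens** — refills are stitched into drug eras per
   (ingredient, daily dose) with a 30-day gap tolerance, the follow-up is
   partitioned into maximal constant-regimen intervals, sub-30-day
   excursions are filtered out, and every persisted transition is
   classified into one of six modes (dose ↑, dose ↓, added, removed,
   changed within class, changed to a different class);
3. **phenotypes comorbidities** — dyslipidemia (TC ≥ 240, LDL ≥ 160,
   TG ≥ 200, HDL < 40 mg/dL or diagnosis), liver disease (AST/ALT ≥ 120
   IU/L or diagnosis) and renal disease (creatinine > 1.4 mg/dL, MDRD
   eGFR < 60 mL/min/1.73 m², or diagnosis), with
   eGFR = 175 · scr⁻¹·¹⁵⁴ · age⁻⁰·²⁰³ · 0.742(female) · 1.212(black);
4. **estimates change factors** — 1:1 greedy propensity matching on the
   logit scale (caliper 0.2 SD), baseline t/χ²/Fisher comparisons, crude
   odds ratios OR = ad/bc with profile-likelihood CIs, and multivariate
   logistic regression selected by stepwise AIC over main effects and
   their second-order interactions, plus a 6-month-baseline sensitivity
   re-run.

A synthetic-data generator (`sim_config()` / `simulate_omop()`) emulates
refill streams, planted change events governed by a known logistic model,
labs and diagnoses consistent with the phenotype thresholds, and planted
eligibility violations — with a ground-truth log, so the whole pipeline
is testable end to end. See `vignette("htnpathways-methods")` for the
modelling decisions.

## Worked example

```r
library(htnpathways)

sim <- simulate_omop(sim_config(n_persons = 600, rng_seed = 42))
fit <- htn_pathway_analysis(sim$bundle, seed = 1, stepwise = FALSE)
fit
#> Anti-hypertensive treatment-pathway analysis
#>   screened 600 -> eligible 516 -> matched 442 (221 pairs)
#>   changed 221 / unchanged 221; 652 change events; baseline window 365 days
```

600 simulated persons are screened; 84 fall to the eligibility rules
(`attrition_table(fit$cohort)` itemises them: 9 without sufficient prior
history, 40 discontinuous, 3 under-age, 21 surgery, 3 pregnancy, 2 hCG,
6 without baseline blood pressure), and greedy matching pairs 221 changed
with 221 unchanged persons. The strongest univariate associations on the
matched cohort recover the effects the generator planted (diastolic blood
pressure and arrhythmia):

```r
head(fit$univariate[order(fit$univariate$p_value),
                    c("covariate", "or", "ci_low", "ci_high", "p_value")])
#>    covariate    or ci_low ci_high p_value
#>   arrhythmia 4.649  1.181  30.723   0.051
#>          dbp 1.015  0.996   1.034   0.122
#> rx_sedatives 1.394  0.909   2.147   0.129
#>    ...
```

The wide, asymmetric arrhythmia interval is the profile-likelihood CI of
a rare exposure. Individual pieces are usable on their own, e.g. a crude
odds ratio from a published 2×2 (here 3/294 exposed changed vs 9/288
unexposed):

```r
crude_or(3, 294, 9, 288, covariate = "insomnia")
#>   covariate        or     ci_low  ci_high    p_value adjusted
#> 1  insomnia 0.3265306 0.07190955 1.106929 0.09570964    FALSE

mdrd_egfr(1.0, 60, female = TRUE)
#> [1] 56.56998   # below 60: the renal phenotype fires
```

`write_report(fit, "report/")` emits the full artifact set
(`attrition.csv`, `table1.csv`, `initial_regimens.csv`,
`change_modes.csv`, `table4.csv`, `sankey.json`, `run_log.txt`), and
`inst/cli/htnpathways.R` wraps the same functions as `simulate` /
`validate` / `build-cohort` / `pathways` / `run-all` subcommands.

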
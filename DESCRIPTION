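Package: htnpathways
Title: Treatment-Pathway Analysis of Anti-Hypertensive Medication Changes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for treatment-pathway analysis of
    anti-hypertensive prescribing in OMOP-CDM-style observational data.
    From flat person/drug-exposure/condition/measurement tables it builds an
    eligible cohort (index date with a prior-history requirement, a fixed
    1,095-day follow-up, coverage and drug-holiday continuity rules,
    exclusions), constructs drug eras and regimens with a gap tolerance,
    detects and classifies persisted medication changes into a six-mode
    taxonomy (dose increased/reduced, medication added/removed, changed
    within class, changed to a different class), phenotypes dyslipidemia,
    liver and renal disease from laboratory thresholds (including the MDRD
    eGFR equation), and estimates factors associated with medication change
    via 1:1 propensity-score matching and univariate/multivariate logistic
    regression with AIC-based stepwise selection. A bundled synthetic-data
    generator with a ground-truth log makes every stage testable without
    access to real electronic health records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
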
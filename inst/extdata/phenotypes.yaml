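# Operational phenotype definitions: lab thresholds (with units) and the
# diagnosis-category tokens that satisfy each rule. Each rule is an OR over
# its clauses. Comparators: *_ge = inclusive >=, *_lt = strict <,
# *_gt = strict >.
dyslipidemia:
  tc_ge: 240      # total cholesterol, mg/dL
  hdl_lt: 40      # HDL cholesterol, mg/dL
  ldl_ge: 160     # LDL cholesterol, mg/dL
  tg_ge: 200      # triglycerides, mg/dL
  diagnoses: [dyslipidemia]
liver_disease:
  ast_ge: 120     # IU/L, 3x upper limit of normal
  alt_ge: 120     # IU/L
  diagnoses: [steatosis_of_liver, cirrhosis, hepatitis]
renal_disease:
  scr_gt: 1.4     # serum creatinine, mg/dL
  egfr_lt: 60     # MDRD eGFR, mL/min/1.73 m^2
  diagnoses: [renal_failure, chronic_kidney_disease]
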
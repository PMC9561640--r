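## Lab/diagnosis phenotyping rules for dyslipidemia, liver and renal
## disease. All other history flags are plain category lookups (see
## build_baseline_covariates); only these three carry lab clauses.

#' MDRD estimated glomerular filtration rate
#'
#' Four-variable MDRD equation:
#' `eGFR = k * scr^-1.154 * age^-0.203 * (0.742 if female) * (1.212 if black)`
#' in mL/min/1.73 m^2. The default coefficient `k = 175` is the
#' IDMS-traceable re-expression; `k = 186` selects the legacy variant for
#' laboratories with non-standardised creatinine assays.
#'
#' @param scr serum creatinine, mg/dL (must be > 0).
#' @param age age in years (>= 18; the equation is not validated below).
#' @param female,black logical demographic indicators.
#' @param coefficient 175 (IDMS, default) or 186 (legacy).
#' @return eGFR in mL/min/1.73 m^2 (vectorised).
#' @examples
#' mdrd_egfr(1.0, 60, female = TRUE)   # ~56.6, below the 60 threshold
#' mdrd_egfr(1.0, 60, female = FALSE)  # ~76.2
#' @export
mdrd_egfr <- function(scr, age, female, black = FALSE, coefficient = 175) {
  if (any(scr <= 0)) stop("serum creatinine must be positive")
  if (any(age < 18)) stop("MDRD eGFR is defined for adults (age >= 18)")
  coefficient * scr^(-1.154) * age^(-0.203) *
    ifelse(female, 0.742, 1) * ifelse(black, 1.212, 1)
}

#' Default phenotype rule set
#'
#' Reads the lab thresholds and diagnosis-category token lists for the
#' three operationally defined phenotypes from the `phenotypes.yaml` file
#' shipped with the package (or a user-supplied file with the same layout).
#'
#' @param path YAML rule file; default is the packaged rule set.
#' @return named list of rules (`dyslipidemia`, `liver_disease`,
#'   `renal_disease`).
#' @export
phenotype_rules <- function(path = system.file("extdata", "phenotypes.yaml",
                                               package = "htnpathways")) {
  yaml::read_yaml(path)
}

in_window <- function(day, window) day >= window[1L] & day < window[2L]

lab_values <- function(measurements, analyte, window) {
  sel <- measurements$analyte == analyte &
    in_window(measurements$day, window)
  measurements$value[sel]
}

has_diagnosis <- function(conditions, categories, window) {
  any(conditions$condition_category %in% categories &
        in_window(conditions$day, window))
}

#' Flag dyslipidemia from labs or diagnoses
#'
#' True iff any in-window record satisfies one clause of the disjunction:
#' total cholesterol >= 240 mg/dL, HDL < 40 mg/dL, LDL >= 160 mg/dL,
#' triglycerides >= 200 mg/dL, or any diagnosis in the dyslipidemia
#' category list. Comparator strictness follows the operational definition
#' exactly (>= for TC/LDL/TG, strict < for HDL).
#'
#' @param measurements data.frame (`analyte`, `value`, `day`) for one person.
#' @param conditions data.frame (`condition_category`, `day`) for one person.
#' @param window length-2 integer vector, half-open `[lo, hi)` day window.
#' @param rules rule list from [phenotype_rules()].
#' @return logical flag.
#' @export
flag_dyslipidemia <- function(measurements, conditions, window,
                              rules = phenotype_rules()) {
  r <- rules$dyslipidemia
  any(lab_values(measurements, "TC", window) >= r$tc_ge) ||
    any(lab_values(measurements, "HDL", window) < r$hdl_lt) ||
    any(lab_values(measurements, "LDL", window) >= r$ldl_ge) ||
    any(lab_values(measurements, "TG", window) >= r$tg_ge) ||
    has_diagnosis(conditions, r$diagnoses, window)
}

#' Flag liver disease from labs or diagnoses
#'
#' True iff any in-window AST or ALT is >= 120 IU/L (three times the upper
#' limit of normal) or any diagnosis of hepatic steatosis, cirrhosis or
#' hepatitis is recorded in the window.
#'
#' @inheritParams flag_dyslipidemia
#' @return logical flag.
#' @export
flag_liver_disease <- function(measurements, conditions, window,
                               rules = phenotype_rules()) {
  r <- rules$liver_disease
  any(lab_values(measurements, "AST", window) >= r$ast_ge) ||
    any(lab_values(measurements, "ALT", window) >= r$alt_ge) ||
    has_diagnosis(conditions, r$diagnoses, window)
}

#' Flag renal disease from labs or diagnoses
#'
#' True iff any in-window serum creatinine is strictly > 1.4 mg/dL, any
#' in-window creatinine implies an MDRD eGFR strictly < 60 mL/min/1.73 m^2,
#' or a renal-failure / chronic-kidney-disease diagnosis is recorded in the
#' window.
#'
#' @inheritParams flag_dyslipidemia
#' @param age,female,black demographics fed to [mdrd_egfr()].
#' @param coefficient MDRD coefficient (175 IDMS default, 186 legacy).
#' @return logical flag.
#' @export
flag_renal_disease <- function(measurements, conditions, window,
                               age, female, black = FALSE,
                               rules = phenotype_rules(),
                               coefficient = 175) {
  r <- rules$renal_disease
  scr <- lab_values(measurements, "SCR", window)
  scr <- scr[scr > 0]
  lab_hit <- any(scr > r$scr_gt) ||
    (length(scr) > 0 && age >= 18 &&
       any(mdrd_egfr(scr, age, female, black, coefficient) < r$egfr_lt))
  lab_hit || has_diagnosis(conditions, r$diagnoses, window)
}
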
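## Cohort construction: index date, continuity, exclusions, group
## assignment and baseline covariates.

EXCLUSION_REASONS <- c("no_prior_history", "discontinuous", "age",
                       "surgery", "pregnancy", "hcg", "no_baseline_bp")

#' Find the index date for one person
#'
#' The index date is the first anti-hypertensive prescription start that is
#' preceded by at least 365 days of recorded clinical history. History is
#' anchored at the person's earliest record of any kind (drug, condition or
#' measurement), the conventional observation-period reading.
#'
#' @param exposures data.frame of the person's drug exposures (needs
#'   `start_day`).
#' @param history_start_day day offset of the earliest record.
#' @param min_history_days required run-in, days.
#' @return integer index day, or `NA` if no exposure qualifies.
#' @export
find_index_date <- function(exposures, history_start_day,
                            min_history_days = MIN_HISTORY_DAYS) {
  if (nrow(exposures) == 0L || is.na(history_start_day)) return(NA_integer_)
  ok <- exposures$start_day - history_start_day >= min_history_days
  if (!any(ok)) return(NA_integer_)
  min(exposures$start_day[ok])
}

#' Assess treatment continuity over the follow-up window
#'
#' Coverage counts the calendar days covered by the union of exposure
#' intervals clipped to `[index_day, exit_day]` (overlaps are not
#' double-counted). The gap between adjacent covered intervals is
#' `next start - previous end - 1` (days with no supply at all); a refill
#' on the day after exhaustion is a 0-day holiday. Continuous treatment
#' requires `coverage >= min_coverage` days and no gap exceeding
#' `max_gap` days.
#'
#' @param exposures data.frame with `start_day`, `end_day`.
#' @param index_day,exit_day closed follow-up window.
#' @param min_coverage coverage floor in days (875 = 80% of 1,095).
#' @param max_gap drug-holiday tolerance in days.
#' @return list with `coverage_days`, `max_gap_days`, `continuous`.
#' @export
assess_continuity <- function(exposures, index_day, exit_day,
                              min_coverage = MIN_COVERAGE_DAYS,
                              max_gap = DEFAULT_GAP_DAYS) {
  iv <- clip_intervals(exposures$start_day, exposures$end_day,
                       index_day, exit_day)
  if (nrow(iv) == 0L) {
    return(list(coverage_days = 0L, max_gap_days = NA_integer_,
                continuous = FALSE))
  }
  m <- merge_intervals(iv$start, iv$end, gap = 0L)
  gaps <- if (nrow(m) > 1L) m$start[-1L] - m$end[-nrow(m)] - 1L else 0L
  cov <- interval_days(m)
  mg <- as.integer(max(0L, gaps))
  list(coverage_days = as.integer(cov), max_gap_days = mg,
       continuous = cov >= min_coverage && mg <= max_gap)
}

#' Apply the person-level exclusion rules
#'
#' Rules are evaluated in a fixed order and the first failing rule is
#' reported, which makes attrition counts deterministic:
#' age < 18 at index; any major-surgery condition in `[index, exit]`; any
#' pregnancy condition in `[index, exit]`; any hCG measurement strictly
#' greater than 5 mIU/mL in `[index, exit]`; no SBP/DBP measurement before
#' the index date.
#'
#' @param age_at_index age in years on the index date.
#' @param conditions data.frame (`condition_category`, `day`) for the
#'   person.
#' @param measurements data.frame (`analyte`, `value`, `day`) for the
#'   person.
#' @param index_day,exit_day follow-up window.
#' @param surgery_categories,pregnancy_categories condition tokens treated
#'   as major surgery / pregnancy.
#' @return `NA_character_` if the person passes, else the first failing
#'   rule: one of `"age"`, `"surgery"`, `"pregnancy"`, `"hcg"`,
#'   `"no_baseline_bp"`.
#' @export
apply_exclusions <- function(age_at_index, conditions, measurements,
                             index_day, exit_day,
                             surgery_categories = "major_surgery",
                             pregnancy_categories = "pregnancy") {
  in_followup <- function(day) day >= index_day & day <= exit_day
  if (age_at_index < 18) return("age")
  if (any(conditions$condition_category %in% surgery_categories &
            in_followup(conditions$day))) return("surgery")
  if (any(conditions$condition_category %in% pregnancy_categories &
            in_followup(conditions$day))) return("pregnancy")
  hcg <- measurements$analyte == "HCG" & in_followup(measurements$day)
  if (any(measurements$value[hcg] > 5)) return("hcg")
  bp <- measurements$analyte %in% c("SBP", "DBP") &
    measurements$day < index_day
  if (!any(bp)) return("no_baseline_bp")
  NA_character_
}

#' Assign the changed/unchanged group label
#'
#' A person is `changed` iff at least one persisted change event falls in
#' the half-open interval `(index_day, exit_day]`; transient (< 30 day)
#' regimens have already been filtered upstream.
#'
#' @param change_events data.frame from [detect_changes()] (needs `day`).
#' @param index_day,exit_day follow-up window.
#' @return `"changed"` or `"unchanged"`.
#' @export
assign_group <- function(change_events, index_day, exit_day) {
  if (nrow(change_events) &&
      any(change_events$day > index_day & change_events$day <= exit_day)) {
    "changed"
  } else {
    "unchanged"
  }
}

sanitize_token <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Baseline covariates for one person
#'
#' Builds the covariate map over the half-open baseline window
#' `[index - window_days, index)`: demographics, index year, last SBP/DBP
#' before index, the three lab-defined phenotypes
#' ([flag_dyslipidemia()] and friends), a binary flag per disease and
#' medication-use category token observed in the window, a hospitalization
#' flag, and counts of distinct comorbidity and concomitant-medication
#' categories. Medication-use categories are condition tokens prefixed
#' `rx:` and become covariates prefixed `rx_`.
#'
#' @param person one-row data.frame from the persons table.
#' @param measurements,conditions this person's records.
#' @param index_day index date (day offset).
#' @param window_days baseline window length: 365 (main) or 183
#'   (6-month sensitivity).
#' @param anchor_date bundle anchor (day 0) used for age and index year.
#' @param rules phenotype rules ([phenotype_rules()]).
#' @return named list of covariate values.
#' @export
build_baseline_covariates <- function(person, measurements, conditions,
                                      index_day, window_days = 365L,
                                      anchor_date = as.Date("2010-01-01"),
                                      rules = phenotype_rules()) {
  stopifnot(window_days %in% c(365L, 183L) || window_days > 0)
  window <- c(index_day - window_days, index_day)
  index_date <- anchor_date + index_day
  index_year <- as.integer(format(index_date, "%Y"))
  age <- index_year - person$birth_year

  last_bp <- function(analyte) {
    sel <- measurements$analyte == analyte & measurements$day < index_day
    if (!any(sel)) stop("missing baseline ", analyte,
                        " for person ", person$person_id,
                        " (should have been excluded)")
    measurements$value[sel][which.max(measurements$day[sel])]
  }

  in_win <- conditions$day >= window[1L] & conditions$day < window[2L]
  toks <- unique(conditions$condition_category[in_win])
  special <- c("major_surgery", "pregnancy", "hospitalization")
  rx_toks <- toks[startsWith(toks, "rx:")]
  dx_toks <- setdiff(toks[!startsWith(toks, "rx:")], special)

  cov <- list(
    age = age,
    male = as.integer(person$sex == "M"),
    index_year = index_year,
    sbp = last_bp("SBP"),
    dbp = last_bp("DBP"),
    hospitalization = as.integer("hospitalization" %in% toks),
    n_comorbidities = length(dx_toks),
    n_concomitant_meds = length(rx_toks),
    dyslipidemia = as.integer(
      flag_dyslipidemia(measurements, conditions, window, rules)),
    liver_disease = as.integer(
      flag_liver_disease(measurements, conditions, window, rules)),
    renal_disease = as.integer(
      flag_renal_disease(measurements, conditions, window,
                         age = age, female = person$sex == "F",
                         black = isTRUE(person$race_flag), rules = rules)))
  for (t in dx_toks) cov[[sanitize_token(t)]] <- 1L
  for (t in rx_toks) cov[[paste0("rx_", sanitize_token(sub("^rx:", "", t)))]] <- 1L
  cov
}

#' Build the analysis cohort from a table bundle
#'
#' Runs the full eligibility pipeline for every person: index date
#' ([find_index_date()]), fixed 1,095-day follow-up, continuity
#' ([assess_continuity()]), exclusions ([apply_exclusions()]), regimen
#' construction and persisted-change detection (regimen engine), group
#' assignment ([assign_group()]) and baseline covariates
#' ([build_baseline_covariates()]).
#'
#' @param bundle an [omop_bundle()].
#' @param window_days baseline covariate window (365 or 183).
#' @param gap_tolerance drug-holiday tolerance, days.
#' @param persist_days persistence threshold for regimen changes, days.
#' @param min_coverage continuity coverage floor, days.
#' @param followup_days cohort exit offset from index, days.
#' @param max_steps regimen-sequence truncation for pathway summaries.
#' @param rules phenotype rules.
#' @return object of class `htn_cohort`: a person-level data.frame of the
#'   eligible cohort (index/exit days, group, `first_regimen`, `n_changes`
#'   and covariate columns, absent flags filled with 0) with attributes
#'   `attrition` (ordered stage counts), `exclusions` (per-person verdicts
#'   for all screened persons), `changes` (all persisted change events of
#'   eligible persons) and `sequences` (named list of class-label
#'   sequences).
#' @export
build_cohort <- function(bundle, window_days = 365L,
                         gap_tolerance = DEFAULT_GAP_DAYS,
                         persist_days = DEFAULT_PERSIST_DAYS,
                         min_coverage = MIN_COVERAGE_DAYS,
                         followup_days = FOLLOWUP_DAYS,
                         max_steps = 5L,
                         rules = phenotype_rules()) {
  anchor <- attr(bundle, "anchor_date")
  persons <- bundle$persons
  ids <- persons$person_id
  de <- split(bundle$drug_exposures,
              factor(bundle$drug_exposures$person_id, levels = ids))
  co <- split(bundle$condition_occurrences,
              factor(bundle$condition_occurrences$person_id, levels = ids))
  me <- split(bundle$measurements,
              factor(bundle$measurements$person_id, levels = ids))

  screened <- which(vapply(de, nrow, integer(1)) > 0L)
  verdicts <- data.frame(person_id = ids[screened],
                         index_day = NA_integer_, eligible = FALSE,
                         exclusion = NA_character_,
                         group = NA_character_)
  rows <- list(); changes <- list(); sequences <- list()

  for (k in seq_along(screened)) {
    i <- screened[k]
    pid <- ids[i]
    ex <- de[[i]]; cnd <- co[[i]]; msr <- me[[i]]
    hist_start <- suppressWarnings(
      min(c(ex$start_day, cnd$day, msr$day)))
    idx <- find_index_date(ex, hist_start)
    if (is.na(idx)) {
      verdicts$exclusion[k] <- "no_prior_history"
      next
    }
    verdicts$index_day[k] <- idx
    exit <- idx + followup_days
    cont <- assess_continuity(ex, idx, exit,
                              min_coverage = min_coverage,
                              max_gap = gap_tolerance)
    if (!cont$continuous) {
      verdicts$exclusion[k] <- "discontinuous"
      next
    }
    index_year <- as.integer(format(anchor + idx, "%Y"))
    age <- index_year - persons$birth_year[i]
    reason <- apply_exclusions(age, cnd, msr, idx, exit)
    if (!is.na(reason)) {
      verdicts$exclusion[k] <- reason
      next
    }
    eras <- build_drug_eras(ex, gap_tolerance = gap_tolerance)
    regs <- filter_transient_regimens(
      derive_regimens(eras, idx, exit), min_days = persist_days)
    ev <- detect_changes(regs)
    grp <- assign_group(ev, idx, exit)
    verdicts$eligible[k] <- TRUE
    verdicts$group[k] <- grp
    cov <- build_baseline_covariates(persons[i, , drop = FALSE], msr, cnd,
                                     idx, window_days = window_days,
                                     anchor_date = anchor, rules = rules)
    seq_labels <- extract_sequence(regs, max_steps = max_steps)
    sequences[[as.character(pid)]] <- seq_labels
    if (nrow(ev)) {
      ev$person_id <- pid
      changes[[length(changes) + 1L]] <- ev
    }
    rows[[length(rows) + 1L]] <- c(
      list(person_id = pid, index_day = idx, exit_day = exit,
           group = grp, first_regimen = seq_labels[1L],
           n_changes = nrow(ev),
           coverage_days = cont$coverage_days,
           max_gap_days = cont$max_gap_days),
      cov)
  }

  # assemble with a consistent covariate universe (absent flags -> 0)
  all_names <- unique(unlist(lapply(rows, names)))
  cohort <- as.data.frame(do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(all_names, names(r))
    for (mn in miss) r[[mn]] <- 0L
    r[all_names]
  })))
  if (length(rows)) {
    for (nm in all_names) cohort[[nm]] <- unlist(cohort[[nm]])
  } else {
    cohort <- data.frame(person_id = integer(), index_day = integer(),
                         exit_day = integer(), group = character(),
                         first_regimen = character(), n_changes = integer())
  }

  reason_counts <- vapply(EXCLUSION_REASONS, function(r) {
    sum(verdicts$exclusion == r, na.rm = TRUE)
  }, integer(1))
  attrition <- data.frame(
    stage = c("screened", paste0("excluded_", EXCLUSION_REASONS),
              "eligible"),
    n = c(length(screened), reason_counts, sum(verdicts$eligible)))
  remaining <- length(screened) - cumsum(c(0L, reason_counts))
  attrition$remaining <- c(remaining, remaining[length(remaining)])

  changes <- if (length(changes)) do.call(rbind, changes) else
    data.frame(day = integer(), mode = character(),
               prev_label = character(), next_label = character(),
               person_id = integer())
  structure(cohort, class = c("htn_cohort", "data.frame"),
            attrition = attrition, exclusions = verdicts,
            changes = changes, sequences = sequences,
            window_days = window_days, anchor_date = anchor)
}

#' @export
print.htn_cohort <- function(x, ...) {
  at <- attr(x, "attrition")
  cat(sprintf("Analysis cohort: %d eligible of %d screened\n",
              nrow(x), at$n[at$stage == "screened"]))
  if (nrow(x)) {
    cat(sprintf("  changed %d / unchanged %d; baseline window %d days\n",
                sum(x$group == "changed"), sum(x$group == "unchanged"),
                attr(x, "window_days")))
  }
  invisible(x)
}

#' Attrition table of a cohort
#'
#' Ordered stage-by-stage record of screened persons, per-reason
#' exclusions, and the final eligible count; counts telescope.
#'
#' @param cohort an `htn_cohort`.
#' @return data.frame with `stage`, `n`, `remaining`.
#' @export
attrition_table <- function(cohort) attr(cohort, "attrition")
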
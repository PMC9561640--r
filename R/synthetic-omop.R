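## Synthetic OMOP-style data generator with a ground-truth log.
## Emulates refill-style anti-hypertensive prescribing, regimen-change
## events governed by a logistic model on person covariates, baseline labs
## and diagnoses consistent with the phenotype thresholds, and planted
## eligibility violations -- so every downstream stage can be tested
## against known truth.

# ingredients per class with a base daily dose (mg/day); doses are
# synthetic round numbers, not product strengths
SIM_FORMULARY <- list(
  ACEi  = c(ramipril = 5,  enalapril = 10),
  ARB   = c(losartan = 50, valsartan = 80, telmisartan = 40),
  BB    = c(bisoprolol = 5, carvedilol = 25),
  CCB   = c(amlodipine = 5, nifedipine = 30),
  DU    = c(hydrochlorothiazide = 25, chlorthalidone = 25),
  OTHER = c(doxazosin = 4, hydralazine = 50))

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by the
#' synthetic-data stages. Defaults reproduce the study conditions the
#' pipeline is designed for: a cohort with mean age 62.8 (SD 10.8) years,
#' 55.5% male, ARB/CCB-dominated initial prescribing with 63.2% / 27.5% /
#' 9.3% mono/dual/triple-plus initial regimens, 30-day refills with short
#' stochastic gaps, a ~52% changed fraction driven by diastolic blood
#' pressure (log-OR 0.02 per mmHg) and arrhythmia (log-OR ln 10), and
#' comorbidity prevalences matching the baseline table of a tertiary-care
#' hypertension cohort.
#'
#' @param n_persons number of persons to simulate.
#' @param rng_seed integer seed; every stage derives its own stream from it.
#' @param anchor_date calendar date of day 0.
#' @param study_days study horizon in days (> 1460 so a 365-day history and
#'   a 1,095-day follow-up fit).
#' @param index_day_range range the per-person index day is drawn from.
#' @param age_mean,age_sd age at index, years.
#' @param male_fraction probability of male sex.
#' @param class_weights named probability per anti-HTN class for the
#'   initial regimen (must sum to 1).
#' @param initial_combo_fractions probabilities of 1 / 2 / >=3 initial
#'   drugs (must sum to 1).
#' @param refill_interval_days days of supply per refill.
#' @param gap_probs named vector: probability of each inter-refill gap
#'   length (names are gap days; must sum to 1).
#' @param change_intercept log-odds intercept of the medication-change
#'   model.
#' @param covariate_effects named log-odds-ratios; names must be simulated
#'   covariates (`age_c`, `male`, `dbp_c`, `sbp_c`, phenotype or
#'   prevalence-flag names).
#' @param extra_changes_mean mean of the Poisson count of additional
#'   changes beyond the first for changed persons (total capped at 7).
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd blood-pressure distribution,
#'   mmHg.
#' @param prevalence named vector of binary covariate prevalences; names
#'   starting `rx_` are concomitant-medication categories, the rest are
#'   diagnosis categories; `dyslipidemia`, `liver_disease` and
#'   `renal_disease` are planted through lab thresholds or diagnoses.
#' @param exclusion_fractions named vector over
#'   `no_prior_history, discontinuous, age, surgery, pregnancy, hcg,
#'   no_baseline_bp`; each person is planted with at most one violation.
#' @param lab_noise_sd named vector of per-analyte measurement noise SDs.
#' @return object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_persons = 1000L,
                       rng_seed = 1L,
                       anchor_date = as.Date("2010-01-01"),
                       study_days = 1700L,
                       index_day_range = c(400L, 520L),
                       age_mean = 62.8, age_sd = 10.8,
                       male_fraction = 0.555,
                       class_weights = c(ACEi = 0.02, ARB = 0.42,
                                         BB = 0.10, CCB = 0.36,
                                         DU = 0.06, OTHER = 0.04),
                       initial_combo_fractions = c(0.632, 0.275, 0.093),
                       refill_interval_days = 30L,
                       gap_probs = c("0" = 0.75, "1" = 0.10, "2" = 0.05,
                                     "3" = 0.05, "4" = 0.03, "5" = 0.02),
                       change_intercept = 0.05,
                       covariate_effects = c(dbp_c = 0.02,
                                             arrhythmia = log(10)),
                       extra_changes_mean = 1.5,
                       sbp_mean = 135, sbp_sd = 15,
                       dbp_mean = 82, dbp_sd = 10,
                       prevalence = c(diabetes = 0.215,
                                      dyslipidemia = 0.461,
                                      liver_disease = 0.123,
                                      renal_disease = 0.099,
                                      gastrointestinal_diseases = 0.146,
                                      insomnia = 0.020,
                                      mental_behavioral_diseases = 0.057,
                                      angina_pectoris = 0.071,
                                      arrhythmia = 0.022,
                                      hospitalization = 0.150,
                                      rx_antianginal = 0.094,
                                      rx_nsaids = 0.374,
                                      rx_sedatives = 0.247,
                                      rx_gastrointestinal_agents = 0.470,
                                      rx_statins = 0.456),
                       exclusion_fractions = c(no_prior_history = 0.02,
                                               discontinuous = 0.05,
                                               age = 0.01,
                                               surgery = 0.02,
                                               pregnancy = 0.01,
                                               hcg = 0.01,
                                               no_baseline_bp = 0.02),
                       lab_noise_sd = c(SBP = 5, DBP = 4, TC = 15,
                                        HDL = 6, LDL = 12, TG = 30,
                                        AST = 8, ALT = 8, SCR = 0.08)) {
  cfg <- list(n_persons = as.integer(n_persons),
              rng_seed = as.integer(rng_seed),
              anchor_date = as.Date(anchor_date),
              study_days = as.integer(study_days),
              index_day_range = as.integer(index_day_range),
              age_mean = age_mean, age_sd = age_sd,
              male_fraction = male_fraction,
              class_weights = class_weights,
              initial_combo_fractions = initial_combo_fractions,
              refill_interval_days = as.integer(refill_interval_days),
              gap_probs = gap_probs,
              change_intercept = change_intercept,
              covariate_effects = covariate_effects,
              extra_changes_mean = extra_changes_mean,
              sbp_mean = sbp_mean, sbp_sd = sbp_sd,
              dbp_mean = dbp_mean, dbp_sd = dbp_sd,
              prevalence = prevalence,
              exclusion_fractions = exclusion_fractions,
              lab_noise_sd = lab_noise_sd)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_persons < 0L) stop("n_persons must be >= 0")
  if (abs(sum(cfg$class_weights) - 1) > 1e-9) {
    stop("class_weights must sum to 1")
  }
  if (!all(names(cfg$class_weights) %in% HTN_CLASSES)) {
    stop("class_weights names must be drug classes")
  }
  if (abs(sum(cfg$initial_combo_fractions) - 1) > 1e-9) {
    stop("initial_combo_fractions must sum to 1")
  }
  if (cfg$study_days <= 1460L) {
    stop("study_days must exceed 1460 (365-day history + 1,095-day follow-up)")
  }
  if (abs(sum(cfg$gap_probs) - 1) > 1e-9) stop("gap_probs must sum to 1")
  if (cfg$index_day_range[1L] < 365L) {
    stop("index_day_range must start at or after day 365")
  }
  if (cfg$index_day_range[2L] + FOLLOWUP_DAYS > cfg$study_days) {
    stop("index_day_range leaves no room for the 1,095-day follow-up")
  }
  if (any(cfg$exclusion_fractions < 0) ||
      sum(cfg$exclusion_fractions) >= 1) {
    stop("exclusion_fractions must be non-negative and sum to < 1")
  }
  bad <- setdiff(names(cfg$exclusion_fractions), EXCLUSION_REASONS)
  if (length(bad)) stop("unknown exclusion reason(s): ",
                        paste(bad, collapse = ", "))
  invisible(cfg)
}

sim_covariate_names <- function(cfg) {
  c("age_c", "male", "dbp_c", "sbp_c", names(cfg$prevalence))
}

# independent, reproducible stream per generation stage
stage_seed <- function(cfg, stage) {
  (abs(cfg$rng_seed) * 11L + stage * 7919L) %% 2147483629L
}

#' Generate the simulated population and seed the truth log
#'
#' Draws demographics, the per-person index day, measured blood pressure,
#' binary covariate flags, and at most one planted eligibility violation
#' per person (multinomial over `exclusion_fractions`; pregnancy/hCG
#' plants drawn for a male are reassigned to surgery). Deterministic given
#' the config seed.
#'
#' @param config a [sim_config()].
#' @return a `sim_state` list with `persons` (the OMOP persons table) and
#'   `truth` (the truth log; see [simulate_omop()]).
#' @export
generate_population <- function(config) {
  validate_sim_config(config)
  n <- config$n_persons
  set.seed(stage_seed(config, 1L))
  if (n == 0L) {
    persons <- data.frame(person_id = integer(), sex = character(),
                          birth_year = integer(), race_flag = logical())
    truth <- structure(list(persons = data.frame(),
                            changes = data.frame(person_id = integer(),
                                                 day = integer(),
                                                 mode = character()),
                            config = config),
                       class = "truth_log")
    return(structure(list(persons = persons, truth = truth,
                          config = config), class = "sim_state"))
  }
  sex <- ifelse(stats::runif(n) < config$male_fraction, "M", "F")
  planted <- sample(c("none", names(config$exclusion_fractions)), n,
                    replace = TRUE,
                    prob = c(1 - sum(config$exclusion_fractions),
                             config$exclusion_fractions))
  # pregnancy/hCG violations are female phenomena
  swap <- planted %in% c("pregnancy", "hcg") & sex == "M"
  planted[swap] <- "surgery"

  age <- round(stats::rnorm(n, config$age_mean, config$age_sd))
  age <- pmin(pmax(age, 20L), 95L)
  age[planted == "age"] <- sample(15:17, sum(planted == "age"),
                                  replace = TRUE)
  index_day <- sample(seq(config$index_day_range[1L],
                          config$index_day_range[2L]), n, replace = TRUE)
  index_year <- as.integer(format(config$anchor_date + index_day, "%Y"))
  birth_year <- index_year - age

  sbp <- round(stats::rnorm(n, config$sbp_mean, config$sbp_sd), 1L)
  dbp <- round(stats::rnorm(n, config$dbp_mean, config$dbp_sd), 1L)
  flags <- vapply(config$prevalence, function(p) {
    stats::runif(n) < p
  }, logical(n))
  if (n == 1L) flags <- matrix(flags, nrow = 1L,
                               dimnames = list(NULL,
                                               names(config$prevalence)))

  tp <- data.frame(person_id = seq_len(n), sex = sex, age = age,
                   index_day = index_day,
                   exit_day = index_day + FOLLOWUP_DAYS,
                   planted_exclusion = planted,
                   changed = NA, sbp = sbp, dbp = dbp)
  tp <- cbind(tp, as.data.frame(flags))
  truth <- structure(list(persons = tp,
                          changes = data.frame(person_id = integer(),
                                               day = integer(),
                                               mode = character()),
                          config = config),
                     class = "truth_log")
  persons <- data.frame(person_id = seq_len(n), sex = sex,
                        birth_year = birth_year,
                        race_flag = FALSE)
  structure(list(persons = persons, truth = truth, config = config),
            class = "sim_state")
}

# draw one person's initial member set
draw_initial_members <- function(cfg) {
  k <- sample(1:3, 1L, prob = cfg$initial_combo_fractions)
  classes <- sample(names(cfg$class_weights),
                    min(k, length(cfg$class_weights)),
                    prob = cfg$class_weights)
  members <- lapply(classes, function(cl) {
    ing <- sample(names(SIM_FORMULARY[[cl]]), 1L)
    data.frame(ingredient = ing, drug_class = cl,
               daily_dose = unname(SIM_FORMULARY[[cl]][ing]))
  })
  do.call(rbind, members)
}

# refill start/end days for one segment; gaps shared across members
segment_refills <- function(from, to, interval, gap_probs,
                            forced_gap_at = NA, forced_gap_days = 0L) {
  if (from > to) return(data.frame(start = integer(), end = integer()))
  m <- ceiling((to - from + 1L) / interval) + 2L
  gaps <- sample(as.integer(names(gap_probs)), m, replace = TRUE,
                 prob = gap_probs)
  if (!is.na(forced_gap_at) && forced_gap_at <= m) {
    gaps[forced_gap_at] <- forced_gap_days
  }
  starts <- from + cumsum(c(0L, interval + gaps[-m]))
  starts <- starts[starts <= to]
  data.frame(start = starts, end = pmin(starts + interval - 1L, to))
}

# expand refill schedule x member set into exposure rows
member_rows <- function(pid, members, refills) {
  nr <- nrow(refills); nm <- nrow(members)
  if (nr == 0L || nm == 0L) return(NULL)
  list(person_id = rep.int(pid, nr * nm),
       ingredient = rep(members$ingredient, each = nr),
       drug_class = rep(members$drug_class, each = nr),
       daily_dose = rep(members$daily_dose, each = nr),
       start_day = rep.int(refills$start, nm),
       end_day = rep.int(refills$end, nm))
}

#' Generate refill-style prescriptions for every person
#'
#' Each person receives a refill chain of their initial regimen from the
#' index day to the cohort exit: fixed days of supply, inter-refill gaps
#' drawn from `gap_probs`. Persons planted `discontinuous` get one forced
#' gap longer than 30 days; persons planted `no_prior_history` get a chain
#' truncated at ~180 days so no later prescription can qualify as an index
#' date.
#'
#' @param sim a `sim_state` from [generate_population()].
#' @param config the same [sim_config()].
#' @return the `sim_state` with a `drug_exposures` table added.
#' @export
generate_prescriptions <- function(sim, config = sim$config) {
  set.seed(stage_seed(config, 2L))
  tp <- sim$truth$persons
  n <- nrow(tp)
  acc <- vector("list", n)
  members_by_person <- vector("list", n)
  for (i in seq_len(n)) {
    members <- draw_initial_members(config)
    members_by_person[[i]] <- members
    from <- tp$index_day[i]
    to <- tp$exit_day[i]
    forced_at <- NA; forced_days <- 0L
    if (tp$planted_exclusion[i] == "no_prior_history") {
      to <- from + 180L
    } else if (tp$planted_exclusion[i] == "discontinuous") {
      # keep the forced holiday well inside the window so the post-gap
      # refills cannot be pushed past the exit (which would turn the
      # violation into an unmeasured trailing gap)
      n_refills <- ceiling((to - from + 1L) / config$refill_interval_days)
      forced_at <- sample(seq(2L, max(3L, n_refills - 12L)), 1L)
      forced_days <- 31L + sample(0:29, 1L)
    }
    refills <- segment_refills(from, to, config$refill_interval_days,
                               config$gap_probs, forced_at, forced_days)
    acc[[i]] <- member_rows(tp$person_id[i], members, refills)
  }
  sim$drug_exposures <- bind_row_lists(acc)
  sim$initial_members <- members_by_person
  sim
}

bind_row_lists <- function(acc) {
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (length(acc) == 0L) return(empty_drug_exposures())
  out <- lapply(names(acc[[1L]]), function(nm) {
    unlist(lapply(acc, `[[`, nm), use.names = FALSE)
  })
  names(out) <- names(acc[[1L]])
  as.data.frame(out)
}

# one regimen edit of the given mode applied to a member set; returns NULL
# when the mode is not applicable to the current set
apply_edit <- function(members, mode, cfg) {
  switch(mode,
    DOSE_INCREASED = {
      j <- sample(nrow(members), 1L)
      members$daily_dose[j] <- members$daily_dose[j] * 2
      members
    },
    DOSE_REDUCED = {
      j <- sample(nrow(members), 1L)
      members$daily_dose[j] <- members$daily_dose[j] / 2
      members
    },
    MEDICATION_ADDED = {
      free <- setdiff(HTN_CLASSES, members$drug_class)
      if (!length(free)) return(NULL)
      cl <- sample(free, 1L)
      ing <- sample(names(SIM_FORMULARY[[cl]]), 1L)
      rbind(members, data.frame(ingredient = ing, drug_class = cl,
                                daily_dose = unname(SIM_FORMULARY[[cl]][ing])))
    },
    MEDICATION_REMOVED = {
      if (nrow(members) < 2L) return(NULL)
      members[-sample(nrow(members), 1L), , drop = FALSE]
    },
    CHANGED_WITHIN_CLASS = {
      j <- sample(nrow(members), 1L)
      cl <- members$drug_class[j]
      alt <- setdiff(names(SIM_FORMULARY[[cl]]), members$ingredient)
      if (!length(alt)) return(NULL)
      ing <- sample(alt, 1L)
      members$ingredient[j] <- ing
      members$daily_dose[j] <- unname(SIM_FORMULARY[[cl]][ing])
      members
    },
    CHANGED_TO_DIFFERENT_CLASS = {
      free <- setdiff(HTN_CLASSES, members$drug_class)
      if (!length(free)) return(NULL)
      j <- sample(nrow(members), 1L)
      cl <- sample(free, 1L)
      ing <- sample(names(SIM_FORMULARY[[cl]]), 1L)
      members$ingredient[j] <- ing
      members$drug_class[j] <- cl
      members$daily_dose[j] <- unname(SIM_FORMULARY[[cl]][ing])
      members
    })
}

#' Plant regimen-change events according to a logistic model
#'
#' The probability that a person belongs to the changed group is
#' `plogis(change_intercept + sum(effects * covariates))`, where the
#' covariates are the simulated person attributes named in
#' `covariate_effects` (continuous ones centred: `dbp_c`, `sbp_c`,
#' `age_c`). For changed persons, 1 + Poisson(`extra_changes_mean`)
#' regimen edits (capped at 7) of randomly chosen applicable modes are
#' written into the prescription stream at days spaced >= 61 days apart
#' inside the follow-up window, so every planted regimen persists >= 30
#' days. Persons with a planted eligibility violation are never planted
#' with changes.
#'
#' @param sim a `sim_state` from [generate_prescriptions()].
#' @param config the same [sim_config()].
#' @return the `sim_state` with exposures rewritten for changed persons
#'   and the truth log updated (`changed` labels, `changes` table).
#' @export
plant_change_events <- function(sim, config = sim$config) {
  bad <- setdiff(names(config$covariate_effects),
                 sim_covariate_names(config))
  if (length(bad)) {
    stop("unknown covariate name(s) in covariate_effects: ",
         paste(bad, collapse = ", "))
  }
  set.seed(stage_seed(config, 3L))
  tp <- sim$truth$persons
  n <- nrow(tp)
  if (n == 0L) return(sim)

  covs <- data.frame(age_c = tp$age - config$age_mean,
                     male = as.numeric(tp$sex == "M"),
                     dbp_c = tp$dbp - config$dbp_mean,
                     sbp_c = tp$sbp - config$sbp_mean)
  for (nm in names(config$prevalence)) covs[[nm]] <- as.numeric(tp[[nm]])
  eta <- config$change_intercept
  for (nm in names(config$covariate_effects)) {
    eta <- eta + config$covariate_effects[[nm]] * covs[[nm]]
  }
  changed <- stats::runif(n) < stats::plogis(eta)
  changed[tp$planted_exclusion != "none"] <- FALSE
  sim$truth$persons$changed <- changed

  change_rows <- list()
  exposures <- sim$drug_exposures
  drop_pid <- integer()
  acc <- list()
  for (i in which(changed)) {
    pid <- tp$person_id[i]
    idx <- tp$index_day[i]; exit <- tp$exit_day[i]
    n_changes <- min(1L + stats::rpois(1L, config$extra_changes_mean), 7L)
    grid <- seq(idx + 61L, exit - 61L, by = 61L)
    n_changes <- min(n_changes, length(grid))
    days <- sort(sample(grid, n_changes))
    members <- sim$initial_members[[i]]
    seg_from <- idx
    person_acc <- list()
    planted <- data.frame(person_id = integer(), day = integer(),
                          mode = character())
    for (d in days) {
      mode <- NULL; new_members <- NULL
      for (m in sample(CHANGE_MODES)) {
        new_members <- apply_edit(members, m, config)
        if (!is.null(new_members)) { mode <- m; break }
      }
      if (is.null(mode)) next   # cannot edit (never happens in practice)
      refills <- segment_refills(seg_from, d - 1L,
                                 config$refill_interval_days,
                                 config$gap_probs)
      person_acc[[length(person_acc) + 1L]] <-
        member_rows(pid, members, refills)
      planted <- rbind(planted,
                       data.frame(person_id = pid, day = d, mode = mode))
      members <- new_members
      seg_from <- d
    }
    refills <- segment_refills(seg_from, exit, config$refill_interval_days,
                               config$gap_probs)
    person_acc[[length(person_acc) + 1L]] <-
      member_rows(pid, members, refills)
    if (nrow(planted)) {
      drop_pid <- c(drop_pid, pid)
      acc <- c(acc, person_acc)
      change_rows[[length(change_rows) + 1L]] <- planted
    } else {
      sim$truth$persons$changed[i] <- FALSE
    }
  }
  if (length(drop_pid)) {
    keep <- !(exposures$person_id %in% drop_pid)
    sim$drug_exposures <- rbind(exposures[keep, , drop = FALSE],
                                bind_row_lists(acc))
    sim$truth$changes <- do.call(rbind, change_rows)
  }
  sim
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate measurements and condition occurrences
#'
#' Every person (except `no_prior_history` plants) receives a history
#' anchor record ~400 days before index, pre-index SBP/DBP measurements
#' (the last one carrying the exact covariate value used by the change
#' model, an earlier one adding measurement noise), an in-window lipid and
#' liver panel with values clamped below the phenotype thresholds, and
#' diagnosis / medication-category condition rows for every planted binary
#' flag. Phenotype plants cross their thresholds through a randomly chosen
#' route (each lab clause or a diagnosis); planted exclusions produce the
#' corresponding surgery/pregnancy condition, an hCG measurement > 5, or
#' the absence of pre-index blood-pressure rows.
#'
#' @param sim a `sim_state` from [plant_change_events()].
#' @param config the same [sim_config()].
#' @return the `sim_state` with `condition_occurrences` and `measurements`
#'   tables added.
#' @export
generate_labs_and_conditions <- function(sim, config = sim$config) {
  set.seed(stage_seed(config, 4L))
  tp <- sim$truth$persons
  n <- nrow(tp)
  meas <- list(); cond <- list()
  add_meas <- function(pid, analyte, value, day) {
    meas[[length(meas) + 1L]] <<- list(person_id = pid, analyte = analyte,
                                       value = value,
                                       unit = analyte_unit(analyte),
                                       day = as.integer(day))
  }
  add_cond <- function(pid, category, day) {
    cond[[length(cond) + 1L]] <<- list(person_id = pid,
                                       condition_category = category,
                                       day = as.integer(day))
  }
  nsd <- config$lab_noise_sd
  for (i in seq_len(n)) {
    pid <- tp$person_id[i]
    idx <- tp$index_day[i]; exit <- tp$exit_day[i]
    plant <- tp$planted_exclusion[i]
    win_day <- function() idx - sample(30:300, 1L)  # inside [idx-365, idx)

    if (plant == "no_prior_history") {
      # only near-index BP: any earlier record would re-create a history
      # long enough for a later refill to qualify as an index date
      add_meas(pid, "SBP", tp$sbp[i], idx - 7L)
      add_meas(pid, "DBP", tp$dbp[i], idx - 7L)
      next
    }
    # history anchor, outside the baseline window
    add_meas(pid, "SCR", round(clamp(stats::rnorm(1, 0.9, nsd[["SCR"]]),
                                     0.5, 1.1), 2L), idx - 400L)
    if (plant == "no_baseline_bp") {
      add_meas(pid, "SBP", tp$sbp[i], idx + 10L)
      add_meas(pid, "DBP", tp$dbp[i], idx + 10L)
    } else {
      add_meas(pid, "SBP", round(tp$sbp[i] +
                                   stats::rnorm(1, 0, nsd[["SBP"]]), 1L),
               idx - 30L)
      add_meas(pid, "DBP", round(tp$dbp[i] +
                                   stats::rnorm(1, 0, nsd[["DBP"]]), 1L),
               idx - 30L)
      add_meas(pid, "SBP", tp$sbp[i], idx - 7L)
      add_meas(pid, "DBP", tp$dbp[i], idx - 7L)
    }
    if (plant == "surgery") add_cond(pid, "major_surgery",
                                     idx + sample(0:FOLLOWUP_DAYS, 1L))
    if (plant == "pregnancy") add_cond(pid, "pregnancy",
                                       idx + sample(0:FOLLOWUP_DAYS, 1L))
    if (plant == "hcg") add_meas(pid, "HCG", round(stats::runif(1, 25, 900)),
                                 idx + sample(0:FOLLOWUP_DAYS, 1L))

    # lipid/liver panel, clamped clear of the thresholds unless planted
    lip_day <- win_day()
    if (isTRUE(tp$dyslipidemia[i])) {
      route <- sample(c("TC", "HDL", "LDL", "TG", "dx"), 1L)
      switch(route,
        TC = add_meas(pid, "TC", round(stats::runif(1, 240, 300)), lip_day),
        HDL = add_meas(pid, "HDL", round(stats::runif(1, 25, 39)), lip_day),
        LDL = add_meas(pid, "LDL", round(stats::runif(1, 160, 220)), lip_day),
        TG = add_meas(pid, "TG", round(stats::runif(1, 200, 400)), lip_day),
        dx = add_cond(pid, "dyslipidemia", lip_day))
    } else {
      add_meas(pid, "TC", round(clamp(stats::rnorm(1, 185, nsd[["TC"]]),
                                      120, 235)), lip_day)
      add_meas(pid, "HDL", round(clamp(stats::rnorm(1, 55, nsd[["HDL"]]),
                                       41, 90)), lip_day)
      add_meas(pid, "TG", round(clamp(stats::rnorm(1, 120, nsd[["TG"]]),
                                      50, 195)), lip_day)
    }
    liv_day <- win_day()
    if (isTRUE(tp$liver_disease[i])) {
      route <- sample(c("AST", "ALT", "dx"), 1L)
      switch(route,
        AST = add_meas(pid, "AST", round(stats::runif(1, 120, 300)), liv_day),
        ALT = add_meas(pid, "ALT", round(stats::runif(1, 120, 300)), liv_day),
        dx = add_cond(pid, sample(c("hepatitis", "cirrhosis",
                                    "steatosis_of_liver"), 1L), liv_day))
    } else {
      add_meas(pid, "AST", round(clamp(stats::rnorm(1, 26, nsd[["AST"]]),
                                       10, 110)), liv_day)
      add_meas(pid, "ALT", round(clamp(stats::rnorm(1, 24, nsd[["ALT"]]),
                                       10, 110)), liv_day)
    }
    if (isTRUE(tp$renal_disease[i])) {
      route <- sample(c("SCR", "dx"), 1L)
      if (route == "SCR") {
        add_meas(pid, "SCR", round(stats::runif(1, 1.5, 3.0), 2L), win_day())
      } else {
        add_cond(pid, sample(c("renal_failure", "chronic_kidney_disease"),
                             1L), win_day())
      }
    }
    for (nm in names(config$prevalence)) {
      if (nm %in% c("dyslipidemia", "liver_disease", "renal_disease")) next
      if (!tp[[nm]][i]) next
      token <- if (startsWith(nm, "rx_")) sub("^rx_", "rx:", nm) else nm
      add_cond(pid, token, win_day())
    }
  }
  sim$measurements <- if (length(meas)) {
    as.data.frame(lapply(stats::setNames(names(meas[[1L]]),
                                         names(meas[[1L]])),
                         function(nm) unlist(lapply(meas, `[[`, nm),
                                             use.names = FALSE)))
  } else empty_measurements()
  sim$condition_occurrences <- if (length(cond)) {
    as.data.frame(lapply(stats::setNames(names(cond[[1L]]),
                                         names(cond[[1L]])),
                         function(nm) unlist(lapply(cond, `[[`, nm),
                                             use.names = FALSE)))
  } else empty_conditions()
  sim
}

analyte_unit <- function(analyte) {
  switch(analyte,
         SBP = "mmHg", DBP = "mmHg",
         TC = "mg/dL", HDL = "mg/dL", LDL = "mg/dL", TG = "mg/dL",
         AST = "IU/L", ALT = "IU/L",
         SCR = "mg/dL", HCG = "mIU/mL", "")
}

#' Simulate a complete OMOP bundle with ground truth
#'
#' Convenience wrapper running [generate_population()],
#' [generate_prescriptions()], [plant_change_events()] and
#' [generate_labs_and_conditions()] and assembling the result.
#'
#' @param config a [sim_config()].
#' @return list with `bundle` (an [omop_bundle()]) and `truth` (a
#'   `truth_log`: `$persons` with planted labels/covariates/exclusions,
#'   `$changes` with planted change days and modes, `$config`).
#' @export
simulate_omop <- function(config = sim_config()) {
  sim <- generate_population(config)
  sim <- generate_prescriptions(sim, config)
  sim <- plant_change_events(sim, config)
  sim <- generate_labs_and_conditions(sim, config)
  de <- sim$drug_exposures %||% empty_drug_exposures()
  de <- de[order(de$person_id, de$start_day, de$ingredient), , drop = FALSE]
  rownames(de) <- NULL
  bundle <- omop_bundle(sim$persons, de,
                        sim$condition_occurrences %||% empty_conditions(),
                        sim$measurements %||% empty_measurements(),
                        anchor_date = config$anchor_date)
  list(bundle = bundle, truth = sim$truth)
}

#' Write a truth log as JSON
#'
#' @param truth a `truth_log` from [simulate_omop()].
#' @param path output file (`truth.json`).
#' @export
write_truth_log <- function(truth, path) {
  jsonlite::write_json(list(persons = truth$persons,
                            changes = truth$changes),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
print.truth_log <- function(x, ...) {
  cat(sprintf("Truth log: %d persons, %d planted change events\n",
              nrow(x$persons), nrow(x$changes)))
  if (nrow(x$persons)) {
    cat(sprintf("  planted changed: %d; planted exclusions: %d\n",
                sum(x$persons$changed, na.rm = TRUE),
                sum(x$persons$planted_exclusion != "none")))
  }
  invisible(x)
}
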
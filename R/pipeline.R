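## End-to-end orchestration: cohort -> pathways -> matching -> regression,
## exposed as a fitting-style function returning a classed object.

COHORT_META_COLS <- c("person_id", "index_day", "exit_day", "group",
                      "first_regimen", "n_changes", "coverage_days",
                      "max_gap_days")

default_ps_covariates <- function(cohort) {
  # index year, age, sex, prescription records, general medical history
  general <- c("n_concomitant_meds", "diabetes", "dyslipidemia",
               "liver_disease", "renal_disease",
               "gastrointestinal_diseases", "insomnia",
               "mental_behavioral_diseases")
  intersect(c("index_year", "age", "male", general), names(cohort))
}

cohort_covariates <- function(cohort) {
  setdiff(names(cohort), COHORT_META_COLS)
}

#' Run the full treatment-pathway analysis
#'
#' Fits the whole pipeline on a table bundle: cohort eligibility and
#' baseline covariates ([build_cohort()]), regimen pathways and change-mode
#' tabulations, 1:1 propensity matching ([fit_propensity()],
#' [match_1to1()]), pre/post-matching baseline comparisons
#' ([compare_baseline()]), univariate logistic associations for every
#' covariate, and optional AIC-stepwise multivariate selection over main
#' effects and their pairwise interactions ([stepwise_aic()],
#' [fit_multivariate()]).
#'
#' @param bundle an [omop_bundle()].
#' @param window_days baseline covariate window in days: 365 (main
#'   analysis) or 183 (6-month sensitivity analysis).
#' @param gap_tolerance,persist_days,max_steps passed to [build_cohort()].
#' @param match perform 1:1 propensity matching before regression.
#' @param ps_covariates covariates of the propensity model (default:
#'   index year, age, sex, concomitant-medication count and the general
#'   medical-history flags present in the cohort).
#' @param analysis_covariates covariates assessed in the association
#'   analysis (default: every baseline covariate).
#' @param caliper_sd_logit matching caliper in logit-score SDs.
#' @param stepwise run AIC-stepwise multivariate selection.
#' @param min_count a binary covariate must have at least this many
#'   positives and negatives to enter the regressions.
#' @param seed integer seed controlling matching tie-breaks.
#' @return object of class `htn_pathway`; see [print.htn_pathway()],
#'   [summary.htn_pathway()], [coef.htn_pathway()], [write_report()].
#' @export
htn_pathway_analysis <- function(bundle,
                                 window_days = 365L,
                                 gap_tolerance = DEFAULT_GAP_DAYS,
                                 persist_days = DEFAULT_PERSIST_DAYS,
                                 max_steps = 5L,
                                 match = TRUE,
                                 ps_covariates = NULL,
                                 analysis_covariates = NULL,
                                 caliper_sd_logit = 0.2,
                                 stepwise = TRUE,
                                 min_count = 5L,
                                 seed = 1L) {
  cohort <- build_cohort(bundle, window_days = window_days,
                         gap_tolerance = gap_tolerance,
                         persist_days = persist_days,
                         max_steps = max_steps)
  if (nrow(cohort) == 0L) stop("no eligible persons in the cohort")

  sequences <- attr(cohort, "sequences")
  changes <- attr(cohort, "changes")
  initial_regimens <- tabulate_initial_regimens(cohort)
  change_modes <- tabulate_change_modes(changes)
  sankey <- export_sankey(sequences)
  freq <- summarize_change_frequency(cohort$n_changes)

  covs <- analysis_covariates %||% cohort_covariates(cohort)
  both_groups <- all(c("changed", "unchanged") %in% cohort$group)

  baseline_pre <- if (both_groups) {
    suppressWarnings(compare_baseline(cohort, covs))
  }
  psm <- NULL
  analysis <- cohort
  if (match && both_groups) {
    psc <- ps_covariates %||% default_ps_covariates(cohort)
    psc <- psc[vapply(psc, function(v) length(unique(cohort[[v]])) > 1L,
                      logical(1))]
    scores <- fit_propensity(cohort, psc)
    psm <- match_1to1(scores, cohort$group,
                      ids = as.character(cohort$person_id),
                      caliper_sd_logit = caliper_sd_logit, seed = seed)
    keep <- cohort$person_id %in%
      as.integer(c(psm$pairs$changed_id, psm$pairs$unchanged_id))
    analysis <- cohort[keep, , drop = FALSE]
  }
  baseline_post <- if (!is.null(psm) &&
                       all(c("changed", "unchanged") %in% analysis$group)) {
    suppressWarnings(compare_baseline(analysis, covs))
  }

  usable <- covs[vapply(covs, function(v) {
    x <- analysis[[v]]
    if (length(unique(x)) <= 1L) return(FALSE)
    if (all(x %in% c(0, 1))) {
      sum(x == 1) >= min_count && sum(x == 0) >= min_count
    } else TRUE
  }, logical(1))]

  univariate <- NULL
  selected <- NULL
  multivariate <- NULL
  if (all(c("changed", "unchanged") %in% analysis$group)) {
    uni <- lapply(usable, function(v) {
      tryCatch(fit_univariate(analysis, v), error = function(e) {
        warning("univariate fit skipped for '", v, "': ",
                conditionMessage(e))
        NULL
      })
    })
    univariate <- do.call(rbind, uni[!vapply(uni, is.null, logical(1))])
    if (stepwise && length(usable) >= 1L) {
      selected <- stepwise_aic(analysis, usable, interactions = TRUE)
      multivariate <- fit_multivariate(selected$fit)
    }
  }

  structure(list(cohort = cohort,
                 analysis_cohort = analysis,
                 match = psm,
                 baseline_pre = baseline_pre,
                 baseline_post = baseline_post,
                 univariate = univariate,
                 selected = selected,
                 multivariate = multivariate,
                 initial_regimens = initial_regimens,
                 change_modes = change_modes,
                 sankey = sankey,
                 freq = freq,
                 config = list(window_days = window_days,
                               gap_tolerance = gap_tolerance,
                               persist_days = persist_days,
                               max_steps = max_steps,
                               caliper_sd_logit = caliper_sd_logit,
                               match = match, stepwise = stepwise,
                               min_count = min_count, seed = seed)),
            class = "htn_pathway")
}

#' Six-month sensitivity re-run
#'
#' Repeats the whole analysis with the baseline covariate window shortened
#' to 183 days (6 months); everything else identical.
#'
#' @param bundle an [omop_bundle()].
#' @param ... passed to [htn_pathway_analysis()].
#' @return an `htn_pathway` with `config$window_days = 183`.
#' @export
sensitivity_run <- function(bundle, ...) {
  htn_pathway_analysis(bundle, window_days = 183L, ...)
}

#' Summarise per-person change counts
#'
#' @param counts integer vector of change counts (one per person).
#' @return list with `min`, `max`, `median`, `histogram` (named table
#'   summing to the cohort size).
#' @export
summarize_change_frequency <- function(counts) {
  if (length(counts) == 0L) {
    return(list(min = NA, max = NA, median = NA, histogram = table(integer())))
  }
  list(min = min(counts), max = max(counts),
       median = stats::median(counts),
       histogram = table(factor(counts, levels = 0:max(counts))))
}

#' Render the attrition table, optionally with the matched row
#'
#' @param cohort an `htn_cohort`.
#' @param match optional `ps_match`; adds a final row with 2 x pair count.
#' @return data.frame `stage`, `n`, `remaining`.
#' @export
render_attrition <- function(cohort, match = NULL) {
  at <- attrition_table(cohort)
  if (!is.null(match)) {
    at <- rbind(at, data.frame(stage = "matched",
                               n = 2L * nrow(match$pairs),
                               remaining = 2L * nrow(match$pairs)))
  }
  at
}

#' @export
print.htn_pathway <- function(x, ...) {
  cat("Anti-hypertensive treatment-pathway analysis\n")
  at <- attrition_table(x$cohort)
  cat(sprintf("  screened %d -> eligible %d", at$n[at$stage == "screened"],
              nrow(x$cohort)))
  if (!is.null(x$match)) {
    cat(sprintf(" -> matched %d (%d pairs)", 2L * nrow(x$match$pairs),
                nrow(x$match$pairs)))
  }
  cat("\n")
  cat(sprintf("  changed %d / unchanged %d; %d change events; baseline window %d days\n",
              sum(x$analysis_cohort$group == "changed"),
              sum(x$analysis_cohort$group == "unchanged"),
              x$change_modes$grand_total, x$config$window_days))
  if (!is.null(x$multivariate)) {
    cat(sprintf("  multivariate model: %d term(s), AIC %.1f\n",
                nrow(x$multivariate), x$selected$aic))
  }
  invisible(x)
}

#' @export
summary.htn_pathway <- function(object, ...) {
  print(object)
  cat("\nChange frequency: min", object$freq$min, "median",
      object$freq$median, "max", object$freq$max, "\n")
  cat("\nInitial regimens (overall):\n")
  ir <- object$initial_regimens
  ir <- ir[ir$stratum == "(overall)", c("regimen", "n", "pct")]
  print(ir[order(-ir$n), ], row.names = FALSE)
  if (!is.null(object$univariate)) {
    cat("\nUnivariate associations (matched cohort):\n")
    u <- object$univariate
    u$or <- round(u$or, 2); u$ci_low <- round(u$ci_low, 2)
    u$ci_high <- round(u$ci_high, 2); u$p_value <- round(u$p_value, 3)
    print(u[, c("covariate", "or", "ci_low", "ci_high", "p_value")],
          row.names = FALSE)
  }
  if (!is.null(object$multivariate)) {
    cat("\nAdjusted odds ratios (selected model):\n")
    m <- object$multivariate
    m$or <- round(m$or, 2); m$ci_low <- round(m$ci_low, 2)
    m$ci_high <- round(m$ci_high, 2); m$p_value <- round(m$p_value, 3)
    print(m[, c("covariate", "or", "ci_low", "ci_high", "p_value")],
          row.names = FALSE)
  }
  invisible(object)
}

#' Adjusted (or univariate) odds ratios of a fitted pathway analysis
#'
#' @param object an `htn_pathway`.
#' @param ... unused.
#' @return the multivariate effect table when a model was selected, else
#'   the univariate table.
#' @export
coef.htn_pathway <- function(object, ...) {
  object$multivariate %||% object$univariate
}

#' Bar plot of change-mode totals
#'
#' @param x an `htn_pathway`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.htn_pathway <- function(x, ...) {
  tot <- x$change_modes$mode_totals
  graphics::barplot(tot, names.arg = gsub("_", "\n", names(tot)),
                    ylab = "change events", cex.names = 0.7,
                    main = "Medication changes by mode", ...)
  invisible(x)
}

#' Write the report artifact bundle
#'
#' Emits the paper-style artifacts of a fitted analysis into a directory:
#' `attrition.csv`, `table1.csv` (pre/post-matching baseline comparison),
#' `initial_regimens.csv`, `change_modes.csv`, `table4.csv` (univariate +
#' adjusted effects, annotated with the baseline window), `sankey.json`
#' and `run_log.txt` (config echo and stage counts). Re-running with the
#' same object produces identical files.
#'
#' @param x an `htn_pathway`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wcsv <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                           row.names = FALSE)
  wcsv(render_attrition(x$cohort, x$match), "attrition.csv")
  t1 <- rbind(
    if (!is.null(x$baseline_pre)) cbind(phase = "pre_match",
                                        x$baseline_pre),
    if (!is.null(x$baseline_post)) cbind(phase = "post_match",
                                         x$baseline_post))
  if (!is.null(t1)) wcsv(t1, "table1.csv")
  wcsv(x$initial_regimens, "initial_regimens.csv")
  wcsv(as.data.frame(x$change_modes), "change_modes.csv")
  t4 <- rbind(x$univariate, x$multivariate)
  if (!is.null(t4)) {
    t4$window_days <- x$config$window_days
    t4$sensitivity <- x$config$window_days != 365L
    wcsv(t4, "table4.csv")
  }
  jsonlite::write_json(x$sankey, file.path(dir, "sankey.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  log <- c("htn_pathway_analysis run log",
           paste0("config: ", paste(names(x$config), unlist(x$config),
                                    sep = "=", collapse = ", ")),
           paste0("screened: ",
                  attrition_table(x$cohort)$n[1L]),
           paste0("eligible: ", nrow(x$cohort)),
           paste0("matched pairs: ",
                  if (is.null(x$match)) NA else nrow(x$match$pairs)),
           paste0("change events: ", x$change_modes$grand_total),
           paste0("change frequency: min ", x$freq$min, " median ",
                  x$freq$median, " max ", x$freq$max))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
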
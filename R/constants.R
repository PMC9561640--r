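#' Anti-hypertensive drug classes
#'
#' The six-class taxonomy used throughout the package:
#' angiotensin-converting-enzyme inhibitors (ACEi), angiotensin receptor
#' blockers (ARB), beta-blockers (BB), calcium channel blockers (CCB),
#' diuretics (DU), and others (e.g. alpha-blockers, vasodilators).
#' The vector is in canonical sort order, used when regimen labels are built.
#'
#' @export
HTN_CLASSES <- c("ACEi", "ARB", "BB", "CCB", "DU", "OTHER")

#' Change-mode taxonomy
#'
#' The six mutually exclusive modes a persisted regimen transition is
#' classified into, in the fixed order used by tabulations.
#'
#' @export
CHANGE_MODES <- c("DOSE_INCREASED", "DOSE_REDUCED", "MEDICATION_ADDED",
                  "MEDICATION_REMOVED", "CHANGED_WITHIN_CLASS",
                  "CHANGED_TO_DIFFERENT_CLASS")

#' Recognised measurement analytes
#' @export
ANALYTES <- c("SBP", "DBP", "TC", "HDL", "LDL", "TG", "AST", "ALT",
              "SCR", "HCG")

# follow-up length in days: cohort exit = index + FOLLOWUP_DAYS
FOLLOWUP_DAYS <- 1095L
# continuous treatment: >= 80% of follow-up covered ...
MIN_COVERAGE_DAYS <- 875L
# ... with no drug holiday longer than this between adjacent prescriptions
DEFAULT_GAP_DAYS <- 30L
# a new regimen must persist this long to count as a change
DEFAULT_PERSIST_DAYS <- 30L
# required prior clinical history before the index prescription
MIN_HISTORY_DAYS <- 365L

`%||%` <- function(a, b) if (is.null(a)) b else a

## Interval helpers. All intervals are closed integer [start, end] day ranges.

# merge sorted-or-unsorted intervals, joining neighbours separated by an
# uncovered run of <= gap days (gap = next.start - prev.end - 1)
merge_intervals <- function(start, end, gap = 0L) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  o <- order(start, end)
  start <- as.integer(start[o]); end <- as.integer(end[o])
  ms <- start[1L]; me <- end[1L]
  out_s <- integer(); out_e <- integer()
  if (length(start) > 1L) {
    for (i in 2L:length(start)) {
      if (start[i] - me - 1L <= gap) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# clip intervals to [lo, hi], dropping the empty ones
clip_intervals <- function(start, end, lo, hi) {
  s <- pmax(as.integer(start), as.integer(lo))
  e <- pmin(as.integer(end), as.integer(hi))
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

interval_days <- function(iv) {
  if (nrow(iv) == 0L) 0L else sum(iv$end - iv$start + 1L)
}
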
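#' Example summary tables
#'
#' Small worked-example tables shipped with the package, as reported by a
#' tertiary-care hospital treatment-pathway study of anti-hypertensive
#' prescribing:
#' \describe{
#'   \item{`change_mode_counts`}{change events cross-classified by
#'     previous regimen and change mode.}
#'   \item{`matched_2x2`}{post-matching 2x2 cell counts (changed/unchanged
#'     by exposed/unexposed) for six baseline covariates, 297 persons per
#'     group.}
#'   \item{`initial_regimen_counts`}{first-regimen counts for 636 eligible
#'     persons.}
#' }
#'
#' @param name one of `"change_mode_counts"`, `"matched_2x2"`,
#'   `"initial_regimen_counts"`.
#' @return the table as a data.frame.
#' @export
example_table <- function(name = c("change_mode_counts", "matched_2x2",
                                   "initial_regimen_counts")) {
  name <- match.arg(name)
  utils::read.csv(system.file("extdata", paste0("example_", name, ".csv"),
                              package = "htnpathways"),
                  check.names = FALSE)
}

#' Expand a regimen-by-mode count table into individual change events
#'
#' Inverse of counting: produces one event row per counted change so that
#' aggregate tables can be fed through [tabulate_change_modes()].
#'
#' @param counts data.frame with a `regimen` column and one column per
#'   change mode (as in `example_table("change_mode_counts")`).
#' @return data.frame with `prev_label` and `mode`, one row per event.
#' @export
change_events_from_counts <- function(counts) {
  modes <- intersect(CHANGE_MODES, names(counts))
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (m in modes) {
      k <- counts[[m]][i]
      if (k > 0L) {
        rows[[length(rows) + 1L]] <-
          data.frame(prev_label = rep(counts$regimen[i], k),
                     mode = rep(m, k))
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(prev_label = character(), mode = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
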
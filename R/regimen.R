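## Regimen engine: drug eras -> regimen timeline -> persisted changes ->
## six-mode classification and pathway tabulations.

#' Build drug eras from prescription records
#'
#' Collapses refill-style drug exposures into maximal eras of continuous
#' exposure, separately for each (ingredient, daily dose) pair. Two records
#' are stitched into one era when the uncovered run between them
#' (`next start - previous end - 1`) does not exceed `gap_tolerance` days --
#' the same drug-holiday tolerance the cohort continuity rule uses.
#' Overlapping records are coalesced; a refill starting the day after the
#' previous supply ran out is a 0-day holiday.
#'
#' @param exposures data.frame of one person's exposures with columns
#'   `ingredient`, `drug_class`, `daily_dose`, `start_day`, `end_day`.
#' @param gap_tolerance maximum bridged drug holiday, in days.
#' @return data.frame of eras (`ingredient`, `drug_class`, `daily_dose`,
#'   `start_day`, `end_day`), sorted by start day.
#' @export
build_drug_eras <- function(exposures, gap_tolerance = DEFAULT_GAP_DAYS) {
  if (nrow(exposures) == 0L) {
    return(data.frame(ingredient = character(), drug_class = character(),
                      daily_dose = numeric(), start_day = integer(),
                      end_day = integer()))
  }
  if (any(exposures$daily_dose < 0)) stop("negative daily_dose in exposures")
  key <- paste(exposures$ingredient, exposures$daily_dose, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(exposures)), key), function(idx) {
    iv <- merge_intervals(exposures$start_day[idx], exposures$end_day[idx],
                          gap = gap_tolerance)
    data.frame(ingredient = exposures$ingredient[idx[1L]],
               drug_class = exposures$drug_class[idx[1L]],
               daily_dose = exposures$daily_dose[idx[1L]],
               start_day = iv$start, end_day = iv$end)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$start_day, out$ingredient, out$daily_dose), , drop = FALSE]
}

# canonical member key: one row per ingredient with its total daily dose
member_set <- function(members) {
  if (is.null(members) || nrow(members) == 0L) {
    return(data.frame(ingredient = character(), drug_class = character(),
                      daily_dose = numeric()))
  }
  agg <- stats::aggregate(daily_dose ~ ingredient + drug_class,
                          data = members, FUN = sum)
  agg[order(agg$ingredient), c("ingredient", "drug_class", "daily_dose")]
}

member_key <- function(members) {
  m <- member_set(members)
  paste(sprintf("%s@%g", m$ingredient, m$daily_dose), collapse = "|")
}

#' Canonical regimen label from drug classes
#'
#' Distinct classes are sorted in the fixed order
#' ACEi < ARB < BB < CCB < DU < OTHER and joined with `+`, e.g. `"ARB+CCB"`.
#'
#' @param classes character vector of drug classes (repeats allowed).
#' @return single label string ("" for an empty set).
#' @export
regimen_label <- function(classes) {
  cl <- unique(classes)
  cl <- cl[order(match(cl, HTN_CLASSES))]
  paste(cl, collapse = "+")
}

#' Partition a follow-up window into regimens
#'
#' Sweeps the era start/end boundaries over `[index_day, exit_day]` and cuts
#' the window into maximal intervals on which the active
#' (ingredient, dose) member set is constant. Intervals with no active era
#' (a full drug holiday) are bridged by carrying the preceding member set
#' forward, so the returned regimens tile the window exactly.
#'
#' @param eras data.frame from [build_drug_eras()].
#' @param index_day,exit_day closed follow-up window.
#' @return list of regimens; each is a list with `start`, `end`, `members`
#'   (data.frame `ingredient`, `drug_class`, `daily_dose`),
#'   `is_combination` (>= 2 distinct ingredients or classes) and `label`.
#' @export
derive_regimens <- function(eras, index_day, exit_day) {
  keep <- eras$start_day <= exit_day & eras$end_day >= index_day
  eras <- eras[keep, , drop = FALSE]
  if (nrow(eras) == 0L) return(list())
  eras$start_day <- pmax(eras$start_day, as.integer(index_day))
  eras$end_day <- pmin(eras$end_day, as.integer(exit_day))

  cuts <- sort(unique(c(index_day, eras$start_day, eras$end_day + 1L,
                        exit_day + 1L)))
  cuts <- cuts[cuts >= index_day & cuts <= exit_day + 1L]
  out <- list()
  prev_members <- NULL
  for (i in seq_len(length(cuts) - 1L)) {
    s <- cuts[i]; e <- cuts[i + 1L] - 1L
    on <- eras$start_day <= s & eras$end_day >= s
    members <- eras[on, c("ingredient", "drug_class", "daily_dose"),
                    drop = FALSE]
    if (nrow(members) == 0L) {
      if (is.null(prev_members)) next     # uncovered lead-in: skip
      members <- prev_members             # bridge the holiday
    }
    members <- member_set(members)
    prev_members <- members
    if (length(out) &&
        identical(member_key(out[[length(out)]]$members),
                  member_key(members))) {
      out[[length(out)]]$end <- e
    } else {
      out[[length(out) + 1L]] <- list(
        start = s, end = e, members = members,
        is_combination = nrow(members) >= 2L ||
          length(unique(members$drug_class)) >= 2L,
        label = regimen_label(members$drug_class))
    }
  }
  out
}

#' Drop transient regimens
#'
#' Regimens persisting fewer than `min_days` days are deleted and their
#' interval absorbed by the preceding kept regimen (the first regimen is
#' always kept); neighbours that become identical are merged. The result is
#' a fixpoint: filtering an already-filtered sequence changes nothing.
#'
#' @param regimens list from [derive_regimens()].
#' @param min_days persistence threshold in days.
#' @return filtered regimen list.
#' @export
filter_transient_regimens <- function(regimens,
                                      min_days = DEFAULT_PERSIST_DAYS) {
  kept <- list()
  for (r in regimens) {
    if (length(kept) == 0L) {
      kept[[1L]] <- r
      next
    }
    last <- kept[[length(kept)]]
    if (r$end - r$start + 1L < min_days) {
      kept[[length(kept)]]$end <- r$end          # absorb the excursion
    } else if (identical(member_key(last$members), member_key(r$members))) {
      kept[[length(kept)]]$end <- r$end          # merge equal neighbours
    } else {
      kept[[length(kept) + 1L]] <- r
    }
  }
  kept
}

#' Classify a regimen transition into one of six change modes
#'
#' Modes are assigned by the first matching rule, giving every transition
#' exactly one mode:
#' \enumerate{
#'   \item same ingredient set, some total daily dose differs:
#'     `DOSE_INCREASED` if every differing dose rises, `DOSE_REDUCED` if
#'     every differing dose falls (mixed moves fall through to rule 5);
#'   \item previous ingredients are a strict subset of the next:
#'     `MEDICATION_ADDED`;
#'   \item next ingredients are a strict subset of the previous:
#'     `MEDICATION_REMOVED`;
#'   \item same class multiset but different ingredients:
#'     `CHANGED_WITHIN_CLASS`;
#'   \item otherwise `CHANGED_TO_DIFFERENT_CLASS`.
#' }
#'
#' @param prev,next_ regimens (lists with a `members` data.frame) or bare
#'   member data.frames.
#' @return one of [CHANGE_MODES].
#' @export
classify_change <- function(prev, next_) {
  pm <- member_set(if (is.data.frame(prev)) prev else prev$members)
  nm <- member_set(if (is.data.frame(next_)) next_ else next_$members)
  if (identical(member_key(pm), member_key(nm))) {
    stop("classify_change called on identical regimens")
  }
  p_ing <- pm$ingredient; n_ing <- nm$ingredient
  if (setequal(p_ing, n_ing)) {
    # rule 1: dose change on an unchanged ingredient set
    nm_ord <- nm[match(p_ing, nm$ingredient), , drop = FALSE]
    d <- nm_ord$daily_dose - pm$daily_dose
    d <- d[d != 0]
    if (all(d > 0)) return("DOSE_INCREASED")
    if (all(d < 0)) return("DOSE_REDUCED")
    return("CHANGED_TO_DIFFERENT_CLASS")   # mixed dose moves: fall-through
  }
  if (all(p_ing %in% n_ing)) return("MEDICATION_ADDED")
  if (all(n_ing %in% p_ing)) return("MEDICATION_REMOVED")
  if (identical(sort(pm$drug_class), sort(nm$drug_class))) {
    return("CHANGED_WITHIN_CLASS")
  }
  "CHANGED_TO_DIFFERENT_CLASS"
}

#' Detect classified change events in a filtered regimen sequence
#'
#' @param regimens output of [filter_transient_regimens()].
#' @return data.frame with one row per transition: `day` (start of the new
#'   regimen), `mode`, `prev_label`, `next_label`.
#' @export
detect_changes <- function(regimens) {
  n <- length(regimens)
  if (n < 2L) {
    return(data.frame(day = integer(), mode = character(),
                      prev_label = character(), next_label = character()))
  }
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    out[[i]] <- data.frame(
      day = regimens[[i + 1L]]$start,
      mode = classify_change(regimens[[i]], regimens[[i + 1L]]),
      prev_label = regimens[[i]]$label,
      next_label = regimens[[i + 1L]]$label)
  }
  do.call(rbind, out)
}

#' Extract the class-level regimen sequence
#'
#' Maps a persisted regimen sequence to its ordered class-set labels,
#' collapsing consecutive equal labels (a dose-only change is invisible at
#' class level) and truncating to the first `max_steps` entries.
#'
#' @param regimens output of [filter_transient_regimens()].
#' @param max_steps maximum sequence length retained.
#' @return character vector of labels, length <= `max_steps`.
#' @export
extract_sequence <- function(regimens, max_steps = 5L) {
  labels <- vapply(regimens, function(r) r$label, character(1))
  if (length(labels)) labels <- labels[c(TRUE, labels[-1L] !=
                                           labels[-length(labels)])]
  utils::head(labels, max_steps)
}

#' Tabulate initial regimens, overall and by strata
#'
#' Counts first-regimen labels with row percentages (one decimal), overall
#' and within each level of the requested stratifying covariates.
#'
#' @param cohort data.frame with a `first_regimen` column plus any stratum
#'   columns.
#' @param strata character vector of stratifying column names (may be
#'   empty: overall row only).
#' @return data.frame with columns `stratum`, `level`, `regimen`, `n`,
#'   `pct`, `row_total`.
#' @export
tabulate_initial_regimens <- function(cohort, strata = character()) {
  stopifnot("first_regimen" %in% names(cohort))
  bad <- setdiff(strata, names(cohort))
  if (length(bad)) stop("unknown stratum name(s): ",
                        paste(bad, collapse = ", "))
  one_stratum <- function(name, values) {
    pieces <- lapply(split(cohort$first_regimen, values), function(lab) {
      tab <- table(lab)
      data.frame(regimen = names(tab), n = as.integer(tab),
                 pct = round(100 * as.integer(tab) / length(lab), 1L),
                 row_total = length(lab))
    })
    out <- do.call(rbind, Map(function(lv, df) {
      df$stratum <- name; df$level <- lv; df
    }, names(pieces), pieces))
    rownames(out) <- NULL
    out[, c("stratum", "level", "regimen", "n", "pct", "row_total")]
  }
  res <- one_stratum("(overall)", rep("(all)", nrow(cohort)))
  for (s in strata) res <- rbind(res, one_stratum(s, cohort[[s]]))
  res
}

#' Tabulate change events by previous regimen and mode
#'
#' Builds the mode-by-regimen count matrix with row totals, mode totals, a
#' grand total, and row percentages rounded to one decimal. Rows are
#' ordered by decreasing total.
#'
#' @param events data.frame with columns `prev_label` and `mode` (rows are
#'   individual change events).
#' @return object of class `change_mode_table`: list with `counts` (matrix
#'   regimen x mode), `row_totals`, `mode_totals`, `grand_total`, `row_pct`.
#' @export
tabulate_change_modes <- function(events) {
  if (nrow(events)) {
    counts <- table(factor(events$prev_label),
                    factor(events$mode, levels = CHANGE_MODES))
    counts <- unclass(counts)[, CHANGE_MODES, drop = FALSE]
    counts <- counts[order(-rowSums(counts), rownames(counts)), ,
                     drop = FALSE]
  } else {
    counts <- matrix(0L, nrow = 0L, ncol = length(CHANGE_MODES),
                     dimnames = list(NULL, CHANGE_MODES))
  }
  row_totals <- rowSums(counts)
  row_pct <- counts
  if (nrow(counts)) {
    row_pct <- round(100 * sweep(counts, 1L, pmax(row_totals, 1L), "/"), 1L)
  }
  structure(list(counts = counts,
                 row_totals = row_totals,
                 mode_totals = colSums(counts),
                 grand_total = sum(counts),
                 row_pct = row_pct),
            class = "change_mode_table")
}

#' @export
print.change_mode_table <- function(x, ...) {
  cat("Change events by previous regimen and mode\n")
  if (nrow(x$counts) == 0L) {
    cat("  (no events)\n")
    return(invisible(x))
  }
  m <- cbind(x$counts, Total = x$row_totals)
  m <- rbind(m, Total = c(x$mode_totals, x$grand_total))
  print(m)
  invisible(x)
}

#' Convert a change-mode table to a flat data.frame
#'
#' @param x a `change_mode_table`.
#' @param ... unused.
#' @export
as.data.frame.change_mode_table <- function(x, ...) {
  if (nrow(x$counts) == 0L) {
    return(data.frame(regimen = character(), mode = character(),
                      n = integer(), row_pct = numeric()))
  }
  df <- expand.grid(regimen = rownames(x$counts), mode = CHANGE_MODES,
                    stringsAsFactors = FALSE)
  df$n <- as.vector(x$counts)
  df$row_pct <- as.vector(x$row_pct)
  df[order(df$regimen, match(df$mode, CHANGE_MODES)), , drop = FALSE]
}

#' Build a Sankey node/link structure from regimen sequences
#'
#' One node per (step, label) pair actually visited; one link per observed
#' consecutive transition, weighted by the number of persons making it.
#' The structure serialises directly to JSON for any Sankey renderer.
#'
#' @param sequences list of per-person label vectors
#'   (from [extract_sequence()]).
#' @return list with data.frames `nodes` (`id`, `step`, `label`) and
#'   `links` (`source`, `target`, `value`).
#' @export
export_sankey <- function(sequences) {
  steps <- unlist(lapply(sequences, seq_along))
  labels <- unlist(sequences)
  if (length(labels) == 0L) {
    return(list(nodes = data.frame(id = integer(), step = integer(),
                                   label = character()),
                links = data.frame(source = integer(), target = integer(),
                                   value = integer())))
  }
  nodes <- unique(data.frame(step = steps, label = labels))
  nodes <- nodes[order(nodes$step, nodes$label), , drop = FALSE]
  nodes$id <- seq_len(nrow(nodes)) - 1L
  rownames(nodes) <- NULL
  node_id <- function(step, label) {
    nodes$id[match(paste(step, label), paste(nodes$step, nodes$label))]
  }
  trans <- list()
  for (s in sequences) {
    if (length(s) < 2L) next
    for (i in seq_len(length(s) - 1L)) {
      trans[[length(trans) + 1L]] <-
        c(node_id(i, s[i]), node_id(i + 1L, s[i + 1L]))
    }
  }
  if (length(trans)) {
    tm <- do.call(rbind, trans)
    agg <- stats::aggregate(list(value = rep(1L, nrow(tm))),
                            by = list(source = tm[, 1L], target = tm[, 2L]),
                            FUN = sum)
  } else {
    agg <- data.frame(source = integer(), target = integer(),
                      value = integer())
  }
  list(nodes = nodes[, c("id", "step", "label")], links = agg)
}
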
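#' Construct an OMOP-style table bundle
#'
#' Assembles the four-table subset of the OMOP common data model that the
#' pipeline consumes, after light type coercion. Dates are held in memory as
#' integer day offsets from an anchor calendar date; conversion to ISO-8601
#' happens only at [write_omop_bundle()] / [read_omop_bundle()].
#'
#' @param persons data.frame with columns `person_id`, `sex` ("M"/"F"),
#'   `birth_year`, `race_flag` (logical; used only by the MDRD equation).
#' @param drug_exposures data.frame with columns `person_id`, `ingredient`,
#'   `drug_class` (one of [HTN_CLASSES]), `daily_dose` (mg/day),
#'   `start_day`, `end_day` (closed interval, day offsets).
#' @param condition_occurrences data.frame with columns `person_id`,
#'   `condition_category` (free token; medication-use categories carry an
#'   `rx:` prefix), `day`.
#' @param measurements data.frame with columns `person_id`, `analyte`
#'   (one of [ANALYTES]), `value`, `unit`, `day`.
#' @param anchor_date calendar date corresponding to day offset 0.
#' @return An object of class `omop_bundle` (a named list of the four
#'   data.frames with an `anchor_date` attribute).
#' @export
omop_bundle <- function(persons,
                        drug_exposures = empty_drug_exposures(),
                        condition_occurrences = empty_conditions(),
                        measurements = empty_measurements(),
                        anchor_date = as.Date("2010-01-01")) {
  b <- structure(
    list(persons = as.data.frame(persons),
         drug_exposures = as.data.frame(drug_exposures),
         condition_occurrences = as.data.frame(condition_occurrences),
         measurements = as.data.frame(measurements)),
    anchor_date = as.Date(anchor_date),
    class = "omop_bundle")
  b$persons$person_id <- as.integer(b$persons$person_id)
  for (tb in c("drug_exposures", "condition_occurrences", "measurements")) {
    b[[tb]]$person_id <- as.integer(b[[tb]]$person_id)
  }
  for (col in c("start_day", "end_day")) {
    b$drug_exposures[[col]] <- as.integer(b$drug_exposures[[col]])
  }
  b$condition_occurrences$day <- as.integer(b$condition_occurrences$day)
  b$measurements$day <- as.integer(b$measurements$day)
  b
}

empty_drug_exposures <- function() {
  data.frame(person_id = integer(), ingredient = character(),
             drug_class = character(), daily_dose = numeric(),
             start_day = integer(), end_day = integer())
}
empty_conditions <- function() {
  data.frame(person_id = integer(), condition_category = character(),
             day = integer())
}
empty_measurements <- function() {
  data.frame(person_id = integer(), analyte = character(),
             value = numeric(), unit = character(), day = integer())
}

#' @export
print.omop_bundle <- function(x, ...) {
  cat("OMOP table bundle\n")
  cat(sprintf("  persons:               %d\n", nrow(x$persons)))
  cat(sprintf("  drug exposures:        %d\n", nrow(x$drug_exposures)))
  cat(sprintf("  condition occurrences: %d\n", nrow(x$condition_occurrences)))
  cat(sprintf("  measurements:          %d\n", nrow(x$measurements)))
  cat(sprintf("  anchor date:           %s\n",
              format(attr(x, "anchor_date"))))
  invisible(x)
}

bundle_columns <- list(
  persons = c("person_id", "sex", "birth_year", "race_flag"),
  drug_exposures = c("person_id", "ingredient", "drug_class", "daily_dose",
                     "start_day", "end_day"),
  condition_occurrences = c("person_id", "condition_category", "day"),
  measurements = c("person_id", "analyte", "value", "unit", "day"))

bundle_files <- c(persons = "persons.csv",
                  drug_exposures = "drug_exposure.csv",
                  condition_occurrences = "condition_occurrence.csv",
                  measurements = "measurement.csv")

# columns that are day offsets in memory and ISO dates on disk
day_columns <- list(
  persons = character(),
  drug_exposures = c("start_day", "end_day"),
  condition_occurrences = "day",
  measurements = "day")
date_columns <- list(
  persons = character(),
  drug_exposures = c("start_date", "end_date"),
  condition_occurrences = "date",
  measurements = "date")

#' Validate an OMOP bundle
#'
#' Pure, report-only validation: returns a data.frame of violations and
#' never mutates or errors. An empty report means the bundle is valid.
#' Checks performed: required columns, enum membership (`drug_class`,
#' `analyte`, `sex`), interval orientation (`end_day >= start_day`),
#' non-negative doses and measurement values, duplicate person rows, and
#' referential integrity of every child-table `person_id`.
#'
#' @param bundle an [omop_bundle()].
#' @return data.frame with columns `table`, `row`, `problem` (zero rows if
#'   valid).
#' @export
validate_omop_bundle <- function(bundle) {
  viol <- function(table, row, problem) {
    data.frame(table = table, row = as.integer(row), problem = problem)
  }
  out <- list()
  for (tb in names(bundle_columns)) {
    missing <- setdiff(bundle_columns[[tb]], names(bundle[[tb]]))
    if (length(missing)) {
      out[[length(out) + 1L]] <-
        viol(tb, NA, paste0("missing column(s): ",
                            paste(missing, collapse = ", ")))
    }
  }
  # content checks only make sense once the schemas are complete
  if (length(out) == 0L) {
    p <- bundle$persons
    dup <- which(duplicated(p$person_id))
    for (i in dup) out[[length(out) + 1L]] <-
      viol("persons", i, sprintf("duplicate person_id %d", p$person_id[i]))
    bad_sex <- which(!p$sex %in% c("M", "F"))
    for (i in bad_sex) out[[length(out) + 1L]] <-
      viol("persons", i, sprintf("sex must be 'M' or 'F', got '%s'", p$sex[i]))

    de <- bundle$drug_exposures
    bad_cls <- which(!de$drug_class %in% HTN_CLASSES)
    for (i in bad_cls) out[[length(out) + 1L]] <-
      viol("drug_exposures", i,
           sprintf("unknown drug_class '%s'", de$drug_class[i]))
    bad_iv <- which(de$end_day < de$start_day)
    for (i in bad_iv) out[[length(out) + 1L]] <-
      viol("drug_exposures", i, "end_day < start_day")
    bad_dose <- which(!is.na(de$daily_dose) & de$daily_dose < 0)
    for (i in bad_dose) out[[length(out) + 1L]] <-
      viol("drug_exposures", i, "negative daily_dose")

    me <- bundle$measurements
    bad_an <- which(!me$analyte %in% ANALYTES)
    for (i in bad_an) out[[length(out) + 1L]] <-
      viol("measurements", i, sprintf("unknown analyte '%s'", me$analyte[i]))
    bad_val <- which(!is.na(me$value) & me$value < 0)
    for (i in bad_val) out[[length(out) + 1L]] <-
      viol("measurements", i, "negative value")

    for (tb in c("drug_exposures", "condition_occurrences", "measurements")) {
      orphan <- which(!bundle[[tb]]$person_id %in% p$person_id)
      for (i in orphan) out[[length(out) + 1L]] <-
        viol(tb, i, sprintf("person_id %d not present in persons",
                            bundle[[tb]]$person_id[i]))
    }
  }
  if (length(out) == 0L) {
    data.frame(table = character(), row = integer(), problem = character())
  } else {
    do.call(rbind, out)
  }
}

#' Write an OMOP bundle to a directory of CSV files
#'
#' Emits `persons.csv`, `drug_exposure.csv`, `condition_occurrence.csv` and
#' `measurement.csv` as UTF-8, comma-delimited files with a header row.
#' Day offsets are converted to ISO-8601 dates using the bundle's anchor
#' date; rows are sorted by (`person_id`, start day) so repeated writes of
#' the same bundle are byte-identical.
#'
#' @param bundle an [omop_bundle()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_omop_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  anchor <- attr(bundle, "anchor_date")
  for (tb in names(bundle_files)) {
    df <- bundle[[tb]][, bundle_columns[[tb]], drop = FALSE]
    dcol <- day_columns[[tb]]
    for (k in seq_along(dcol)) {
      df[[dcol[k]]] <- format(anchor + df[[dcol[k]]], "%Y-%m-%d")
      names(df)[names(df) == dcol[k]] <- date_columns[[tb]][k]
    }
    key2 <- if (tb == "persons") rep(0L, nrow(df)) else
      bundle[[tb]][[if (tb == "drug_exposures") "start_day" else "day"]]
    df <- df[order(df$person_id, key2), , drop = FALSE]
    utils::write.csv(df, file.path(dir, bundle_files[[tb]]),
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' Read an OMOP bundle from a directory of CSV files
#'
#' Counterpart of [write_omop_bundle()]. ISO dates are converted back to
#' integer day offsets relative to `anchor_date` (by default the earliest
#' date found in any table). The bundle is validated on the way in; enum or
#' referential-integrity violations abort with the offending rows listed.
#' Unknown extra columns are dropped with a warning, so richer CDM extracts
#' can be read directly.
#'
#' @param dir directory containing the four CSV files.
#' @param anchor_date day-0 calendar date; `NULL` (default) uses the
#'   earliest date present.
#' @return an [omop_bundle()].
#' @export
read_omop_bundle <- function(dir, anchor_date = NULL) {
  paths <- file.path(dir, bundle_files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing input file(s): ",
         paste(bundle_files[missing], collapse = ", "))
  }
  col_types <- list(
    persons = c(person_id = "integer", sex = "character",
                birth_year = "integer", race_flag = "logical"),
    drug_exposures = c(person_id = "integer", ingredient = "character",
                       drug_class = "character", daily_dose = "numeric",
                       start_date = "character", end_date = "character"),
    condition_occurrences = c(person_id = "integer",
                              condition_category = "character",
                              date = "character"),
    measurements = c(person_id = "integer", analyte = "character",
                     value = "numeric", unit = "character",
                     date = "character"))
  raw <- Map(function(path, types) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    # pin declared column types (a header-only file reads as all-logical)
    for (nm in intersect(names(types), names(df))) {
      df[[nm]] <- switch(types[[nm]],
                         integer = as.integer(df[[nm]]),
                         numeric = as.numeric(df[[nm]]),
                         logical = as.logical(df[[nm]]),
                         as.character(df[[nm]]))
    }
    df
  }, paths, col_types[names(bundle_files)])
  names(raw) <- names(bundle_files)

  # locate the anchor before converting anything
  all_dates <- as.Date(character())
  for (tb in names(raw)) {
    for (dc in date_columns[[tb]]) {
      if (dc %in% names(raw[[tb]])) {
        d <- as.Date(raw[[tb]][[dc]])
        if (anyNA(d)) {
          stop(sprintf("unparseable date in %s column '%s' (row %d)",
                       bundle_files[[tb]], dc, which(is.na(d))[1L]))
        }
        all_dates <- c(all_dates, d)
      }
    }
  }
  if (is.null(anchor_date)) {
    anchor_date <- if (length(all_dates)) min(all_dates)
    else as.Date("2010-01-01")
  }
  anchor_date <- as.Date(anchor_date)

  for (tb in names(raw)) {
    dcs <- date_columns[[tb]]
    for (k in seq_along(dcs)) {
      if (dcs[k] %in% names(raw[[tb]])) {
        raw[[tb]][[dcs[k]]] <-
          as.integer(as.Date(raw[[tb]][[dcs[k]]]) - anchor_date)
        names(raw[[tb]])[names(raw[[tb]]) == dcs[k]] <- day_columns[[tb]][k]
      }
    }
    expected <- bundle_columns[[tb]]
    absent <- setdiff(expected, names(raw[[tb]]))
    if (length(absent)) {
      stop(sprintf("%s lacks required column(s): %s",
                   bundle_files[[tb]], paste(absent, collapse = ", ")))
    }
    extra <- setdiff(names(raw[[tb]]), expected)
    if (length(extra)) {
      warning(sprintf("%s: ignoring unknown column(s) %s",
                      bundle_files[[tb]], paste(extra, collapse = ", ")))
      raw[[tb]] <- raw[[tb]][, expected, drop = FALSE]
    }
  }
  if ("race_flag" %in% names(raw$persons)) {
    raw$persons$race_flag <- as.logical(raw$persons$race_flag)
  }
  b <- omop_bundle(raw$persons, raw$drug_exposures,
                   raw$condition_occurrences, raw$measurements,
                   anchor_date = anchor_date)
  rep <- validate_omop_bundle(b)
  if (nrow(rep)) {
    stop("invalid bundle:\n",
         paste(sprintf("  %s row %s: %s", rep$table, rep$row, rep$problem),
               collapse = "\n"))
  }
  b
}
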
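ALLOWED_DOMAINS <- c("condition", "observation", "drug_era", "procedure")
ALLOWED_GENDERS <- c("male", "female", "unknown")

readDelim <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  sep <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t"
         else if (grepl("\\.csv$", path, ignore.case = TRUE)) ","
         else "auto"
  data.table::fread(path, sep = sep, colClasses = list(character = 1L),
                    data.table = TRUE, showProgress = FALSE)
}

#' Read and validate a person table
#'
#' Reads a delimited person table (comma or tab, detected from the file
#' extension) with columns `person_id`, `gender_concept`, `year_of_birth`,
#' `observation_period_start_date`, `observation_period_end_date`
#' (ISO-8601 dates). Every row is validated: dates must parse, the
#' observation period must be ordered, the birth year must not postdate the
#' observation start, person ids must be unique and the gender must be one
#' of `male`, `female`, `unknown`. Violations abort with the offending row
#' numbers.
#'
#' @param path path to the delimited file.
#' @return data.frame with columns `person_id` (character), `gender`,
#'   `birth_year`, `obs_start`, `obs_end`.
#' @export
readPersonTable <- function(path) {
  dt <- readDelim(path, "person")
  checkColumns(dt, c("person_id", "gender_concept", "year_of_birth",
                     "observation_period_start_date",
                     "observation_period_end_date"), "person table")
  if (nrow(dt) == 0) {
    return(data.frame(person_id = character(), gender = character(),
                      birth_year = integer(),
                      obs_start = as.Date(character()),
                      obs_end = as.Date(character()),
                      stringsAsFactors = FALSE))
  }
  start <- parseDateColumn(dt$observation_period_start_date,
                           "observation_period_start_date")
  end <- parseDateColumn(dt$observation_period_end_date,
                         "observation_period_end_date")
  gender <- tolower(trimws(as.character(dt$gender_concept)))
  badG <- which(!gender %in% ALLOWED_GENDERS)
  if (length(badG)) {
    stop(sprintf("person table: invalid gender at row(s) %s (allowed: %s)",
                 paste(head(badG, 10), collapse = ", "),
                 paste(ALLOWED_GENDERS, collapse = ", ")), call. = FALSE)
  }
  by <- suppressWarnings(as.integer(dt$year_of_birth))
  badY <- which(is.na(by))
  if (length(badY)) {
    stop(sprintf("person table: unparseable year_of_birth at row(s) %s",
                 paste(head(badY, 10), collapse = ", ")), call. = FALSE)
  }
  badW <- which(end < start)
  if (length(badW)) {
    stop(sprintf(
      "person table: observation_period_end_date before start date at row(s) %s",
      paste(head(badW, 10), collapse = ", ")), call. = FALSE)
  }
  badB <- which(by > yearOf(start))
  if (length(badB)) {
    stop(sprintf(
      "person table: year_of_birth after observation start at row(s) %s",
      paste(head(badB, 10), collapse = ", ")), call. = FALSE)
  }
  pid <- as.character(dt$person_id)
  dup <- which(duplicated(pid))
  if (length(dup)) {
    stop(sprintf("person table: duplicate person_id at row(s) %s",
                 paste(head(dup, 10), collapse = ", ")), call. = FALSE)
  }
  data.frame(person_id = pid, gender = gender, birth_year = by,
             obs_start = start, obs_end = end, stringsAsFactors = FALSE)
}

#' Read and filter an event table
#'
#' Reads a delimited long event table with columns `person_id`,
#' `concept_id`, `concept_name`, `domain`, `event_date`. Rows whose domain
#' is outside `includedDomains` are dropped (and counted); an unrecognised
#' domain value is a row-level error. When a person table is supplied,
#' events for unknown persons or dated outside the person's observation
#' window are excluded and counted. The drop counts are attached as the
#' `"attrition"` attribute and reported via `message()`.
#'
#' @param path path to the delimited file.
#' @param includedDomains subset of
#'   `c("condition", "observation", "drug_era", "procedure")`.
#' @param persons optional person table from [readPersonTable()] used to
#'   window-check events.
#' @param verbose emit per-filter messages.
#' @return data.frame of events with an `"attrition"` attribute.
#' @export
readEventTable <- function(path, includedDomains = ALLOWED_DOMAINS,
                           persons = NULL, verbose = TRUE) {
  bad <- setdiff(includedDomains, ALLOWED_DOMAINS)
  if (length(bad)) {
    stop(sprintf("includedDomains outside the allowed set: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  dt <- readDelim(path, "event")
  checkColumns(dt, c("person_id", "concept_id", "concept_name", "domain",
                     "event_date"), "event table")
  att <- attritionRow("events_read", nrow(dt), nrow(dt))
  if (nrow(dt) == 0) {
    out <- data.frame(person_id = character(), concept_id = integer(),
                      concept_name = character(), domain = character(),
                      event_date = as.Date(character()),
                      stringsAsFactors = FALSE)
    attr(out, "attrition") <- att
    return(out)
  }
  dom <- tolower(trimws(as.character(dt$domain)))
  unknown <- which(!dom %in% ALLOWED_DOMAINS)
  if (length(unknown)) {
    stop(sprintf("event table: unknown domain at row(s) %s",
                 paste(head(unknown, 10), collapse = ", ")), call. = FALSE)
  }
  ev <- data.frame(person_id = as.character(dt$person_id),
                   concept_id = as.integer(dt$concept_id),
                   concept_name = as.character(dt$concept_name),
                   domain = dom,
                   event_date = parseDateColumn(dt$event_date, "event_date"),
                   stringsAsFactors = FALSE)
  keep <- ev$domain %in% includedDomains
  att <- rbind(att, attritionRow("domain_filter", nrow(ev), sum(keep)))
  if (any(!keep)) {
    ctLog(verbose, sprintf("dropped %d event(s) outside included domains",
                           sum(!keep)))
  }
  ev <- ev[keep, , drop = FALSE]
  if (!is.null(persons)) {
    idx <- match(ev$person_id, persons$person_id)
    inWin <- !is.na(idx) &
      ev$event_date >= persons$obs_start[idx] &
      ev$event_date <= persons$obs_end[idx]
    att <- rbind(att, attritionRow("observation_window", nrow(ev), sum(inWin)))
    if (any(!inWin)) {
      ctLog(verbose, sprintf(
        "dropped %d event(s) outside the person observation window or for unknown persons",
        sum(!inWin)))
    }
    ev <- ev[inWin, , drop = FALSE]
  }
  rownames(ev) <- NULL
  attr(ev, "attrition") <- att
  ev
}

#' Read a cohort window table
#'
#' Columns: `person_id`, `cohort_start_date`, `cohort_end_date`. Windows
#' must be ordered and non-overlapping within a person.
#'
#' @param path path to the delimited file.
#' @return data.frame with `person_id`, `entry_date`, `exit_date`.
#' @export
readCohortTable <- function(path) {
  dt <- readDelim(path, "cohort")
  checkColumns(dt, c("person_id", "cohort_start_date", "cohort_end_date"),
               "cohort table")
  if (nrow(dt) == 0) {
    return(data.frame(person_id = character(),
                      entry_date = as.Date(character()),
                      exit_date = as.Date(character()),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(person_id = as.character(dt$person_id),
                    entry_date = parseDateColumn(dt$cohort_start_date,
                                                 "cohort_start_date"),
                    exit_date = parseDateColumn(dt$cohort_end_date,
                                                "cohort_end_date"),
                    stringsAsFactors = FALSE)
  badW <- which(out$exit_date < out$entry_date)
  if (length(badW)) {
    stop(sprintf("cohort table: exit before entry at row(s) %s",
                 paste(head(badW, 10), collapse = ", ")), call. = FALSE)
  }
  validateCohortWindows(out)
  out
}

validateCohortWindows <- function(cohort) {
  dt <- as.data.table(cohort)
  setorder(dt, person_id, entry_date)
  overlap <- dt[, {
    if (.N > 1) any(entry_date[-1] <= exit_date[-.N]) else FALSE
  }, by = person_id]
  bad <- overlap[overlap$V1 == TRUE, person_id]
  if (length(bad)) {
    stop(sprintf("cohort table: overlapping windows for person(s) %s",
                 paste(head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
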
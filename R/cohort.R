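#' Apply a cohort restriction to events
#'
#' Restricts the event table to the cohort windows and produces the table of
#' eligible sequence units. With `cohort = "whole-database"` every person
#' forms one unit whose window is their observation period and the events
#' pass through unchanged (apart from the observation-window check already
#' applied on read). With an explicit cohort table, each window becomes an
#' independent sequence unit (`unit_id = person_id#k`, windows ordered by
#' entry date) — a person enrolled over several periods is represented once
#' per period and pair counts downstream count sequence units, not persons.
#' Cohort windows are clipped to the person's observation period; events
#' outside every window are dropped and counted.
#'
#' @param events event data.frame from [readEventTable()].
#' @param persons person data.frame from [readPersonTable()].
#' @param cohort `"whole-database"` (or `NULL`) or a cohort window
#'   data.frame from [readCohortTable()].
#' @param verbose emit messages.
#' @return list with `units` (unit table), `events` (events annotated with
#'   `unit_id`) and `attrition`.
#' @export
applyCohort <- function(events, persons, cohort = "whole-database",
                        verbose = TRUE) {
  att <- attr(events, "attrition")
  if (is.null(att)) att <- attritionRow("events_in", nrow(events), nrow(events))
  wholeDb <- is.null(cohort) ||
    (is.character(cohort) && identical(cohort, "whole-database"))
  if (wholeDb) {
    units <- data.frame(unit_id = persons$person_id,
                        person_id = persons$person_id,
                        gender = persons$gender,
                        birth_year = persons$birth_year,
                        window_start = persons$obs_start,
                        window_end = persons$obs_end,
                        stringsAsFactors = FALSE)
  } else {
    unknown <- setdiff(unique(cohort$person_id), persons$person_id)
    if (length(unknown)) {
      stop(sprintf("cohort persons absent from the person table: %s",
                   paste(head(unknown, 10), collapse = ", ")), call. = FALSE)
    }
    validateCohortWindows(cohort)
    co <- as.data.table(cohort)
    setorder(co, person_id, entry_date)
    co[, k := seq_len(.N), by = person_id]
    idx <- match(co$person_id, persons$person_id)
    ws <- pmax(co$entry_date, persons$obs_start[idx])
    we <- pmin(co$exit_date, persons$obs_end[idx])
    keep <- ws <= we
    units <- data.frame(
      unit_id = paste0(co$person_id, "#", co$k),
      person_id = co$person_id,
      gender = persons$gender[idx],
      birth_year = persons$birth_year[idx],
      window_start = ws,
      window_end = we,
      stringsAsFactors = FALSE)[keep, , drop = FALSE]
    rownames(units) <- NULL
  }
  ev <- as.data.table(events)
  if (nrow(ev) == 0) {
    ev <- data.table(person_id = character(), concept_id = integer(),
                     concept_name = character(), domain = character(),
                     event_date = as.Date(character()))
  }
  un <- as.data.table(units)
  assigned <- un[ev,
                 on = .(person_id, window_start <= event_date,
                        window_end >= event_date),
                 nomatch = 0L,
                 .(unit_id = x.unit_id, person_id = i.person_id,
                   concept_id = i.concept_id, concept_name = i.concept_name,
                   domain = i.domain, event_date = i.event_date)]
  att <- rbind(att, attritionRow("cohort_windows", nrow(ev), nrow(assigned)))
  if (nrow(assigned) < nrow(ev)) {
    ctLog(verbose, sprintf("dropped %d event(s) outside cohort windows",
                           nrow(ev) - nrow(assigned)))
  }
  list(units = units, events = as.data.frame(assigned), attrition = att)
}

#' Reduce events to per-unit first-occurrence sequences
#'
#' For each sequence unit, keeps only the earliest occurrence of every
#' distinct concept and orders the resulting sequence by date, breaking
#' same-date ties by ascending concept id (a deterministic convention; the
#' temporal-gap parameter decides whether same-day events can ever pair).
#'
#' @param applied list from [applyCohort()], or an event data.frame carrying
#'   a `unit_id` column together with `units`.
#' @param units unit table (only needed when `applied` is a data.frame).
#' @return An [EventCohort-class] object.
#' @examples
#' persons <- data.frame(person_id = "p1", gender = "female",
#'                       birth_year = 1960,
#'                       obs_start = as.Date("2010-01-01"),
#'                       obs_end = as.Date("2019-12-31"))
#' events <- data.frame(person_id = "p1", concept_id = c(1L, 1L, 2L),
#'                      concept_name = c("A", "A", "B"), domain = "condition",
#'                      event_date = as.Date(c("2011-01-01", "2011-05-01",
#'                                             "2011-03-01")))
#' co <- firstOccurrences(applyCohort(events, persons, verbose = FALSE))
#' eventSequences(co)
#' @export
firstOccurrences <- function(applied, units = NULL) {
  if (is.data.frame(applied)) {
    stopifnot(!is.null(units), "unit_id" %in% names(applied))
    applied <- list(units = units, events = applied,
                    attrition = attritionRow("events_in", nrow(applied),
                                             nrow(applied)))
  }
  ev <- as.data.table(applied$events)
  if (nrow(ev)) {
    setorder(ev, unit_id, concept_id, event_date)
    first <- ev[, .SD[1L], by = .(unit_id, concept_id)]
    setorder(first, unit_id, event_date, concept_id)
    seqs <- as.data.frame(first[, .(unit_id, concept_id, concept_name,
                                    event_date)])
  } else {
    seqs <- data.frame(unit_id = character(), concept_id = integer(),
                       concept_name = character(),
                       event_date = as.Date(character()),
                       stringsAsFactors = FALSE)
  }
  att <- rbind(applied$attrition,
               attritionRow("first_occurrences", nrow(ev), nrow(seqs)))
  new("EventCohort", units = applied$units, sequences = seqs,
      attrition = att, metadata = list())
}

#' Number of sequence units in a cohort
#' @param cohort an [EventCohort-class].
#' @return integer count.
#' @export
nUnits <- function(cohort) nrow(cohort@units)
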
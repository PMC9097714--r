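#' Generate random longitudinal event data
#'
#' Produces a person table and a long event table in the schema consumed by
#' [readPersonTable()]/[readEventTable()]: every person gets a
#' uniform-random number of events in `eventsPerPerson`, with concepts
#' uniform over `nConcepts` background concept ids and dates uniform over
#' the observation window. Demographics are independent of everything else:
#' gender uniform over male/female, birth year uniform over
#' `birthYearRange`. The output is fully deterministic given `seed`.
#'
#' @param nPersons number of persons.
#' @param eventsPerPerson integer range `c(lo, hi)` of events per person
#'   (`c(0, 0)` produces event-free persons).
#' @param nConcepts number of distinct background concepts.
#' @param dateRange observation window (two Dates), shared by all persons.
#' @param birthYearRange inclusive birth-year span.
#' @param conceptOffset background concept ids are
#'   `conceptOffset + 1 ... conceptOffset + nConcepts`.
#' @param seed integer seed.
#' @return list with `persons` and `events` data.frames.
#' @examples
#' tabs <- generateRandomEvents(nPersons = 50, seed = 7)
#' range(table(tabs$events$person_id))
#' @export
generateRandomEvents <- function(nPersons = 1000,
                                 eventsPerPerson = c(1, 30),
                                 nConcepts = 100,
                                 dateRange = as.Date(c("2010-01-01",
                                                       "2019-12-31")),
                                 birthYearRange = c(1940, 2000),
                                 conceptOffset = 1000L,
                                 seed = 1L) {
  stopifnot(length(eventsPerPerson) == 2,
            eventsPerPerson[1] <= eventsPerPerson[2],
            eventsPerPerson[1] >= 0, nPersons >= 1, nConcepts >= 1)
  set.seed(as.integer(seed))
  pid <- sprintf("P%06d", seq_len(nPersons))
  persons <- data.frame(
    person_id = pid,
    gender = sample(c("male", "female"), nPersons, replace = TRUE),
    birth_year = sample(seq(birthYearRange[1], birthYearRange[2]),
                        nPersons, replace = TRUE),
    obs_start = dateRange[1],
    obs_end = dateRange[2],
    stringsAsFactors = FALSE)
  evRange <- seq(eventsPerPerson[1], eventsPerPerson[2])
  nEv <- if (length(evRange) == 1) {
    rep(evRange, nPersons)
  } else {
    sample(evRange, nPersons, replace = TRUE)
  }
  total <- sum(nEv)
  days <- as.integer(dateRange[2] - dateRange[1])
  conceptIds <- conceptOffset + sample.int(nConcepts, total, replace = TRUE)
  events <- data.frame(
    person_id = rep(pid, nEv),
    concept_id = conceptIds,
    concept_name = if (total) paste0("concept_", conceptIds)
                   else character(0),
    domain = rep("condition", total),
    event_date = dateRange[1] + sample.int(days + 1L, total,
                                           replace = TRUE) - 1L,
    stringsAsFactors = FALSE)
  list(persons = persons, events = events)
}

checkInjectedConcepts <- function(tables, ids) {
  clash <- intersect(ids, unique(tables$events$concept_id))
  if (length(clash)) {
    stop(sprintf("injected concept id(s) already present in the data: %s",
                 paste(clash, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

sampleAnchors <- function(persons, maxGap, anchorRange = NULL) {
  lo <- persons$obs_start
  hi <- persons$obs_end - maxGap
  if (!is.null(anchorRange)) {
    lo <- pmax(lo, as.Date(anchorRange[1]))
    hi <- pmin(hi, as.Date(anchorRange[2]))
  }
  if (any(hi < lo)) {
    stop("anchor range leaves no room for the event gap inside the window",
         call. = FALSE)
  }
  span <- as.integer(hi - lo)
  lo + vapply(span, function(s) sample.int(s + 1L, 1L) - 1L, integer(1))
}

#' Plant a pairwise risk signal
#'
#' Selects `nCarriers` persons without replacement; each carrier receives
#' E1 at an anchor date drawn uniformly so that the maximum gap still fits
#' in the observation window, and independently receives E2 at
#' `anchor + gap` (gap uniform over `gapRange`) with probability
#' `pE2GivenE1` — so the probability of observing E2 after E1 among
#' carriers is `pE2GivenE1` by construction. Optionally every non-carrier
#' receives E2 at its own anchor plus gap with probability `pE2Baseline`,
#' planting a background E2 risk so that the design relative risk is
#' `pE2GivenE1 / pE2Baseline`.
#'
#' @param tables list with `persons` and `events`.
#' @param e1,e2 injected concept ids (must not collide with existing ones).
#' @param nCarriers number of E1 carriers (<= persons).
#' @param pE2GivenE1 probability of E2 after E1 for carriers.
#' @param pE2Baseline probability of a background E2 for non-carriers.
#' @param gapRange uniform integer day-gap range between anchor and E2 (and
#'   E1 and E2 for carriers).
#' @param anchorRange optional date range constraining anchor dates (used
#'   e.g. to place all exposures early in the window).
#' @param seed integer seed.
#' @return The tables with injected rows appended; realized counts are in
#'   the `"injection"` attribute of the result.
#' @export
injectPair <- function(tables, e1, e2, nCarriers, pE2GivenE1,
                       pE2Baseline = 0, gapRange = c(30, 365),
                       anchorRange = NULL, seed = 1L) {
  stopifnot(nCarriers <= nrow(tables$persons), nCarriers >= 0,
            pE2GivenE1 >= 0, pE2GivenE1 <= 1,
            pE2Baseline >= 0, pE2Baseline <= 1,
            gapRange[1] >= 1, gapRange[1] <= gapRange[2])
  checkInjectedConcepts(tables, c(e1, e2))
  set.seed(as.integer(seed))
  persons <- tables$persons
  n <- nrow(persons)
  anchors <- sampleAnchors(persons, gapRange[2], anchorRange)
  gaps <- sample(seq(gapRange[1], gapRange[2]), n, replace = TRUE)
  carrier <- seq_len(n) %in% sample.int(n, nCarriers)
  hasE2 <- ifelse(carrier,
                  stats::runif(n) < pE2GivenE1,
                  stats::runif(n) < pE2Baseline)
  newRows <- list()
  if (any(carrier)) {
    newRows$e1 <- data.frame(
      person_id = persons$person_id[carrier],
      concept_id = e1, concept_name = paste0("injected_", e1),
      domain = "condition", event_date = anchors[carrier],
      stringsAsFactors = FALSE)
  }
  if (any(hasE2)) {
    newRows$e2 <- data.frame(
      person_id = persons$person_id[hasE2],
      concept_id = e2, concept_name = paste0("injected_", e2),
      domain = "condition", event_date = (anchors + gaps)[hasE2],
      stringsAsFactors = FALSE)
  }
  events <- rbind(tables$events, do.call(rbind, unname(newRows)))
  rownames(events) <- NULL
  out <- list(persons = persons, events = events)
  attr(out, "injection") <- list(
    e1 = e1, e2 = e2, nCarriers = nCarriers,
    nE2Exposed = sum(carrier & hasE2),
    nE2Baseline = sum(!carrier & hasE2))
  out
}

#' Plant a multi-event trajectory
#'
#' Exactly `nCarriers` persons (chosen without replacement) receive the
#' full ordered chain of concepts, with strictly positive adjacent gaps
#' drawn uniformly from `gapRange`, anchored so the whole chain fits inside
#' the observation window.
#'
#' @param tables list with `persons` and `events`.
#' @param concepts ordered vector of >= 2 injected concept ids.
#' @param nCarriers number of carriers.
#' @param gapRange uniform integer day-gap range between adjacent chain
#'   events.
#' @param seed integer seed.
#' @return The tables with injected rows appended.
#' @export
injectTrajectory <- function(tables, concepts, nCarriers,
                             gapRange = c(30, 365), seed = 1L) {
  stopifnot(length(concepts) >= 2, !anyDuplicated(concepts),
            nCarriers <= nrow(tables$persons), nCarriers >= 0,
            gapRange[1] >= 1, gapRange[1] <= gapRange[2])
  checkInjectedConcepts(tables, concepts)
  if (nCarriers == 0) return(tables)
  set.seed(as.integer(seed))
  persons <- tables$persons
  nSteps <- length(concepts) - 1L
  carrierIdx <- sample.int(nrow(persons), nCarriers)
  carriers <- persons[carrierIdx, , drop = FALSE]
  anchors <- sampleAnchors(carriers, nSteps * gapRange[2])
  gaps <- matrix(sample(seq(gapRange[1], gapRange[2]), nCarriers * nSteps,
                        replace = TRUE), nrow = nCarriers)
  cum <- gaps
  if (nSteps > 1) {
    for (cc in 2:nSteps) cum[, cc] <- cum[, cc - 1L] + gaps[, cc]
  }
  offsets <- cbind(0L, cum)
  newRows <- data.frame(
    person_id = rep(carriers$person_id, times = length(concepts)),
    concept_id = rep(concepts, each = nCarriers),
    concept_name = paste0("injected_", rep(concepts, each = nCarriers)),
    domain = "condition",
    event_date = rep(anchors, times = length(concepts)) + as.vector(offsets),
    stringsAsFactors = FALSE)
  events <- rbind(tables$events, newRows)
  rownames(events) <- NULL
  list(persons = persons, events = events)
}

#' Build an event cohort directly from generated tables
#'
#' Convenience wrapper chaining [applyCohort()] (whole-database mode) and
#' [firstOccurrences()] over in-memory synthetic tables.
#'
#' @param tables list with `persons` and `events`.
#' @return An [EventCohort-class].
#' @export
cohortFromTables <- function(tables) {
  firstOccurrences(applyCohort(tables$events, tables$persons,
                               verbose = FALSE))
}
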
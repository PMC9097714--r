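#' Enumerate ordered event pairs under a temporal gap window
#'
#' Every ordered pair of distinct concepts (E1, E2) whose first occurrences
#' within a sequence unit satisfy
#' `date(E1) + minGapDays <= date(E2) <= date(E1) + maxGapDays` contributes
#' one count; intermediate events between the two do not matter. Pairs never
#' realized are omitted.
#'
#' @param cohort an [EventCohort-class].
#' @param params a [StudyParams-class]; only the gap window is used here.
#' @return data.frame with `e1`, `e2`, `e1_name`, `e2_name`, `n_pair`,
#'   sorted by decreasing count then concept ids.
#' @export
enumeratePairs <- function(cohort, params = studyParams()) {
  s <- as.data.table(eventSequences(cohort))
  if (nrow(s) == 0) {
    return(data.frame(e1 = integer(), e2 = integer(), e1_name = character(),
                      e2_name = character(), n_pair = integer(),
                      stringsAsFactors = FALSE))
  }
  a <- s[, .(unit_id, e1 = concept_id, d1 = event_date)]
  b <- s[, .(unit_id, e2 = concept_id, d2 = event_date)]
  joined <- a[b, on = "unit_id", allow.cartesian = TRUE]
  joined <- joined[e1 != e2]
  joined[, gap := as.numeric(d2 - d1)]
  joined <- joined[gap >= params@minGapDays & gap <= params@maxGapDays]
  counts <- joined[, .(n_pair = .N), by = .(e1, e2)]
  nm <- conceptNames(cohort)
  counts[, `:=`(e1_name = nm[as.character(e1)], e2_name = nm[as.character(e2)])]
  setorder(counts, -n_pair, e1, e2)
  as.data.frame(counts[, .(e1, e2, e1_name, e2_name, n_pair)])
}

conceptNames <- function(cohort) {
  s <- eventSequences(cohort)
  nm <- s$concept_name[!duplicated(s$concept_id)]
  names(nm) <- s$concept_id[!duplicated(s$concept_id)]
  nm
}

#' Filter pairs by a minimum count or cohort prevalence
#'
#' A pair is kept when its count reaches `minPairCount`, or — when a
#' prevalence floor is configured — when it reaches
#' `ceiling(minPairPrevalence * nUnits)` ("at least this fraction of the
#' cohort" semantics).
#'
#' @param pairs data.frame from [enumeratePairs()].
#' @param params a [StudyParams-class].
#' @param nUnits number of sequence units in the cohort.
#' @return The filtered data.frame, with the applied count threshold in the
#'   `"threshold"` attribute.
#' @examples
#' pairs <- data.frame(e1 = 1L, e2 = 2L, e1_name = "A", e2_name = "B",
#'                     n_pair = 111L)
#' filterPairs(pairs, studyParams(minPairPrevalence = 0.01), nUnits = 11009)
#' @export
filterPairs <- function(pairs, params, nUnits) {
  stopifnot(nUnits >= 1)
  threshold <- if (!is.na(params@minPairCount)) {
    params@minPairCount
  } else {
    ceiling(params@minPairPrevalence * nUnits)
  }
  out <- pairs[pairs$n_pair >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}
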
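#' Accessors for package classes
#'
#' `cohortUnits()` returns the sequence-unit table of an
#' [EventCohort-class]; `eventSequences()` its first-occurrence sequences;
#' `attrition()` the attrition log; `resultsTable()` the per-pair results of
#' a [PairResults-class]; `graphNodes()`/`graphEdges()` the node and edge
#' tables of a [TrajectoryGraph-class]; `params()` the study parameters
#' attached to a result object.
#'
#' @param x an object of the documented class.
#' @return A data.frame (or [StudyParams-class] for `params()`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cohortUnits", function(x) standardGeneric("cohortUnits"))
#' @rdname accessors
#' @export
setGeneric("eventSequences", function(x) standardGeneric("eventSequences"))
#' @rdname accessors
#' @export
setGeneric("attrition", function(x) standardGeneric("attrition"))
#' @rdname accessors
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))
#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("params", function(x) standardGeneric("params"))

#' @rdname accessors
#' @export
setMethod("cohortUnits", "EventCohort", function(x) x@units)
#' @rdname accessors
#' @export
setMethod("eventSequences", "EventCohort", function(x) x@sequences)
#' @rdname accessors
#' @export
setMethod("attrition", "EventCohort", function(x) x@attrition)
#' @rdname accessors
#' @export
setMethod("resultsTable", "PairResults", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("params", "PairResults", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("graphNodes", "TrajectoryGraph", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("graphEdges", "TrajectoryGraph", function(x) x@edges)

setMethod("show", "StudyParams", function(object) {
  floor <- if (!is.na(object@minPairCount)) {
    sprintf("min pair count %g", object@minPairCount)
  } else {
    sprintf("min pair prevalence %g", object@minPairPrevalence)
  }
  cat("StudyParams (", object@mode, " mode)\n",
      "  gap window [", object@minGapDays, ", ",
      ifelse(is.infinite(object@maxGapDays), "Inf", object@maxGapDays),
      "] days; ", floor, "; RR >= ", object@rrMin, "\n",
      "  alpha ", object@alpha, " with ", object@correction,
      " correction; age bins ", object@ageBinYears,
      " y; match ratio 1:", object@matchRatio, "\n",
      "  propensity features: top ", object@topKConcepts,
      " concepts; seed ", object@seed, "\n", sep = "")
})

setMethod("show", "EventCohort", function(object) {
  cat("EventCohort with", nrow(object@units), "sequence units,",
      length(unique(object@units$person_id)), "persons,",
      nrow(object@sequences), "first-occurrence events,",
      length(unique(object@sequences$concept_id)), "distinct concepts\n")
  if (nrow(object@attrition)) {
    cat("attrition stages:", paste(object@attrition$stage, collapse = " -> "),
        "\n")
  }
})

setMethod("show", "PairResults", function(object) {
  tab <- object@table
  cat("PairResults:", nrow(tab), "pairs tested over", object@nUnits,
      "sequence units\n")
  if (nrow(tab)) {
    cat("  significant associations:", sum(tab$significant_assoc, na.rm = TRUE),
        "\n  significant directional pairs:",
        sum(tab$significant_direction, na.rm = TRUE), "\n")
  }
})

setMethod("show", "TrajectoryGraph", function(object) {
  cat("TrajectoryGraph with", nrow(object@nodes), "nodes and",
      nrow(object@edges), "directed edges\n")
})
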
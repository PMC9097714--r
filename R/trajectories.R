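#' Build the directed graph of significant directional pairs
#'
#' Nodes are the concepts participating in at least one significant
#' directional pair, annotated with the number of sequence units whose
#' history contains them; edges carry the pair's relative risk and count.
#' An optional minimum pair count filters rare edges for display.
#'
#' @param results a [PairResults-class].
#' @param cohort the [EventCohort-class] the pairs were tested on (for node
#'   patient counts and names).
#' @param minEdgeCount drop edges with `n_pair` below this value.
#' @return A [TrajectoryGraph-class].
#' @export
buildTrajectoryGraph <- function(results, cohort, minEdgeCount = 0) {
  tab <- resultsTable(results)
  keep <- !is.na(tab$significant_direction) & tab$significant_direction &
    (is.na(tab$n_pair) | tab$n_pair >= minEdgeCount)
  edges <- tab[keep, c("e1", "e2", "rr", "n_pair"), drop = FALSE]
  rownames(edges) <- NULL
  ids <- sort(unique(c(edges$e1, edges$e2)))
  s <- as.data.table(eventSequences(cohort))
  cnt <- s[concept_id %in% ids, .(n_units = .N), by = concept_id]
  nm <- conceptNames(cohort)
  nodes <- data.frame(concept_id = ids,
                      concept_name = unname(nm[as.character(ids)]),
                      n_units = cnt$n_units[match(ids, cnt$concept_id)],
                      stringsAsFactors = FALSE)
  nodes$n_units[is.na(nodes$n_units)] <- 0L
  new("TrajectoryGraph", nodes = nodes, edges = edges)
}

trajGraphToIgraph <- function(graph) {
  v <- data.frame(name = as.character(graph@nodes$concept_id),
                  label = graph@nodes$concept_name,
                  n_units = graph@nodes$n_units,
                  stringsAsFactors = FALSE)
  e <- data.frame(from = as.character(graph@edges$e1),
                  to = as.character(graph@edges$e2),
                  rr = graph@edges$rr,
                  n_pair = graph@edges$n_pair,
                  stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(e, directed = TRUE, vertices = v)
}

#' Compose candidate trajectories from the pair graph
#'
#' Enumerates every simple directed path of 2 to `maxLen` concepts in the
#' graph (no concept repeated within a path, so cycles are traversed at
#' most once and enumeration always terminates). The result is ordered
#' lexicographically by the concept-id sequence.
#'
#' @param graph a [TrajectoryGraph-class].
#' @param maxLen maximum number of concepts per trajectory (>= 2).
#' @return list of integer concept-id vectors.
#' @export
composeTrajectories <- function(graph, maxLen = 5) {
  stopifnot(maxLen >= 2)
  if (nrow(graph@edges) == 0) return(list())
  g <- trajGraphToIgraph(graph)
  paths <- list()
  for (v in igraph::V(g)$name) {
    sp <- igraph::all_simple_paths(g, from = v, mode = "out",
                                   cutoff = maxLen - 1)
    for (p in sp) {
      ids <- as.integer(igraph::V(g)$name[as.integer(p)])
      if (length(ids) >= 2) paths[[length(paths) + 1L]] <- ids
    }
  }
  keys <- vapply(paths, function(p)
    paste(formatC(p, width = 12, flag = "0"), collapse = ","), character(1))
  paths[order(keys)]
}

#' Count the units realizing an ordered trajectory
#'
#' A sequence unit realizes a trajectory when the first occurrences of all
#' its concepts are present in strictly increasing order, with every
#' adjacent gap inside the study gap window; other events in between do not
#' block a match.
#'
#' @param concepts ordered vector of >= 2 concept ids.
#' @param cohort an [EventCohort-class].
#' @param params a [StudyParams-class] (gap window).
#' @return Integer count of realizing units.
#' @export
countTrajectory <- function(concepts, cohort, params = studyParams()) {
  stopifnot(length(concepts) >= 2, !anyDuplicated(concepts))
  s <- as.data.table(eventSequences(cohort))
  sub <- s[concept_id %in% concepts,
           .(unit_id, concept_id, event_date = as.numeric(event_date))]
  if (nrow(sub) == 0) return(0L)
  wide <- data.table::dcast(sub, unit_id ~ concept_id,
                            value.var = "event_date")
  cols <- as.character(concepts)
  if (!all(cols %in% names(wide))) return(0L)
  m <- as.matrix(wide[, cols, with = FALSE])
  ok <- rep(TRUE, nrow(m))
  for (jj in seq_len(length(concepts) - 1)) {
    gapj <- m[, jj + 1] - m[, jj]
    ok <- ok & !is.na(gapj) & gapj >= params@minGapDays &
      gapj <= params@maxGapDays
  }
  as.integer(sum(ok))
}

#' Count a set of composed trajectories
#'
#' @param paths list of concept-id vectors from [composeTrajectories()].
#' @param cohort an [EventCohort-class].
#' @param params a [StudyParams-class].
#' @param includeUnrealized keep trajectories counted in zero units
#'   (composable but unrealized); default drops them.
#' @return data.frame with `trajectory` (arrow-joined concept ids),
#'   `length`, `n_patients` and a list-column `concepts`.
#' @export
countTrajectories <- function(paths, cohort, params = studyParams(),
                              includeUnrealized = FALSE) {
  if (length(paths) == 0) {
    return(data.frame(trajectory = character(), length = integer(),
                      n_patients = integer(), stringsAsFactors = FALSE))
  }
  n <- vapply(paths, countTrajectory, integer(1), cohort = cohort,
              params = params)
  nm <- conceptNames(cohort)
  lab <- vapply(paths, function(p) {
    nms <- nm[as.character(p)]
    nms[is.na(nms)] <- as.character(p)[is.na(nms)]
    paste(nms, collapse = " -> ")
  }, character(1))
  out <- data.frame(trajectory = lab,
                    length = lengths(paths),
                    n_patients = n,
                    stringsAsFactors = FALSE)
  out$concepts <- paths
  if (!includeUnrealized) {
    out <- out[out$n_patients > 0, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Rank counted trajectories
#'
#' Sorts by decreasing patient count, breaking ties lexicographically by
#' the concept-id sequence; optionally filters to trajectories starting
#' with a given concept prefix.
#'
#' @param counts data.frame from [countTrajectories()].
#' @param prefix optional vector of concept ids; keep only trajectories
#'   whose first concepts equal it.
#' @return The sorted (and filtered) data.frame.
#' @export
rankTrajectories <- function(counts, prefix = NULL) {
  if (!is.null(prefix) && nrow(counts)) {
    keep <- vapply(counts$concepts, function(p) {
      length(p) >= length(prefix) &&
        all(p[seq_along(prefix)] == prefix)
    }, logical(1))
    counts <- counts[keep, , drop = FALSE]
  }
  if (nrow(counts) == 0) return(counts)
  keys <- vapply(counts$concepts, function(p)
    paste(formatC(p, width = 12, flag = "0"), collapse = ","), character(1))
  out <- counts[order(-counts$n_patients, keys), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export the trajectory graph
#'
#' Writes the directed pair graph as GraphML or DOT, with the concept name
#' as node label, the unit count as node size attribute and the relative
#' risk and pair count as edge attributes.
#'
#' @param graph a [TrajectoryGraph-class].
#' @param path output file path.
#' @param format `"graphml"` or `"dot"`.
#' @return Invisibly, the path.
#' @export
exportGraph <- function(graph, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- trajGraphToIgraph(graph)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
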
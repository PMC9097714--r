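resolveInputs <- function(persons, events, cohort, includedDomains,
                          verbose) {
  if (is.character(persons)) persons <- readPersonTable(persons)
  if (is.character(events)) {
    events <- readEventTable(events, includedDomains = includedDomains,
                             persons = persons, verbose = verbose)
  }
  if (is.character(cohort) && !identical(cohort, "whole-database")) {
    cohort <- readCohortTable(cohort)
  }
  list(persons = persons, events = events, cohort = cohort)
}

paramsToList <- function(p) {
  sn <- slotNames(p)
  out <- lapply(sn, function(s) slot(p, s))
  names(out) <- sn
  out$maxGapDays <- if (is.infinite(out$maxGapDays)) "unbounded"
                    else out$maxGapDays
  out
}

#' Write the per-pair results table with privacy masking
#'
#' Tab-separated output, one row per tested pair; count columns below the
#' privacy threshold are written as `"<k"`.
#'
#' @param results a [PairResults-class].
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @export
writePairResults <- function(results, path) {
  tab <- resultsTable(results)
  k <- params(results)@privacyMinCount
  for (col in intersect(c("n_pair", "n_exposed", "n_background",
                          "k_exposed_e2", "k_background_e2",
                          "n_e1_first", "n_e2_first", "n_exposed_total"),
                        names(tab))) {
    tab[[col]] <- maskCounts(tab[[col]], k)
  }
  data.table::fwrite(tab[, setdiff(names(tab), "concepts"), drop = FALSE],
                     path, sep = "\t")
  invisible(path)
}

#' Write counted trajectories with privacy masking
#'
#' @param counts data.frame from [countTrajectories()].
#' @param path output TSV path.
#' @param privacyMinCount counts below this are masked.
#' @return Invisibly, the path.
#' @export
writeTrajectoryCounts <- function(counts, path, privacyMinCount = 20) {
  out <- counts[, c("trajectory", "length", "n_patients"), drop = FALSE]
  out$concept_ids <- vapply(counts$concepts, paste, character(1),
                            collapse = " -> ")
  out$n_patients <- maskCounts(out$n_patients, privacyMinCount)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

writeBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writePairResults(bundle$results, file.path(outDir, "pairs.tsv"))
  if (nrow(graphEdges(bundle$graph))) {
    exportGraph(bundle$graph, file.path(outDir, "graph.graphml"), "graphml")
    exportGraph(bundle$graph, file.path(outDir, "graph.dot"), "dot")
  }
  writeTrajectoryCounts(bundle$trajectories,
                        file.path(outDir, "trajectories.tsv"),
                        params(bundle$results)@privacyMinCount)
  jsonlite::write_json(bundle$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}

#' Run a discovery study end-to-end
#'
#' Executes the full framework on a dataset without prior knowledge:
#' cohort restriction, first-occurrence sequences, ordered pair enumeration
#' under the gap window, count/prevalence filtering, matched
#' exposed/background testing with Fisher, relative risk and binomial
#' direction tests under multiple-testing correction, trajectory graph
#' construction, simple-path composition and per-unit counting. A manifest
#' records the parameters, seed and the attrition counts at every stage.
#'
#' @param persons person table (data.frame) or path.
#' @param events event table (data.frame) or path.
#' @param cohort `"whole-database"`, a cohort data.frame, or a path.
#' @param params a [StudyParams-class].
#' @param includedDomains event domains to keep when reading from a path.
#' @param outDir optional output directory; when given, writes `pairs.tsv`,
#'   `graph.graphml`, `graph.dot`, `trajectories.tsv` and `manifest.json`.
#' @param verbose emit per-stage messages.
#' @return Invisibly, a list with `cohort`, `pairs`, `results`, `graph`,
#'   `trajectories` and `manifest`.
#' @export
runDiscovery <- function(persons, events, cohort = "whole-database",
                         params = studyParams(),
                         includedDomains = ALLOWED_DOMAINS,
                         outDir = NULL, verbose = FALSE) {
  stopifnot(identical(params@mode, "discovery"))
  inp <- resolveInputs(persons, events, cohort, includedDomains, verbose)
  ctLog(verbose, "building cohort sequences")
  eco <- firstOccurrences(applyCohort(inp$events, inp$persons, inp$cohort,
                                      verbose = verbose))
  ctLog(verbose, "enumerating pairs")
  allPairs <- enumeratePairs(eco, params)
  pairs <- filterPairs(allPairs, params, nUnits(eco))
  ctLog(verbose, sprintf("testing %d candidate pairs", nrow(pairs)))
  results <- testPairs(eco, pairs, params, verbose = verbose)
  graph <- buildTrajectoryGraph(results, eco)
  ctLog(verbose, "composing and counting trajectories")
  paths <- composeTrajectories(graph, params@maxTrajectoryLength)
  trajectories <- rankTrajectories(countTrajectories(paths, eco, params))
  tab <- resultsTable(results)
  manifest <- list(
    mode = "discovery",
    parameters = paramsToList(params),
    pair_count_threshold = attr(pairs, "threshold"),
    attrition = attrition(eco),
    stage_counts = list(
      persons = nrow(inp$persons),
      sequence_units = nUnits(eco),
      first_occurrence_events = nrow(eventSequences(eco)),
      pairs_enumerated = nrow(allPairs),
      pairs_past_floor = nrow(pairs),
      pairs_tested = sum(tab$status == "tested"),
      pairs_untestable = sum(tab$status != "tested"),
      significant_associations = sum(tab$significant_assoc, na.rm = TRUE),
      directional_pairs = sum(tab$significant_direction, na.rm = TRUE),
      trajectories_composed = length(paths),
      trajectories_realized = nrow(trajectories)))
  bundle <- list(cohort = eco, pairs = pairs, results = results,
                 graph = graph, trajectories = trajectories,
                 manifest = manifest)
  if (!is.null(outDir)) writeBundle(bundle, outDir)
  invisible(bundle)
}

#' Run a validation study over a supplied pair list
#'
#' Tests exactly the listed pairs (the hypotheses discovered in another
#' dataset). Pairs whose concepts never co-occur in order are reported with
#' status `"did not occur"`; pairs below the count floor as
#' `"below count threshold"`. Tested pairs are classified as `confirmed`
#' (significant association in the expected direction with RR at or above
#' `rrMin`), `opposite direction` (significant, but the dominant temporal
#' order is reversed), `opposite effect` (significant association with RR
#' below 1 when an increased risk was expected) or `not significant`.
#' Bonferroni is the default correction in this mode.
#'
#' @param persons,events,cohort as in [runDiscovery()].
#' @param pairList data.frame with columns `e1_concept_id`,
#'   `e2_concept_id` (a `validation_status` column is added on output).
#' @param params a [StudyParams-class] with `mode = "validation"`.
#' @param includedDomains event domains to keep when reading from a path.
#' @param outDir optional output directory.
#' @param verbose emit per-stage messages.
#' @return Invisibly, a list as in [runDiscovery()] plus `validation`
#'   (the annotated pair list).
#' @export
runValidation <- function(persons, events, pairList,
                          cohort = "whole-database",
                          params = studyParams(mode = "validation"),
                          includedDomains = ALLOWED_DOMAINS,
                          outDir = NULL, verbose = FALSE) {
  stopifnot(identical(params@mode, "validation"))
  if (is.null(pairList) || nrow(pairList) == 0) {
    stop("validation mode requires a non-empty pair list", call. = FALSE)
  }
  checkColumns(pairList, c("e1_concept_id", "e2_concept_id"), "pair list")
  inp <- resolveInputs(persons, events, cohort, includedDomains, verbose)
  eco <- firstOccurrences(applyCohort(inp$events, inp$persons, inp$cohort,
                                      verbose = verbose))
  allPairs <- enumeratePairs(eco, params)
  key <- paste(allPairs$e1, allPairs$e2)
  wanted <- data.frame(e1 = as.integer(pairList$e1_concept_id),
                       e2 = as.integer(pairList$e2_concept_id))
  idx <- match(paste(wanted$e1, wanted$e2), key)
  wanted$n_pair <- ifelse(is.na(idx), 0L, allPairs$n_pair[idx])
  nm <- conceptNames(eco)
  wanted$e1_name <- unname(nm[as.character(wanted$e1)])
  wanted$e2_name <- unname(nm[as.character(wanted$e2)])
  threshold <- if (!is.na(params@minPairCount)) params@minPairCount
               else ceiling(params@minPairPrevalence * nUnits(eco))
  testable <- wanted[wanted$n_pair >= threshold, , drop = FALSE]
  results <- testPairs(eco, testable, params, verbose = verbose)
  tab <- resultsTable(results)
  ridx <- match(paste(wanted$e1, wanted$e2), paste(tab$e1, tab$e2))
  status <- character(nrow(wanted))
  for (i in seq_len(nrow(wanted))) {
    if (wanted$n_pair[i] == 0) {
      status[i] <- "did not occur"
    } else if (is.na(ridx[i])) {
      status[i] <- "below count threshold"
    } else {
      r <- tab[ridx[i], ]
      status[i] <- if (r$status != "tested") {
        r$status
      } else if (isTRUE(r$significant_direction)) {
        "confirmed"
      } else if (isTRUE(r$significant_assoc) &&
                 !is.na(r$binom_p_adj) && r$binom_p_adj < params@alpha &&
                 r$n_e2_first > r$n_e1_first) {
        "opposite direction"
      } else if (!is.na(r$fisher_p_adj) && r$fisher_p_adj < params@alpha &&
                 !is.na(r$rr) && r$rr < 1) {
        "opposite effect"
      } else {
        "not significant"
      }
    }
  }
  wanted$validation_status <- status
  names(wanted)[match(c("e1", "e2"), names(wanted))] <-
    c("e1_concept_id", "e2_concept_id")
  graph <- buildTrajectoryGraph(results, eco)
  paths <- composeTrajectories(graph, params@maxTrajectoryLength)
  trajectories <- rankTrajectories(countTrajectories(paths, eco, params))
  manifest <- list(
    mode = "validation",
    parameters = paramsToList(params),
    pair_count_threshold = threshold,
    attrition = attrition(eco),
    stage_counts = list(
      persons = nrow(inp$persons),
      sequence_units = nUnits(eco),
      pairs_listed = nrow(wanted),
      pairs_absent = sum(status == "did not occur"),
      pairs_below_threshold = sum(status == "below count threshold"),
      pairs_tested = sum(tab$status == "tested"),
      pairs_confirmed = sum(status == "confirmed"),
      pairs_opposite_direction = sum(status == "opposite direction"),
      pairs_opposite_effect = sum(status == "opposite effect")))
  bundle <- list(cohort = eco, pairs = testable, results = results,
                 graph = graph, trajectories = trajectories,
                 validation = wanted, manifest = manifest)
  if (!is.null(outDir)) {
    writeBundle(bundle, outDir)
    data.table::fwrite(wanted, file.path(outDir, "validation.tsv"),
                       sep = "\t")
  }
  invisible(bundle)
}

#' Read a run configuration file
#'
#' YAML configuration with keys `person_table`, `event_table`,
#' `cohort_table` (optional), `pair_list` (validation mode), `mode`,
#' `output_dir`, `included_domains` and a `params` block whose entries
#' override [studyParams()] defaults.
#'
#' @param path path to a YAML file.
#' @return list with `persons`, `events`, `cohort`, `pairList`, `outDir`,
#'   `includedDomains` and a [StudyParams-class] in `params`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  p <- cfg$params
  if (is.null(p)) p <- list()
  if (!is.null(cfg$mode)) p$mode <- cfg$mode
  if (!is.null(p$maxGapDays) && identical(p$maxGapDays, "unbounded")) {
    p$maxGapDays <- Inf
  }
  params <- do.call(studyParams, p)
  list(persons = cfg$person_table,
       events = cfg$event_table,
       cohort = if (is.null(cfg$cohort_table)) "whole-database"
                else cfg$cohort_table,
       pairList = cfg$pair_list,
       outDir = if (is.null(cfg$output_dir)) "." else cfg$output_dir,
       includedDomains = if (is.null(cfg$included_domains)) ALLOWED_DOMAINS
                         else cfg$included_domains,
       params = params)
}
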
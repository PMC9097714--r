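#' @import methods
#' @importFrom stats median setNames
#' @importFrom utils head
NULL

#' Study parameters for trajectory detection
#'
#' An S4 container for all tunable parameters of a trajectory study: the
#' temporal gap window between paired events, the minimum pair count (or
#' cohort prevalence) a pair must reach to be tested, the relative-risk
#' range of interest, significance level and multiple-testing correction,
#' matching configuration, privacy masking threshold and the random seed.
#'
#' @slot minGapDays minimum days between the two first occurrences of a pair
#'   (default 1: strict temporal order, same-day co-recording excluded).
#' @slot maxGapDays maximum days between the two events; `Inf` = unbounded.
#' @slot minPairCount minimum number of sequence units realizing a pair for
#'   it to be tested (`NA` when `minPairPrevalence` is used instead).
#' @slot minPairPrevalence minimum fraction of the cohort realizing a pair
#'   (`NA` when `minPairCount` is used); converted to a count by ceiling.
#' @slot rrMin lower bound of the relative-risk range of interest; pairs
#'   with estimated RR below it are not flagged significant.
#' @slot alpha significance level applied to adjusted p-values.
#' @slot correction multiple-testing correction, `"fdr"` or `"bonferroni"`.
#' @slot mode `"discovery"` or `"validation"`.
#' @slot ageBinYears width of the exact-matching age bins in years.
#' @slot matchRatio background-to-exposed matching ratio.
#' @slot topKConcepts number of most prevalent concepts used as prior-event
#'   indicator features in the propensity model.
#' @slot maxTrajectoryLength maximum number of concepts in a composed
#'   trajectory.
#' @slot privacyMinCount counts below this value are masked in written
#'   outputs.
#' @slot seed integer seed governing any stochastic step.
#' @export
setClass("StudyParams", representation(
  minGapDays          = "numeric",
  maxGapDays          = "numeric",
  minPairCount        = "numeric",
  minPairPrevalence   = "numeric",
  rrMin               = "numeric",
  alpha               = "numeric",
  correction          = "character",
  mode                = "character",
  ageBinYears         = "numeric",
  matchRatio          = "numeric",
  topKConcepts        = "numeric",
  maxTrajectoryLength = "numeric",
  privacyMinCount     = "numeric",
  seed                = "numeric"
))

setValidity("StudyParams", function(object) {
  msg <- character()
  if (object@minGapDays < 0) msg <- c(msg, "minGapDays must be >= 0")
  if (object@minGapDays > object@maxGapDays)
    msg <- c(msg, "minGapDays must be <= maxGapDays")
  hasCount <- !is.na(object@minPairCount)
  hasPrev  <- !is.na(object@minPairPrevalence)
  if (hasCount == hasPrev)
    msg <- c(msg, "exactly one of minPairCount / minPairPrevalence must be set")
  if (hasCount && object@minPairCount < 1)
    msg <- c(msg, "minPairCount must be >= 1")
  if (hasPrev && (object@minPairPrevalence <= 0 || object@minPairPrevalence > 1))
    msg <- c(msg, "minPairPrevalence must be in (0, 1]")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (!object@correction %in% c("fdr", "bonferroni"))
    msg <- c(msg, "correction must be 'fdr' or 'bonferroni'")
  if (!object@mode %in% c("discovery", "validation"))
    msg <- c(msg, "mode must be 'discovery' or 'validation'")
  if (object@rrMin <= 0) msg <- c(msg, "rrMin must be positive")
  if (object@ageBinYears < 1) msg <- c(msg, "ageBinYears must be >= 1")
  if (object@matchRatio < 1) msg <- c(msg, "matchRatio must be >= 1")
  if (object@maxTrajectoryLength < 2)
    msg <- c(msg, "maxTrajectoryLength must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct study parameters
#'
#' @param minGapDays,maxGapDays inclusive temporal gap window in days.
#' @param minPairCount minimum pair count; set to `NA` to use a prevalence
#'   floor instead.
#' @param minPairPrevalence minimum pair prevalence as a fraction of the
#'   cohort; mutually exclusive with `minPairCount`.
#' @param rrMin lower bound of the relative-risk range of interest.
#' @param alpha significance level for adjusted p-values.
#' @param correction `"fdr"` (discovery default) or `"bonferroni"`
#'   (validation default).
#' @param mode `"discovery"` or `"validation"`.
#' @param ageBinYears exact-matching age bin width.
#' @param matchRatio background members matched per exposed unit.
#' @param topKConcepts number of prevalent-concept propensity features.
#' @param maxTrajectoryLength maximum composed trajectory length.
#' @param privacyMinCount masking threshold for written counts.
#' @param seed integer random seed.
#' @return A validated [StudyParams-class] object.
#' @examples
#' studyParams(minPairCount = 10, maxGapDays = 5 * 365)
#' @export
studyParams <- function(minGapDays = 1, maxGapDays = Inf,
                        minPairCount = 20, minPairPrevalence = NA_real_,
                        rrMin = 1, alpha = 0.05,
                        correction = NULL,
                        mode = "discovery",
                        ageBinYears = 5, matchRatio = 1,
                        topKConcepts = 100, maxTrajectoryLength = 5,
                        privacyMinCount = 20, seed = 1L) {
  if (!is.na(minPairPrevalence) && !missing(minPairPrevalence) &&
      missing(minPairCount)) {
    minPairCount <- NA_real_
  }
  if (is.null(correction)) {
    correction <- if (identical(mode, "validation")) "bonferroni" else "fdr"
  }
  new("StudyParams",
      minGapDays = as.numeric(minGapDays), maxGapDays = as.numeric(maxGapDays),
      minPairCount = as.numeric(minPairCount),
      minPairPrevalence = as.numeric(minPairPrevalence),
      rrMin = as.numeric(rrMin), alpha = as.numeric(alpha),
      correction = correction, mode = mode,
      ageBinYears = as.numeric(ageBinYears), matchRatio = as.numeric(matchRatio),
      topKConcepts = as.numeric(topKConcepts),
      maxTrajectoryLength = as.numeric(maxTrajectoryLength),
      privacyMinCount = as.numeric(privacyMinCount), seed = as.numeric(seed))
}

#' Cohort of per-unit first-occurrence event sequences
#'
#' Holds the eligible sequence units (one per person and cohort window) with
#' their demographics and observation windows, the per-unit chronologically
#' ordered first occurrences of distinct concepts, and the attrition log of
#' every filtering step that produced them. Validity enforces the
#' first-occurrence invariants: at most one row per (unit, concept), event
#' dates inside the unit's window, and every sequence row belonging to a
#' known unit.
#'
#' @slot units data.frame with columns `unit_id`, `person_id`, `gender`,
#'   `birth_year`, `window_start`, `window_end`.
#' @slot sequences data.frame with columns `unit_id`, `concept_id`,
#'   `concept_name`, `event_date`, sorted by unit, date, concept.
#' @slot attrition data.frame logging `stage`, `n_in`, `n_kept`, `n_dropped`
#'   for each filter applied.
#' @slot metadata list of free-form provenance entries.
#' @export
setClass("EventCohort", representation(
  units     = "data.frame",
  sequences = "data.frame",
  attrition = "data.frame",
  metadata  = "list"
))

setValidity("EventCohort", function(object) {
  u <- object@units
  s <- object@sequences
  msg <- character()
  needU <- c("unit_id", "person_id", "gender", "birth_year",
             "window_start", "window_end")
  needS <- c("unit_id", "concept_id", "concept_name", "event_date")
  if (!all(needU %in% names(u)))
    return(paste("units is missing columns:",
                 paste(setdiff(needU, names(u)), collapse = ", ")))
  if (!all(needS %in% names(s)))
    return(paste("sequences is missing columns:",
                 paste(setdiff(needS, names(s)), collapse = ", ")))
  if (anyDuplicated(u$unit_id)) msg <- c(msg, "duplicate unit_id in units")
  if (nrow(s)) {
    if (anyDuplicated(s[, c("unit_id", "concept_id")]))
      msg <- c(msg, "sequences contain a repeated concept within a unit")
    idx <- match(s$unit_id, u$unit_id)
    if (anyNA(idx)) {
      msg <- c(msg, "sequences contain unknown unit_id")
    } else if (any(s$event_date < u$window_start[idx] |
                   s$event_date > u$window_end[idx])) {
      msg <- c(msg, "sequences contain event dates outside the unit window")
    }
  }
  if (any(u$window_start > u$window_end))
    msg <- c(msg, "unit window_start after window_end")
  if (length(msg)) msg else TRUE
})

#' Per-pair statistical test results
#'
#' One row per tested ordered event pair, carrying the matched-group counts,
#' relative risk with confidence interval, Fisher association p-value,
#' binomial direction p-value, their adjusted versions and significance
#' flags. Produced by [testPairs()].
#'
#' @slot table data.frame of per-pair results.
#' @slot params the [StudyParams-class] used for testing.
#' @slot nUnits number of sequence units in the tested cohort.
#' @export
setClass("PairResults", representation(
  table  = "data.frame",
  params = "StudyParams",
  nUnits = "numeric"
))

#' Directed graph of significant directional event pairs
#'
#' Nodes are concepts annotated with the number of sequence units whose
#' history contains them; edges are the significant directional pairs,
#' weighted by relative risk and pair count.
#'
#' @slot nodes data.frame with `concept_id`, `concept_name`, `n_units`.
#' @slot edges data.frame with `e1`, `e2`, `rr`, `n_pair`.
#' @export
setClass("TrajectoryGraph", representation(
  nodes = "data.frame",
  edges = "data.frame"
))

setValidity("TrajectoryGraph", function(object) {
  e <- object@edges
  if (nrow(e) &&
      !all(c(e$e1, e$e2) %in% object@nodes$concept_id))
    return("every edge endpoint must be a node")
  TRUE
})
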
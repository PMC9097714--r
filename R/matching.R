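#' Build the exposed group for a pair
#'
#' One exposed unit per sequence unit containing E1, with the index date set
#' to the first E1 occurrence, age at index (`year(index) - birth_year`),
#' index calendar year and the exact-matching age bin.
#'
#' @param e1 concept id of the exposure event.
#' @param cohort an [EventCohort-class].
#' @param params a [StudyParams-class] (for the age bin width).
#' @return data.frame with `unit_id`, `person_id`, `index_date`, `gender`,
#'   `age_at_index`, `index_year`, `age_bin`.
#' @export
buildExposed <- function(e1, cohort, params = studyParams()) {
  s <- as.data.table(eventSequences(cohort))
  u <- as.data.table(cohortUnits(cohort))
  ex <- s[concept_id == e1, .(unit_id, index_date = event_date)]
  ex <- u[ex, on = "unit_id"]
  ex[, `:=`(index_year = yearOf(index_date))]
  ex[, `:=`(age_at_index = index_year - birth_year)]
  ex[, `:=`(age_bin = age_at_index %/% params@ageBinYears)]
  as.data.frame(ex[, .(unit_id, person_id, index_date, gender,
                       age_at_index, index_year, age_bin)])
}

#' Propensity scores from a ridge-penalized logistic model
#'
#' Fits a ridge-penalized (L2) logistic regression of the exposure
#' indicator on the feature matrix and returns the fitted exposure
#' probabilities, which lie strictly in (0, 1) and are deterministic for a
#' given input. The penalty keeps scores finite even under perfect
#' separation.
#'
#' @param x numeric (possibly sparse) feature matrix, one row per unit; by
#'   convention the indicator of each of the K most prevalent concepts
#'   occurring strictly before the unit's index date, plus the prior-event
#'   count.
#' @param exposed binary indicator (0/1 or logical) of exposure, one per
#'   row of `x`.
#' @param lambda ridge penalty.
#' @return Numeric vector of scores in (0, 1).
#' @export
computePropensity <- function(x, exposed, lambda = 0.1) {
  exposed <- as.integer(exposed)
  if (length(unique(exposed)) < 2 || min(table(exposed)) < 2) {
    stop("cannot fit propensity model: need at least 2 units in each class",
         call. = FALSE)
  }
  if (is.null(dim(x))) x <- as.matrix(x)
  if (ncol(x) < 2) x <- cbind(x, pad_ = 0)
  # all-constant features carry no information: every unit gets the
  # marginal exposure rate
  mu <- Matrix::colMeans(x)
  v <- Matrix::colMeans(x * x) - mu^2
  if (all(v < 1e-12)) {
    return(rep(mean(exposed), length(exposed)))
  }
  fit <- glmnet::glmnet(x, exposed, family = "binomial", alpha = 0,
                        lambda = c(10 * lambda, lambda),
                        standardize = TRUE, thresh = 1e-6)
  eta <- as.numeric(glmnet::predict.glmnet(fit, newx = x, s = lambda,
                                           type = "link"))
  stats::plogis(eta)
}

#' Match a background group to the exposed units
#'
#' Within each exact stratum (gender x age bin x calendar year of the index
#' date), each exposed unit receives `matchRatio` background members by
#' greedy nearest-neighbor matching on the propensity score without
#' replacement. A candidate is eligible for an exposed unit when its
#' observation window covers that unit's index date — which it inherits as
#' its assigned index date — and it carries no E1 on or before that date;
#' the pool must exclude all persons of the exposed group, so no person
#' appears in both groups of the same pair. Exposed units with no eligible
#' candidates are counted in `nUnmatchedExposed` and excluded. Score ties
#' break by lower person id, then unit id; exposed units are processed in
#' person-id order.
#'
#' @param exposed data.frame from [buildExposed()] with a propensity score
#'   column `ps`.
#' @param pool data.frame of candidate units (columns `unit_id`,
#'   `person_id`, `gender`, `birth_year`, `window_start`, `window_end`,
#'   `ps`); must not contain persons from the exposed group.
#' @param params a [StudyParams-class].
#' @return list with `matches` (data.frame `exposed_unit_id`, `bg_unit_id`,
#'   `index_date`), `matchedExposed` (unit ids), `nUnmatchedExposed`.
#' @export
matchBackground <- function(exposed, pool, params = studyParams()) {
  if (nrow(pool) == 0) stop("empty background pool", call. = FALSE)
  if (length(intersect(exposed$person_id, pool$person_id))) {
    stop("background pool contains exposed persons", call. = FALSE)
  }
  mm <- matchUnits(
    exPs = exposed$ps, exPerson = exposed$person_id,
    exGender = exposed$gender, exBin = exposed$age_bin,
    exYear = exposed$index_year, exDate = as.numeric(exposed$index_date),
    poolPs = pool$ps, poolPerson = pool$person_id,
    poolGender = pool$gender, poolBirth = pool$birth_year,
    poolWs = as.numeric(pool$window_start),
    poolWe = as.numeric(pool$window_end),
    ageBin = params@ageBinYears, ratio = as.integer(params@matchRatio))
  matches <- data.frame(
    exposed_unit_id = rep(exposed$unit_id[mm$exSel],
                          each = as.integer(params@matchRatio)),
    bg_unit_id = pool$unit_id[mm$bgSel],
    index_date = as.Date(mm$bgIndex, origin = "1970-01-01"),
    stringsAsFactors = FALSE)
  list(matches = matches,
       matchedExposed = unique(matches$exposed_unit_id),
       nUnmatchedExposed = mm$nUnmatched)
}
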
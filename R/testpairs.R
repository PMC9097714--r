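#' Test candidate event pairs with matched exposed/background groups
#'
#' For every candidate pair E1 -> E2 this runs the full matched
#' case-control test: the exposed group (units with a prior E1, index date
#' = first E1 occurrence) is matched 1:`matchRatio` to background units on
#' exact covariates (gender, age bin, calendar year of E1) plus a
#' ridge-logistic propensity score built from prior-event indicators of the
#' `topKConcepts` most prevalent concepts and the prior-event count; the
#' prevalence of E2 strictly after the (assigned) index date and within the
#' gap window is then compared between the groups with Fisher's exact test
#' and summarized as a relative risk with its confidence interval, and the
#' temporal order of the pair over all units carrying both events is tested
#' with an exact binomial test. Fisher and binomial p-value families are
#' each corrected for multiple testing across all tested pairs, and the
#' pairs are classified via [classifyPairs()].
#'
#' Pairs that cannot be tested (no exposed units, an empty background pool,
#' a degenerate propensity model, or no exposed unit with an exact-stratum
#' match) are retained with an explanatory `status` and NA statistics.
#'
#' @param cohort an [EventCohort-class].
#' @param pairs data.frame of candidate pairs (`e1`, `e2`, optionally
#'   `n_pair` and names), typically [enumeratePairs()] + [filterPairs()].
#' @param params a [StudyParams-class].
#' @param verbose emit progress messages.
#' @return A [PairResults-class] object.
#' @export
testPairs <- function(cohort, pairs, params = studyParams(), verbose = FALSE) {
  units <- cohortUnits(cohort)
  s <- eventSequences(cohort)
  nP <- nrow(pairs)
  nU <- nrow(units)

  # --- precomputed index structures shared by all pairs -------------------
  uIdx <- seq_len(nU)
  uid <- units$unit_id
  person <- match(units$person_id, sort(unique(units$person_id)))
  gender <- match(units$gender, c("male", "female", "unknown"))
  birth <- units$birth_year
  ws <- as.numeric(units$window_start)
  we <- as.numeric(units$window_end)

  sUnit <- match(s$unit_id, uid)
  sDate <- as.numeric(s$event_date)
  # per-concept unit indices and first-occurrence dates
  byConcept <- split(seq_len(nrow(s)), s$concept_id)
  conceptIds <- as.integer(names(byConcept))

  # top-K most prevalent concepts (ties by concept id) as features
  prevN <- lengths(byConcept)
  ordPrev <- order(-prevN, conceptIds)
  K <- min(params@topKConcepts, length(conceptIds))
  topK <- conceptIds[ordPrev[seq_len(K)]]
  featJ <- match(s$concept_id, topK)
  fSel <- which(!is.na(featJ))
  # feature triplets sorted by date for prefix slicing at a reference date
  fOrd <- fSel[order(sDate[fSel])]
  fDateSorted <- sDate[fOrd]
  fUnitSorted <- sUnit[fOrd]
  fJSorted <- featJ[fOrd]
  # all events sorted by date, for prior-event counts at a reference date
  eOrd <- order(sDate)
  eDateSorted <- sDate[eOrd]
  eUnitSorted <- sUnit[eOrd]
  # per-unit event structures (dates ascending within unit) for exposed rows
  uf <- factor(sUnit, levels = uIdx)
  o2 <- order(sUnit, sDate)
  fByUnitJ <- split(featJ[o2], uf[o2])
  fByUnitD <- split(sDate[o2], uf[o2])

  gapLo <- max(1, params@minGapDays)  # outcome strictly after index
  gapHi <- params@maxGapDays
  yearOfNum <- function(x) as.integer(format(as.Date(x, origin = "1970-01-01"),
                                             "%Y"))

  blank <- list(
    n_exposed_total = NA_integer_, n_unmatched_exposed = NA_integer_,
    n_exposed = NA_integer_, n_background = NA_integer_,
    k_exposed_e2 = NA_integer_, k_background_e2 = NA_integer_,
    rr = NA_real_, rr_ci_low = NA_real_, rr_ci_high = NA_real_,
    fisher_p = NA_real_, n_e1_first = NA_integer_,
    n_e2_first = NA_integer_, binom_p = NA_real_)
  out <- lapply(blank, rep, nP)
  status <- rep("tested", nP)

  # the exposed group, propensity model and matched background depend on
  # E1 only, so they are computed once per distinct E1 and reused for all
  # pairs sharing it
  e2dScratch <- rep(NA_real_, nU)
  done <- 0L
  for (e1 in unique(pairs$e1)) {
    rowsI <- which(pairs$e1 == e1)
    r1 <- byConcept[[as.character(e1)]]
    out$n_exposed_total[rowsI] <- length(r1)
    exU <- sUnit[r1]
    exD <- sDate[r1]

    # --- E1-level work: pool, propensity, matching ------------------------
    e1Status <- NULL
    mm <- NULL
    poolIdx <- integer(0)
    if (length(r1) == 0) {
      e1Status <- "untestable: no exposed units"
    } else {
      poolMask <- !(person %in% person[exU])
      poolIdx <- uIdx[poolMask]
      if (length(poolIdx) < 2 || length(exU) < 2) {
        e1Status <- "untestable: insufficient background pool"
      }
    }
    if (is.null(e1Status)) {
      exYear <- yearOfNum(exD)
      exBin <- (exYear - birth[exU]) %/% params@ageBinYears
      # propensity features: exposed at own index date, pool at the median
      # exposed index date (prefix of the date-sorted triplets)
      refPool <- stats::median(exD)
      pos <- findInterval(refPool - 0.5, fDateSorted)
      rowOf <- integer(nU)
      nEx <- length(exU)
      rowOf[exU] <- seq_len(nEx)
      rowOf[poolIdx] <- nEx + seq_along(poolIdx)
      nAll <- nEx + length(poolIdx)
      if (pos > 0) {
        sl <- seq_len(pos)
        keep <- poolMask[fUnitSorted[sl]]
        ti <- rowOf[fUnitSorted[sl][keep]]
        tj <- fJSorted[sl][keep]
      } else {
        ti <- integer(0); tj <- integer(0)
      }
      # exposed rows: per-unit prefix by own index date
      exI <- vector("list", nEx)
      exNprior <- integer(nEx)
      for (ii in seq_len(nEx)) {
        u <- exU[ii]
        p2 <- findInterval(exD[ii] - 0.5, fByUnitD[[u]])
        exNprior[ii] <- p2
        if (p2 > 0) {
          jj <- fByUnitJ[[u]][seq_len(p2)]
          exI[[ii]] <- jj[!is.na(jj)]
        }
      }
      exLen <- lengths(exI)
      ti <- c(rep.int(seq_len(nEx), exLen), ti)
      tj <- c(unlist(exI[exLen > 0], use.names = FALSE), tj)
      # prior-event counts: pool via date prefix, exposed from its loop
      posE <- findInterval(refPool - 0.5, eDateSorted)
      priorAll <- if (posE > 0) {
        tabulate(eUnitSorted[seq_len(posE)], nbins = nU)
      } else {
        numeric(nU)
      }
      priorN <- numeric(nAll)
      priorN[rowOf[poolIdx]] <- priorAll[poolIdx]
      priorN[seq_len(nEx)] <- exNprior
      x <- Matrix::sparseMatrix(
        i = c(ti, seq_len(nAll)), j = c(tj, rep.int(K + 1L, nAll)),
        x = c(rep.int(1, length(ti)), priorN), dims = c(nAll, K + 1L))
      y <- c(rep(1L, nEx), rep(0L, length(poolIdx)))
      ps <- tryCatch(computePropensity(x, y), error = function(e) NULL)
      if (is.null(ps)) {
        e1Status <- "untestable: propensity model could not be fit"
      } else {
        mm <- matchUnits(
          exPs = ps[seq_len(nEx)], exPerson = person[exU],
          exGender = gender[exU], exBin = exBin, exYear = exYear,
          exDate = exD,
          poolPs = ps[nEx + seq_along(poolIdx)],
          poolPerson = person[poolIdx], poolGender = gender[poolIdx],
          poolBirth = birth[poolIdx], poolWs = ws[poolIdx],
          poolWe = we[poolIdx],
          ageBin = params@ageBinYears,
          ratio = as.integer(params@matchRatio))
        out$n_unmatched_exposed[rowsI] <- mm$nUnmatched
        if (length(mm$exSel) == 0) {
          e1Status <- "untestable: no exposed unit could be matched"
        }
      }
    }

    # --- per-E2 work: direction counts, outcome ascertainment, tests ------
    for (i in rowsI) {
      e2 <- pairs$e2[i]
      r2 <- byConcept[[as.character(e2)]]
      e2U <- sUnit[r2]
      e2D <- sDate[r2]
      if (length(r1)) {
        m12 <- match(exU, e2U)
        hit <- which(!is.na(m12))
        dgap <- e2D[m12[hit]] - exD[hit]
        out$n_e1_first[i] <- sum(dgap >= params@minGapDays)
        out$n_e2_first[i] <- sum(-dgap >= params@minGapDays)
      }
      if (!is.null(e1Status)) {
        status[i] <- e1Status
        next
      }
      e2dScratch[e2U] <- e2D
      gExp <- e2dScratch[exU[mm$exSel]] - exD[mm$exSel]
      kExp <- sum(!is.na(gExp) & gExp >= gapLo & gExp <= gapHi)
      gBg <- e2dScratch[poolIdx[mm$bgSel]] - mm$bgIndex
      kBg <- sum(!is.na(gBg) & gBg >= gapLo & gBg <= gapHi)
      e2dScratch[e2U] <- NA_real_
      nExp <- length(mm$exSel)
      nBg <- length(mm$bgSel)

      rrFit <- relativeRisk(kExp, nExp, kBg, nBg)
      out$n_exposed[i] <- nExp
      out$n_background[i] <- nBg
      out$k_exposed_e2[i] <- kExp
      out$k_background_e2[i] <- kBg
      out$rr[i] <- rrFit$rr
      out$rr_ci_low[i] <- rrFit$ci_low
      out$rr_ci_high[i] <- rrFit$ci_high
      out$fisher_p[i] <- fisherAssociation(kExp, nExp, kBg, nBg)
      nOrd <- out$n_e1_first[i] + out$n_e2_first[i]
      out$binom_p[i] <- if (nOrd > 0) {
        binomialDirection(out$n_e1_first[i], out$n_e2_first[i])
      } else {
        NA_real_
      }
      done <- done + 1L
      if (verbose && done %% 1000 == 0) {
        ctLog(verbose, sprintf("tested %d/%d pairs", done, nP))
      }
    }
  }

  tab <- data.frame(
    e1 = pairs$e1, e2 = pairs$e2,
    e1_name = if ("e1_name" %in% names(pairs)) pairs$e1_name else NA,
    e2_name = if ("e2_name" %in% names(pairs)) pairs$e2_name else NA,
    n_pair = if ("n_pair" %in% names(pairs)) pairs$n_pair else NA_integer_,
    stringsAsFactors = FALSE)
  for (nmCol in names(out)) tab[[nmCol]] <- out[[nmCol]]
  tab$status <- status
  if (nrow(tab)) {
    tab$fisher_p_adj <- adjustPvalues(tab$fisher_p, params@correction)
    tab$binom_p_adj <- adjustPvalues(tab$binom_p, params@correction)
    tab <- classifyPairs(tab, params)
  } else {
    tab$fisher_p_adj <- numeric(0)
    tab$binom_p_adj <- numeric(0)
    tab$significant_assoc <- logical(0)
    tab$significant_direction <- logical(0)
  }
  new("PairResults", table = tab, params = params, nUnits = nU)
}

# greedy nearest-neighbor matching on plain vectors; the exported
# matchBackground() wraps this with data.frame bookkeeping
matchUnits <- function(exPs, exPerson, exGender, exBin, exYear, exDate,
                       poolPs, poolPerson, poolGender, poolBirth,
                       poolWs, poolWe, ageBin, ratio) {
  nEx <- length(exPs)
  ordEx <- order(exPerson, method = "radix")
  used <- logical(length(poolPs))
  exSel <- integer(0)
  bgSel <- integer(0)
  bgIndex <- numeric(0)
  nUnmatched <- 0L
  keyAll <- paste(exGender, exBin, exYear)
  for (key in unique(keyAll[ordEx])) {
    rows <- ordEx[keyAll[ordEx] == key]
    g <- exGender[rows[1L]]
    ab <- exBin[rows[1L]]
    iy <- exYear[rows[1L]]
    cand <- which(poolGender == g &
                    ((iy - poolBirth) %/% ageBin) == ab)
    for (ei in rows) {
      idate <- exDate[ei]
      elig <- cand[!used[cand] & poolWs[cand] <= idate &
                     poolWe[cand] >= idate]
      if (length(elig) < ratio) {
        nUnmatched <- nUnmatched + 1L
        next
      }
      o <- order(abs(poolPs[elig] - exPs[ei]), poolPerson[elig],
                 elig, method = "radix")
      pick <- elig[o[seq_len(ratio)]]
      used[pick] <- TRUE
      exSel <- c(exSel, ei)
      bgSel <- c(bgSel, pick)
      bgIndex <- c(bgIndex, rep(idate, ratio))
    }
  }
  list(exSel = exSel, bgSel = bgSel, bgIndex = bgIndex,
       nUnmatched = nUnmatched)
}
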
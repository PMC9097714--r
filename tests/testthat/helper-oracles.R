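# Independent oracles and fixture builders, deliberately naive: direct
# enumeration and double loops, no shared code with the implementation.

# two-sided Fisher p by full hypergeometric enumeration
# (probability-mass rule; tiny relative tolerance for floating-point ties,
# the standard exact-test convention)
oracleFisherP <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  N <- n1 + n2
  supp <- max(0, m - n2):min(n1, m)
  dens <- stats::dhyper(supp, m, N - m, n1)
  dobs <- stats::dhyper(k1, m, N - m, n1)
  sum(dens[dens <= dobs * (1 + 1e-7)])
}

# two-sided binomial p at p = 0.5 by closed-form tail sums
oracleBinomP <- function(a, b) {
  n <- a + b
  dens <- stats::dbinom(0:n, n, 0.5)
  sum(dens[dens <= dens[a + 1] * (1 + 1e-7)])
}

# brute-force ordered pair counting over a list of sequences; each sequence
# is a data.frame with columns concept, day (first occurrences)
oraclePairCounts <- function(seqList, minGap, maxGap) {
  acc <- list()
  for (sq in seqList) {
    for (i in seq_len(nrow(sq))) {
      for (jj in seq_len(nrow(sq))) {
        if (i == jj) next
        gap <- sq$day[jj] - sq$day[i]
        if (gap >= minGap && gap <= maxGap) {
          key <- paste(sq$concept[i], sq$concept[jj])
          acc[[key]] <- (acc[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  acc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force trajectory realization count over sequence list
oracleTrajCount <- function(seqList, concepts, minGap, maxGap) {
  n <- 0L
  for (sq in seqList) {
    days <- sq$day[match(concepts, sq$concept)]
    if (anyNA(days)) next
    gaps <- diff(days)
    if (all(gaps >= minGap & gaps <= maxGap)) n <- n + 1L
  }
  n
}

# build an EventCohort from a compact list of sequences:
#   list(p1 = data.frame(concept = c(1, 2), day = c(0, 10)), ...)
# days are offsets from 2015-01-01; demographics configurable per person
toyCohort <- function(seqList, gender = NULL, birthYear = NULL,
                      obsStart = as.Date("2010-01-01"),
                      obsEnd = as.Date("2019-12-31")) {
  ids <- names(seqList)
  if (is.null(ids)) ids <- sprintf("p%02d", seq_along(seqList))
  if (is.null(gender)) gender <- rep("female", length(ids))
  if (is.null(birthYear)) birthYear <- rep(1960L, length(ids))
  persons <- data.frame(person_id = ids, gender = gender,
                        birth_year = birthYear,
                        obs_start = obsStart, obs_end = obsEnd,
                        stringsAsFactors = FALSE)
  evs <- do.call(rbind, lapply(seq_along(seqList), function(i) {
    sq <- seqList[[i]]
    if (nrow(sq) == 0) return(NULL)
    data.frame(person_id = ids[i],
               concept_id = as.integer(sq$concept),
               concept_name = paste0("c", sq$concept),
               domain = "condition",
               event_date = as.Date("2015-01-01") + sq$day,
               stringsAsFactors = FALSE)
  }))
  if (is.null(evs)) {
    evs <- data.frame(person_id = character(), concept_id = integer(),
                      concept_name = character(), domain = character(),
                      event_date = as.Date(character()),
                      stringsAsFactors = FALSE)
  }
  firstOccurrences(applyCohort(evs, persons, verbose = FALSE))
}

# write person/event fixture files for the IO tests
writePersonFile <- function(df, path) {
  names(df) <- c("person_id", "gender_concept", "year_of_birth",
                 "observation_period_start_date",
                 "observation_period_end_date")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

randomSeqList <- function(nUnits, nConcepts, maxEvents, seed) {
  set.seed(seed)
  lapply(seq_len(nUnits), function(i) {
    k <- sample.int(maxEvents, 1)
    concepts <- sample.int(nConcepts, min(k, nConcepts))
    data.frame(concept = concepts,
               day = sort(sample.int(1500, length(concepts))))
  })
}
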
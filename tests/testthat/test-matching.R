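mkExposed <- function(ids, ps, gender = "female", ageBin = 10L,
                      year = 2015L) {
  data.frame(unit_id = ids, person_id = ids,
             index_date = as.Date("2015-06-01"),
             gender = gender, age_at_index = ageBin * 5 + 2,
             index_year = year, age_bin = ageBin, ps = ps,
             stringsAsFactors = FALSE)
}

mkPool <- function(ids, ps, gender = "female", birthYear = 1963L) {
  data.frame(unit_id = ids, person_id = ids, gender = gender,
             birth_year = birthYear,
             window_start = as.Date("2010-01-01"),
             window_end = as.Date("2019-12-31"), ps = ps,
             stringsAsFactors = FALSE)
}

test_that("exposed group construction sets index date and age", {
  co <- toyCohort(list(p1 = data.frame(concept = c(5, 1), day = c(0, 10)),
                       p2 = data.frame(concept = 5, day = 100),
                       p3 = data.frame(concept = c(2, 5), day = c(0, 50)),
                       p4 = data.frame(concept = 2, day = 3)),
                  birthYear = rep(1960L, 4))
  ex <- buildExposed(5, co, studyParams())
  expect_equal(nrow(ex), 3)
  expect_setequal(ex$person_id, c("p1", "p2", "p3"))
  # index date is the first E1 date; age = index year - birth year
  expect_equal(ex$index_date[ex$person_id == "p2"],
               as.Date("2015-01-01") + 100)
  expect_true(all(ex$age_at_index == 2015 - 1960))
  expect_true(all(ex$age_bin == 55 %/% 5))
})

test_that("an event on the first day of observation is a valid index", {
  co <- toyCohort(list(p1 = data.frame(concept = 9, day = 0)),
                  obsStart = as.Date("2015-01-01"))
  ex <- buildExposed(9, co)
  expect_equal(ex$index_date, as.Date("2015-01-01"))
})

test_that("propensity scores are probabilities with sane behaviour", {
  # identical features for everyone -> identical scores
  x <- matrix(1, nrow = 20, ncol = 3)
  ps <- computePropensity(x, rep(c(0, 1), 10))
  expect_true(all(abs(ps - ps[1]) < 1e-10))

  # a perfectly separating feature under ridge: finite scores, exposed above
  y <- rep(c(0, 1), each = 25)
  x <- cbind(sep = y, noise = 0)
  ps <- computePropensity(x, y)
  expect_true(all(is.finite(ps)))
  expect_true(min(ps[y == 1]) > max(ps[y == 0]))

  # random features: scores strictly inside (0, 1)
  set.seed(1)
  x <- matrix(rnorm(200 * 5), 200)
  y <- rbinom(200, 1, 0.3)
  ps <- computePropensity(x, y)
  expect_true(all(ps > 0 & ps < 1))

  # degenerate single-class input
  expect_error(computePropensity(matrix(rnorm(20), 10), rep(1, 10)),
               "cannot fit propensity model")
})

test_that("matching is exact on covariates with nearest-neighbor scores", {
  pars <- studyParams()
  # one exposed, exactly one exact-stratum candidate -> matched 1:1
  mm <- matchBackground(mkExposed("e1", 0.5), mkPool("b1", 0.9), pars)
  expect_equal(mm$matches$bg_unit_id, "b1")
  expect_equal(mm$nUnmatchedExposed, 0)
  # assigned index date is the exposed unit's index date
  expect_equal(mm$matches$index_date, as.Date("2015-06-01"))

  # only a different-gender candidate -> unmatched
  mm <- matchBackground(mkExposed("e1", 0.5),
                        mkPool("b1", 0.5, gender = "male"), pars)
  expect_equal(mm$nUnmatchedExposed, 1)
  expect_equal(length(mm$matchedExposed), 0)

  # nearest neighbor: scores 0.40 and 0.41 against exposed 0.39 -> 0.40
  mm <- matchBackground(mkExposed("e1", 0.39),
                        mkPool(c("b1", "b2"), c(0.41, 0.40)), pars)
  expect_equal(mm$matches$bg_unit_id, "b2")

  # score tie broken by the lower person id
  mm <- matchBackground(mkExposed("e1", 0.39),
                        mkPool(c("b2", "b1"), c(0.40, 0.40)), pars)
  expect_equal(mm$matches$bg_unit_id, "b1")

  # without replacement: two exposed cannot share one candidate
  mm <- matchBackground(mkExposed(c("e1", "e2"), c(0.5, 0.5)),
                        mkPool("b1", 0.5), pars)
  expect_equal(nrow(mm$matches), 1)
  expect_equal(mm$nUnmatchedExposed, 1)

  # a candidate not under observation at the index date is ineligible
  pool <- mkPool("b1", 0.5)
  pool$window_end <- as.Date("2015-01-01")
  mm <- matchBackground(mkExposed("e1", 0.5), pool, pars)
  expect_equal(mm$nUnmatchedExposed, 1)

  expect_error(matchBackground(mkExposed("e1", 0.5), mkPool("b1", 0.5)[0, ],
                               pars), "empty background pool")
})

test_that("matched groups are exactly balanced and uncontaminated", {
  # synthetic cohort with a planted exposure; run the full per-pair test
  tabs <- generateRandomEvents(nPersons = 300, eventsPerPerson = c(1, 8),
                               nConcepts = 30, seed = 31)
  tabs <- injectPair(tabs, 9001L, 9002L, nCarriers = 60, pE2GivenE1 = 0.5,
                     pE2Baseline = 0.2, seed = 32)
  co <- cohortFromTables(tabs)
  pars <- studyParams(seed = 31)
  ex <- buildExposed(9001L, co, pars)
  units <- cohortUnits(co)
  pool <- units[!units$person_id %in% ex$person_id, ]
  set.seed(33)
  ex$ps <- runif(nrow(ex))
  pool$ps <- runif(nrow(pool))
  mm <- matchBackground(ex, pool, pars)

  # no person in both groups, nobody used twice
  expect_length(intersect(mm$matches$bg_unit_id, ex$unit_id), 0)
  expect_equal(anyDuplicated(mm$matches$bg_unit_id), 0)

  # exact balance of the (gender, age bin, index year) joint distribution
  exM <- ex[ex$unit_id %in% mm$matchedExposed, ]
  bgIdx <- match(mm$matches$bg_unit_id, pool$unit_id)
  exStrata <- table(paste(exM$gender, exM$age_bin, exM$index_year))
  iy <- as.integer(format(mm$matches$index_date, "%Y"))
  bgStrata <- table(paste(pool$gender[bgIdx],
                          (iy - pool$birth_year[bgIdx]) %/% 5, iy))
  expect_equal(as.list(bgStrata), as.list(exStrata))

  # no contamination: no background member has E1 on or before its index
  s <- eventSequences(co)
  e1dates <- setNames(s$event_date[s$concept_id == 9001],
                      s$unit_id[s$concept_id == 9001])
  bgE1 <- e1dates[mm$matches$bg_unit_id]
  expect_true(all(is.na(bgE1) | bgE1 > mm$matches$index_date))
})

test_that("with exposure independent of covariates, matching preserves outcome prevalence", {
  # E2 planted uniformly at random; matched background prevalence should
  # track the population prevalence within binomial error
  set.seed(44)
  n <- 600
  persons <- data.frame(person_id = sprintf("q%03d", 1:n),
                        gender = sample(c("male", "female"), n, TRUE),
                        birth_year = sample(1940:1995, n, TRUE),
                        obs_start = as.Date("2010-01-01"),
                        obs_end = as.Date("2019-12-31"))
  exposedIds <- sample(persons$person_id, 150)
  hasE2 <- runif(n) < 0.3
  events <- rbind(
    data.frame(person_id = exposedIds, concept_id = 1L, concept_name = "E1",
               domain = "condition", event_date = as.Date("2012-06-01")),
    data.frame(person_id = persons$person_id[hasE2], concept_id = 2L,
               concept_name = "E2", domain = "condition",
               event_date = as.Date("2015-06-01")))
  co <- firstOccurrences(applyCohort(events, persons, verbose = FALSE))
  res <- resultsTable(testPairs(co, data.frame(e1 = 1L, e2 = 2L),
                                studyParams(seed = 44)))
  expect_equal(res$status, "tested")
  bgPrev <- res$k_background_e2 / res$n_background
  expect_lt(abs(bgPrev - 0.3), 3 * sqrt(0.3 * 0.7 / res$n_background))
})
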
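test_that("person table reading validates schema, dates and invariants", {
  tmp <- withr::local_tempdir()
  good <- data.frame(id = c("a", "b", "c"),
                     g = c("female", "male", "unknown"),
                     y = c(1950, 1960, 1970),
                     s = c("2010-01-01", "2011-02-03", "2012-03-04"),
                     e = c("2018-01-01", "2019-02-03", "2019-12-31"))
  p <- readPersonTable(writePersonFile(good, file.path(tmp, "p.tsv")))
  expect_equal(nrow(p), 3)
  expect_s3_class(p$obs_start, "Date")
  expect_identical(p$gender, c("female", "male", "unknown"))

  # reversed window on row 2 is reported by row number
  bad <- good
  bad$e[2] <- "2010-01-01"
  f <- writePersonFile(bad, file.path(tmp, "bad.tsv"))
  expect_error(readPersonTable(f), "row\\(s\\) 2")

  # header-only file yields an empty collection
  empty <- good[0, ]
  expect_equal(nrow(readPersonTable(
    writePersonFile(empty, file.path(tmp, "empty.tsv")))), 0)

  # missing column is a schema error
  noCol <- good[, -2]
  write.table(setNames(noCol, c("person_id", "year_of_birth",
                                "observation_period_start_date",
                                "observation_period_end_date")),
              file.path(tmp, "nocol.tsv"), sep = "\t", row.names = FALSE)
  expect_error(readPersonTable(file.path(tmp, "nocol.tsv")),
               "missing required column")

  # unparseable date aborts with the row count
  badDate <- good
  badDate$s[3] <- "not-a-date"
  f <- writePersonFile(badDate, file.path(tmp, "baddate.tsv"))
  expect_error(readPersonTable(f), "unparseable date")

  # duplicate ids and birth year after observation start are rejected
  dup <- good; dup$id[2] <- "a"
  expect_error(readPersonTable(writePersonFile(dup, file.path(tmp, "d.tsv"))),
               "duplicate person_id")
  late <- good; late$y[1] <- 2015
  expect_error(readPersonTable(writePersonFile(late, file.path(tmp, "l.tsv"))),
               "year_of_birth after")
})

test_that("event table filtering by domain and observation window is counted", {
  tmp <- withr::local_tempdir()
  persons <- readPersonTable(writePersonFile(
    data.frame(id = "a", g = "female", y = 1950,
               s = "2010-01-01", e = "2015-01-01"),
    file.path(tmp, "p.tsv")))
  ev <- data.frame(
    person_id = "a",
    concept_id = 1:10,
    concept_name = paste0("c", 1:10),
    domain = c(rep("drug_era", 4), rep("condition", 6)),
    event_date = c(rep("2012-01-01", 9), "2016-01-01"))
  write.table(ev, file.path(tmp, "e.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # domain filter: 4 of 10 rows are drug eras
  out <- readEventTable(file.path(tmp, "e.tsv"),
                        includedDomains = "condition", verbose = FALSE)
  expect_equal(nrow(out), 6)

  # all four domains: everything kept
  out <- readEventTable(file.path(tmp, "e.tsv"), verbose = FALSE)
  expect_equal(nrow(out), 10)

  # with the person table, the event after obs_end is dropped and counted
  expect_message(
    out <- readEventTable(file.path(tmp, "e.tsv"), persons = persons),
    "dropped 1 event")
  expect_equal(nrow(out), 9)
  att <- attr(out, "attrition")
  expect_true(all(att$n_in == att$n_kept + att$n_dropped))

  # unknown domain value is a row-level error
  bad <- ev; bad$domain[3] <- "visit"
  write.table(bad, file.path(tmp, "bad.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(readEventTable(file.path(tmp, "bad.tsv"), verbose = FALSE),
               "unknown domain at row\\(s\\) 3")

  # a domain outside the allowed set cannot be requested
  expect_error(readEventTable(file.path(tmp, "e.tsv"),
                              includedDomains = c("condition", "visit")),
               "outside the allowed set")
})

test_that("cohort restriction keeps events in windows and builds per-window units", {
  persons <- data.frame(person_id = c("a", "b"), gender = "female",
                        birth_year = 1950L,
                        obs_start = as.Date("2010-01-01"),
                        obs_end = as.Date("2019-12-31"))
  events <- data.frame(
    person_id = "a", concept_id = 1:4, concept_name = paste0("c", 1:4),
    domain = "condition",
    event_date = as.Date(c("2011-01-01", "2012-01-01", "2015-06-01",
                           "2016-01-01")))

  # whole-database mode: identity on events
  ap <- applyCohort(events, persons, verbose = FALSE)
  expect_equal(nrow(ap$events), 4)
  expect_equal(nrow(ap$units), 2)
  expect_identical(ap$units$unit_id, persons$person_id)

  # window covering events 1-2 only
  co <- data.frame(person_id = "a",
                   entry_date = as.Date("2010-06-01"),
                   exit_date = as.Date("2012-06-01"))
  ap <- applyCohort(events, persons, co, verbose = FALSE)
  expect_equal(nrow(ap$units), 1)
  expect_equal(sort(ap$events$concept_id), 1:2)

  # two windows -> two independent sequence units
  co2 <- data.frame(person_id = c("a", "a"),
                    entry_date = as.Date(c("2010-06-01", "2015-01-01")),
                    exit_date = as.Date(c("2012-06-01", "2015-12-31")))
  ap <- applyCohort(events, persons, co2, verbose = FALSE)
  expect_equal(ap$units$unit_id, c("a#1", "a#2"))
  expect_equal(ap$events$unit_id[ap$events$concept_id == 3], "a#2")
  # attrition accounts for the dropped event (concept 4 in no window)
  expect_equal(sum(ap$events$concept_id == 4), 0)
  expect_true(all(ap$attrition$n_in == ap$attrition$n_kept +
                    ap$attrition$n_dropped))

  # unknown cohort person is an error listing the id
  bad <- data.frame(person_id = "zz",
                    entry_date = as.Date("2010-01-01"),
                    exit_date = as.Date("2011-01-01"))
  expect_error(applyCohort(events, persons, bad), "zz")
})
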
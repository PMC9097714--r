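mkResults <- function(df, pars = studyParams()) {
  # minimal PairResults stand-in via the real classifier
  df$fisher_p_adj <- df$fisher_p_adj %||% 0.001
  df$binom_p_adj <- df$binom_p_adj %||% 0.001
  df$rr <- df$rr %||% 3
  df$n_e1_first <- df$n_e1_first %||% 30L
  df$n_e2_first <- df$n_e2_first %||% 2L
  tab <- classifyPairs(df, pars)
  new("PairResults", table = tab, params = pars, nUnits = 100)
}

test_that("graph building keeps only significant directional pairs", {
  co <- toyCohort(list(p1 = data.frame(concept = c(1, 2, 3),
                                       day = c(0, 10, 20))))
  df <- data.frame(e1 = c(1L, 2L), e2 = c(2L, 3L), n_pair = c(50L, 40L))
  g <- buildTrajectoryGraph(mkResults(df), co)
  expect_equal(nrow(graphNodes(g)), 3)
  expect_equal(nrow(graphEdges(g)), 2)
  expect_equal(graphNodes(g)$n_units, c(1L, 1L, 1L))

  # an associated but non-directional pair contributes no edge
  df2 <- df
  df2$binom_p_adj <- c(0.001, 0.9)
  g2 <- buildTrajectoryGraph(mkResults(df2), co)
  expect_equal(graphEdges(g2)$e1, 1L)

  # no directional pairs -> empty graph
  df3 <- df; df3$fisher_p_adj <- 0.9
  g3 <- buildTrajectoryGraph(mkResults(df3), co)
  expect_equal(nrow(graphEdges(g3)), 0)
  expect_equal(length(composeTrajectories(g3)), 0)
})

test_that("trajectory composition enumerates simple paths only", {
  co <- toyCohort(list(p1 = data.frame(concept = c(1, 2, 3),
                                       day = c(0, 10, 20))))
  g <- buildTrajectoryGraph(mkResults(
    data.frame(e1 = c(1L, 2L), e2 = c(2L, 3L), n_pair = 50L)), co)
  paths <- composeTrajectories(g, maxLen = 3)
  expect_equal(paths, list(c(1L, 2L), c(1L, 2L, 3L), c(2L, 3L)))

  # a 2-cycle yields the two edges but never A->B->A
  gc <- buildTrajectoryGraph(mkResults(
    data.frame(e1 = c(1L, 2L), e2 = c(2L, 1L), n_pair = 50L)), co)
  paths <- composeTrajectories(gc, maxLen = 3)
  expect_equal(paths, list(c(1L, 2L), c(2L, 1L)))
})

test_that("trajectory counting allows intermediates and enforces gaps", {
  pars <- studyParams(minGapDays = 1, maxGapDays = 365)
  co <- toyCohort(list(
    p1 = data.frame(concept = c(1, 99, 2, 3), day = c(0, 5, 10, 30)),
    p2 = data.frame(concept = c(1, 3, 2), day = c(0, 10, 20)),
    p3 = data.frame(concept = c(1, 2, 3), day = c(0, 400, 420))))
  # p1 realizes 1->2->3 despite the intermediate 99
  # p2 has 3 before 2; p3 violates the 365-day adjacent gap
  expect_equal(countTrajectory(c(1L, 2L, 3L), co, pars), 1L)
  # with an unbounded gap p3 also counts
  expect_equal(countTrajectory(c(1L, 2L, 3L), co,
                               studyParams(maxGapDays = Inf)), 2L)
})

test_that("trajectory counts match brute force and are anti-monotone", {
  for (seed in c(2, 9)) {
    seqList <- randomSeqList(nUnits = 50, nConcepts = 6, maxEvents = 6,
                             seed = seed)
    co <- toyCohort(seqList)
    pars <- studyParams(minGapDays = 1, maxGapDays = 700)
    concepts <- 1:6
    for (len in 2:3) {
      set.seed(seed + len)
      for (rep in 1:10) {
        traj <- sample(concepts, len)
        got <- countTrajectory(traj, co, pars)
        expect_equal(got, oracleTrajCount(seqList, traj, 1, 700),
                     info = paste(traj, collapse = "->"))
        # every contiguous sub-trajectory counts at least as many units
        if (len > 2) {
          for (st in 1:(len - 1)) {
            sub <- traj[st:(st + 1)]
            expect_gte(countTrajectory(sub, co, pars), got)
          }
        }
      }
    }
  }
})

test_that("ranking sorts by count then lexicographic concept order", {
  counts <- data.frame(trajectory = c("a->b", "a->c", "b->c"),
                       length = 2L, n_patients = c(50L, 70L, 50L))
  counts$concepts <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  r <- rankTrajectories(counts)
  expect_equal(r$n_patients, c(70L, 50L, 50L))
  expect_equal(r$concepts[[2]], c(1L, 2L))  # tie broken lexicographically
  # prefix filter
  r2 <- rankTrajectories(counts, prefix = c(1L))
  expect_equal(nrow(r2), 2)
  r3 <- rankTrajectories(counts, prefix = c(1L, 2L))
  expect_equal(r3$concepts[[1]], c(1L, 2L))
})

test_that("graph export writes readable GraphML and DOT", {
  co <- toyCohort(list(p1 = data.frame(concept = c(1, 2), day = c(0, 10))))
  g <- buildTrajectoryGraph(mkResults(
    data.frame(e1 = 1L, e2 = 2L, n_pair = 30L)), co)
  tmp <- withr::local_tempdir()
  gml <- file.path(tmp, "g.graphml")
  dot <- file.path(tmp, "g.dot")
  exportGraph(g, gml, "graphml")
  exportGraph(g, dot, "dot")
  expect_true(file.exists(gml) && file.exists(dot))
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(back), 2)
  expect_equal(igraph::gsize(back), 1)
  expect_equal(sort(igraph::edge_attr(back, "rr")), 3)
})
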
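test_that("candidate edges follow the weight formula and orientation rule", {
  ## p_i = 1, p_j = 0.05 (20 samples): w = 0.05/1.05
  x <- cbind(Ei = rep(1, 20), Ej = c(1, rep(0, 19)))
  built <- buildCompleteGraph(estimateEventStats(CooccurrenceMatrix(x)))
  expect_equal(nrow(built$candidates), 1)
  expect_equal(built$candidates$source, "Ei")
  expect_equal(built$candidates$weight, 0.05 / 1.05, tolerance = 1e-12)
  expect_equal(built$candidates$cond_prob, 0.05)
  ## identical columns: an undirected tie, no directed candidate
  same <- CooccurrenceMatrix(cbind(A = c(1, 0, 1), B = c(1, 0, 1)))
  bt <- buildCompleteGraph(estimateEventStats(same))
  expect_equal(nrow(bt$candidates), 0)
  expect_equal(nrow(bt$ties), 1)
  ## disjoint columns: no candidate in either direction
  disj <- CooccurrenceMatrix(cbind(A = c(1, 1, 0), B = c(0, 0, 1)))
  bd <- buildCompleteGraph(estimateEventStats(disj))
  expect_equal(nrow(bd$candidates), 0)
  expect_equal(nrow(bd$ties), 0)
})

test_that("edge construction agrees with the brute-force oracle on small matrices", {
  for (seed in 1:20) {
    nE <- 3 + seed %% 4
    m <- randomBinaryMatrix(8, nE, 0.5, seed = seed, exact = FALSE)
    st <- estimateEventStats(m)
    got <- filterEdges(buildCompleteGraph(st)$candidates, st)
    got <- got[order(got$source, got$target),
               c("source", "target", "weight", "cond_prob")]
    rownames(got) <- NULL
    want <- bruteForceEdges(m)
    rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("confidence intervals match the closed forms", {
  ci <- confidenceInterval(0.5, 100, 0.95, "wilson")
  expect_equal(unname(ci[1, ]), c(0.404, 0.596), tolerance = 1e-3)
  ## symmetry about one half
  expect_equal(unname(ci[1, "p_min"]), unname(1 - ci[1, "p_max"]),
               tolerance = 1e-12)
  ## literal variant is degenerate at gamma = 0.95: half-width sqrt(1.645)
  cl <- confidenceInterval(0.5, 100, 0.95, "literal")
  expect_equal(unname(cl[1, ]), c(0, 1))
  expect_true(all(confidenceInterval(c(0, .2, .9), 10)[, "p_min"] <=
                    confidenceInterval(c(0, .2, .9), 10)[, "p_max"]))
})

test_that("the literal ci_sum filter empties the worked-example graph", {
  st <- estimateEventStats(stepwiseFill(20, 18))
  cand <- buildCompleteGraph(st)$candidates
  expect_equal(nrow(cand), 19)
  basic <- filterEdges(cand, st, todagConfig(filterMode = "basic"))
  expect_equal(nrow(basic), 19)
  cisum <- filterEdges(cand, st, todagConfig(filterMode = "ci_sum"))
  expect_equal(nrow(cisum), 0)
  ## the variants are nested restrictions of the basic candidate set
  ciprod <- filterEdges(cand, st, todagConfig(filterMode = "ci_product"))
  expect_true(nrow(ciprod) <= nrow(basic))
})

test_that("path probabilities reduce to the pairwise joint for single edges", {
  m <- CooccurrenceMatrix(cbind(E1 = c(1, 1, 0), E2 = c(1, 0, 0)))
  g <- inferTodag(m, seed = 1)
  expect_equal(graphEdges(g)$path_joint, 1 / 3)
})

test_that("nested chains propagate the smallest event probability along paths", {
  tri <- triangularMatrix(3)
  g <- inferTodag(tri, seed = 1)
  e <- graphEdges(g)
  p3 <- 1 / 3
  expect_equal(e$path_joint[e$source == "E2" & e$target == "E3"], p3)
})

test_that("a path through events with empty triple intersection gets joint zero", {
  x <- cbind(E1 = c(1, 1, 0, 1), E2 = c(0, 1, 1, 0), E3 = c(0, 0, 1, 0))
  g <- inferTodag(CooccurrenceMatrix(x), seed = 1)
  e <- graphEdges(g)
  expect_setequal(paste(e$source, e$target),
                  c("E1 E2", "E2 E3"))
  expect_equal(e$path_joint[e$source == "E2"], 0)
})

test_that("literal path pruning removes chains dominated by the conditional sum", {
  ## nested supports 100 > 90 > 81: conditionals 0.9 and 0.9 along the chain
  x <- cbind(E1 = rep(1, 100),
             E2 = c(rep(1, 90), rep(0, 10)),
             E3 = c(rep(1, 81), rep(0, 19)))
  m <- CooccurrenceMatrix(x)
  g0 <- inferTodag(m, seed = 1)
  expect_equal(nrow(graphEdges(g0)), 3)  # prune off: identical graph
  gp <- inferTodag(m, config = todagConfig(pathPrune = "literal"), seed = 1)
  ep <- graphEdges(gp)
  ## single-edge root paths compare joint c against sum c: retained;
  ## the chain's terminal edge fails 0.81 < 0.9 + 0.9 and is removed
  expect_setequal(paste(ep$source, ep$target), c("E1 E2", "E1 E3"))
})

test_that("inference is deterministic and acyclic across random inputs", {
  for (seed in c(2, 9, 31)) {
    m <- randomBinaryMatrix(30, 15, 0.5, seed = seed, exact = FALSE)
    g1 <- suppressWarnings(inferTodag(m, seed = 99))
    g2 <- suppressWarnings(inferTodag(m, seed = 99))
    expect_identical(graphEdges(g1), graphEdges(g2))
    ig <- igraph::graph_from_data_frame(
      graphEdges(g1)[, c("source", "target")], directed = TRUE)
    expect_true(igraph::is_dag(ig))
    ## orientation invariant: sources strictly more frequent than targets
    expect_true(all(graphEdges(g1)$source_count >
                      graphEdges(g1)$target_count))
  }
})

test_that("a shared event bridges otherwise disjoint sub-networks as a root hub", {
  specs <- list(list(nSamples = 10, nEvents = 10),
                list(nSamples = 10, nEvents = 10))
  g <- suppressWarnings(inferTodag(sharedEventDataset(specs, 1), seed = 1))
  e <- graphEdges(g)
  expect_equal(sum(e$target == "E21"), 0)           # in-degree zero
  tgtBlock <- as.integer(sub("E", "", e$target[e$source == "E21"]))
  expect_true(any(tgtBlock <= 10) && any(tgtBlock > 10))  # both components
})

test_that("edge counts grow superlinearly with events and plateau with samples", {
  countEdges <- function(nS, nE, seeds)
    mean(vapply(seeds, function(s)
      nrow(graphEdges(inferRandom(nS, nE, 0.5, s))), numeric(1)))
  e40 <- countEdges(50, 40, 1:5)
  e80 <- countEdges(50, 80, 1:5)
  expect_gt(e80 / e40, 3)
  s200 <- countEdges(200, 50, 1:5)
  s800 <- countEdges(800, 50, 1:5)
  expect_lt(abs(s800 - s200) / s200, 0.25)
})

test_that("exact-frequency matrices yield only undirected ties, never directed edges", {
  ## every column has the same exact count, so all dependent pairs tie
  m <- randomBinaryMatrix(50, 12, 0.5, seed = 4, exact = TRUE)
  g <- suppressWarnings(inferTodag(m, seed = 4))
  expect_equal(nrow(graphEdges(g)), 0)
  expect_gt(nrow(graphTies(g)), 0)
})
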
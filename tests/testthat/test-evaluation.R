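test_that("midrank AUROC equals exhaustive Mann-Whitney comparison", {
  ## 4-node toy: gold {A->B, A->C}; inferred A->B=.9, B->A=.2, rest 0
  scores <- c(0.9, 0, 0.2, rep(0, 9))
  labels <- c(TRUE, TRUE, rep(FALSE, 10))
  expect_equal(todag:::.midrankAUROC(scores, labels),
               bruteForceAUROC(scores, labels))
  expect_equal(todag:::.midrankAUROC(scores, labels), 0.725)
  ## random score vectors
  withr::with_seed(5, {
    for (rep in 1:10) {
      s <- sample(c(0, runif(20)), 30, replace = TRUE)
      y <- seq_along(s) %in% sample(30, 8)
      expect_equal(todag:::.midrankAUROC(s, y), bruteForceAUROC(s, y))
    }
  })
  ## null: random scores give AUROC near one half on average
  null <- withr::with_seed(11, replicate(20, {
    s <- runif(200)
    y <- seq_along(s) %in% sample(200, 50)
    todag:::.midrankAUROC(s, y)
  }))
  expect_lt(abs(mean(null) - 0.5), 0.05)
})

test_that("edge-recovery AUROC matches brute force on whole small instances", {
  for (seed in 1:5) {
    apg <- assignProbabilities(generateAPG(7, 12, seed = seed),
                               seed = seed + 10)
    m <- suppressWarnings(sampleCooccurrence(apg, 60, seed = seed + 20))
    g <- suppressWarnings(inferTodag(m, seed = seed + 30))
    res <- edgeRecoveryAUROC(g, apg)
    ## rebuild the ordered-pair universe independently
    ids <- eventIDs(apg)
    e <- graphEdges(g)
    ge <- goldEdges(apg)
    scores <- labels <- c()
    for (i in ids) for (j in ids) {
      if (i == j) next
      w <- e$weight[e$source == i & e$target == j]
      scores <- c(scores, if (length(w)) w else 0)
      labels <- c(labels, any(ge$parent == i & ge$child == j))
    }
    expect_equal(auroc(res), bruteForceAUROC(scores, labels),
                 tolerance = 1e-12)
    expect_equal(res@nCandidatePairs, length(ids) * (length(ids) - 1L))
  }
})

test_that("AUROC is 1 for perfect recovery and invariant to monotone rescoring", {
  apg <- assignProbabilities(chainAPG(), rootProb = 1,
                             decayRange = c(0.8, 0.8), seed = 1)
  perfect <- makeTestGraph(c("E1", "E2", "E3"),
                           data.frame(source = c("E1", "E2"),
                                      target = c("E2", "E3"),
                                      weight = c(0.4, 0.7)))
  expect_equal(auroc(edgeRecoveryAUROC(perfect, apg)), 1)
  ## monotone transform of the scores leaves the ranking unchanged
  g <- suppressWarnings(
    inferTodag(sampleCooccurrence(apg, 50, seed = 2), seed = 3))
  a1 <- auroc(edgeRecoveryAUROC(g, apg))
  g@edges$weight <- g@edges$weight^3
  expect_equal(auroc(edgeRecoveryAUROC(g, apg)), a1)
  ## node-set mismatch is reported
  bad <- makeTestGraph(c("E1", "E2", "EX"),
                       data.frame(source = "E1", target = "E2",
                                  weight = 0.5))
  expect_error(edgeRecoveryAUROC(bad, apg), "node sets differ")
})

test_that("assortativity is the endpoint-degree correlation", {
  path4 <- makeTestGraph(LETTERS[1:4],
                         data.frame(source = c("A", "B", "C"),
                                    target = c("B", "C", "D"),
                                    weight = rep(.5, 3)))
  expect_equal(degreeAssortativity(path4), -0.5)
  ## two disjoint copies leave the value unchanged
  two <- makeTestGraph(c(LETTERS[1:4], paste0(LETTERS[1:4], "2")),
                       data.frame(source = c("A", "B", "C", "A2", "B2", "C2"),
                                  target = c("B", "C", "D", "B2", "C2", "D2"),
                                  weight = rep(.5, 6)))
  expect_equal(degreeAssortativity(two), -0.5)
  ## regular graphs are degenerate
  single <- makeTestGraph(c("A", "B"),
                          data.frame(source = "A", target = "B",
                                     weight = .5))
  expect_warning(val <- degreeAssortativity(single), "undefined")
  expect_true(is.na(val))
  ## agreement with igraph on a nontrivial inferred graph
  g <- inferRandom(40, 15, 0.4, seed = 13)
  ig <- igraph::as_undirected(
    igraph::graph_from_data_frame(graphEdges(g)[, c("source", "target")],
                                  directed = TRUE,
                                  vertices = eventIDs(g)),
    mode = "collapse")
  ## no pair carries both directions in a DAG, so collapse merges nothing
  expect_equal(igraph::ecount(ig), nrow(graphEdges(g)))
  expect_equal(degreeAssortativity(g),
               igraph::assortativity_degree(ig, directed = FALSE),
               tolerance = 1e-10)
})

test_that("transitivity matches exhaustive triple counting", {
  triangle <- makeTestGraph(c("A", "B", "C"),
                            data.frame(source = c("A", "A", "B"),
                                       target = c("B", "C", "C"),
                                       weight = rep(.5, 3)))
  tr <- graphTransitivity(triangle)
  expect_equal(tr$global, 1)
  expect_true(all(tr$local == 1))
  star <- makeTestGraph(c("A", "B", "C", "D"),
                        data.frame(source = rep("A", 3),
                                   target = c("B", "C", "D"),
                                   weight = rep(.5, 3)))
  trs <- graphTransitivity(star)
  expect_equal(trs$global, 0)
  expect_true(all(trs$local == 0))
  ## square with one diagonal, against the brute-force oracle
  sq <- makeTestGraph(c("A", "B", "C", "D"),
                      data.frame(source = c("A", "B", "A", "C", "A"),
                                 target = c("B", "C", "C", "D", "D"),
                                 weight = rep(.5, 5)))
  want <- bruteForceTransitivity(c("A", "B", "C", "D"),
                                 cbind(c("A", "B", "A", "C", "A"),
                                       c("B", "C", "C", "D", "D")))
  got <- graphTransitivity(sq)
  expect_equal(got$global, want$global)
  expect_equal(unname(got$local), unname(want$local))
})

test_that("HITS scores hit the known fixed points and the duality", {
  fan <- suppressWarnings(inferTodag(stepwiseFill(20, 18), seed = 1))
  sc <- hubAuthorityScores(fan)
  expect_true(all(sc$hub[paste0("E", 1:19)] == 1))
  expect_equal(unname(sc$hub["E20"]), 0)
  expect_equal(unname(sc$authority["E20"]), 1)
  single <- makeTestGraph(c("A", "B"),
                          data.frame(source = "A", target = "B",
                                     weight = .5))
  ss <- hubAuthorityScores(single)
  expect_equal(unname(ss$hub), c(1, 0))
  expect_equal(unname(ss$authority), c(0, 1))
  ## reversing the edges swaps the score vectors
  g <- inferRandom(30, 10, 0.5, seed = 21)
  fw <- hubAuthorityScores(g)
  rev <- g
  rev@edges[, c("source", "target")] <- g@edges[, c("target", "source")]
  rv <- hubAuthorityScores(rev)
  expect_equal(fw$hub, rv$authority, tolerance = 1e-6)
  expect_equal(fw$authority, rv$hub, tolerance = 1e-6)
  ## agreement with the igraph implementation
  ig <- igraph::graph_from_data_frame(graphEdges(g)[, c("source", "target")],
                                      directed = TRUE,
                                      vertices = eventIDs(g))
  ih <- igraph::hits_scores(ig)
  expect_equal(unname(fw$hub[names(ih$hub)]),
               unname(ih$hub / max(ih$hub)), tolerance = 1e-5)
})

test_that("degree/strength tables filter by weight threshold correctly", {
  g <- makeTestGraph(c("A", "B", "C", "D"),
                     data.frame(source = c("A", "A", "B"),
                                target = c("B", "C", "D"),
                                weight = c(0.9, 0.5, 0.3)))
  tab <- degreeStrengthTable(g, c(0, 0.4, 0.8))
  t0 <- tab[tab$threshold == 0, ]
  expect_equal(t0$out_degree[t0$event == "A"], 2)
  expect_equal(t0$out_strength[t0$event == "A"], 1.4)
  expect_equal(t0$in_strength[t0$event == "D"], 0.3)
  expect_true(is.na(t0$out_degree_strength_ratio[t0$event == "D"]))
  t4 <- tab[tab$threshold == 0.4, ]
  expect_equal(t4$out_degree[t4$event == "A"], 2)
  expect_equal(t4$in_degree[t4$event == "D"], 0)
  t8 <- tab[tab$threshold == 0.8, ]
  expect_equal(sum(t8$out_degree), 1)
  ## monotone in the threshold
  perNode <- split(tab$out_degree, tab$event)
  for (v in perNode) expect_true(all(diff(v) <= 0))
})

test_that("induced subgraphs follow the BFS neighborhood and weight filter", {
  g <- makeTestGraph(LETTERS[1:5],
                     data.frame(source = c("A", "B", "C", "D"),
                                target = c("B", "C", "D", "E"),
                                weight = c(0.9, 0.8, 0.7, 0.6)))
  expect_equal(eventIDs(inducedSubgraph(g, "C", order = 0)), "C")
  expect_equal(nrow(graphEdges(inducedSubgraph(g, "C", order = 0))), 0)
  one <- inducedSubgraph(g, "C", order = 1)
  expect_setequal(eventIDs(one), c("B", "C", "D"))
  expect_equal(nrow(graphEdges(one)), 2)
  all5 <- inducedSubgraph(g, "C", order = 10)
  expect_setequal(eventIDs(all5), LETTERS[1:5])
  filt <- inducedSubgraph(g, "C", order = 10, minWeight = 0.75)
  expect_equal(nrow(graphEdges(filt)), 2)
  expect_error(inducedSubgraph(g, "Z"), "unknown center")
})

test_that("the APG benchmark pipeline recovers structure well above chance", {
  b <- runBenchmark(10, 30, reps = 10, seed = 42)
  expect_gte(attr(b, "mean_auroc"), 0.7)
})

test_that("assortativity decreases and transitivity is hump-shaped in frequency", {
  summarize <- function(f) {
    a <- tm <- numeric(0)
    for (s in 1:5) {
      g <- inferRandom(50, 30, f, s)
      a <- c(a, suppressWarnings(degreeAssortativity(g)))
      tm <- c(tm, graphTransitivity(g)$median)
    }
    c(assort = mean(a, na.rm = TRUE), tmed = mean(tm))
  }
  lo <- summarize(0.1)
  mid <- summarize(0.5)
  hi <- summarize(0.975)
  ## signed assortativity decreases as mutation frequency rises
  expect_lt(hi[["assort"]], lo[["assort"]])
  ## median local transitivity peaks at intermediate frequency
  expect_gt(mid[["tmed"]], lo[["tmed"]])
  expect_gt(mid[["tmed"]], hi[["tmed"]])
})
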
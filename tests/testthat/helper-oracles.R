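## Independent brute-force oracles and small fixture builders. These
## re-derive expected values straight from the definitions and never call the
## code paths they check.

## Enumerate all ordered event pairs directly from the defining formulas:
## an edge i -> j exists iff p_i > p_j and p_{i and j} > 0, with
## weight = p_{j|i} / (p_i + p_j).
bruteForceEdges <- function(mat) {
  x <- as.matrix(mat)
  N <- nrow(x)
  ids <- colnames(x)
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      ci <- sum(x[, i])
      cj <- sum(x[, j])
      jc <- sum(x[, i] & x[, j])
      if (jc == 0 || ci <= cj) next
      cond <- jc / ci
      rows[[length(rows) + 1L]] <- data.frame(
        source = ids[[i]], target = ids[[j]],
        weight = cond / ((ci + cj) / N), cond_prob = cond,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(source = character(), target = character(),
                      weight = numeric(), cond_prob = numeric()))
  out[order(out$source, out$target), , drop = FALSE]
}

## Mann-Whitney AUROC by exhaustive pair comparison.
bruteForceAUROC <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

## Exhaustive triangle/triple counting on an undirected edge list.
bruteForceTransitivity <- function(nodes, edgePairs) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edgePairs))) {
    adj[edgePairs[k, 1L], edgePairs[k, 2L]] <- TRUE
    adj[edgePairs[k, 2L], edgePairs[k, 1L]] <- TRUE
  }
  localv <- vapply(nodes, function(v) {
    nb <- nodes[adj[v, ]]
    d <- length(nb)
    if (d < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    links / (d * (d - 1) / 2)
  }, numeric(1))
  triples <- sum(vapply(nodes, function(v) {
    d <- sum(adj[v, ]); d * (d - 1) / 2
  }, numeric(1)))
  triangles <- 0
  for (a in seq_along(nodes)) for (b in seq_along(nodes)) for (ck in seq_along(nodes))
    if (a < b && b < ck && adj[a, b] && adj[b, ck] && adj[a, ck])
      triangles <- triangles + 1
  list(global = if (triples > 0) 3 * triangles / triples else 0,
       local = localv)
}

## Build a TodagGraph directly from node/edge specifications (bypassing
## inference) for metric unit tests.
makeTestGraph <- function(events, edgeDf, probs = NULL, nSamples = 10L) {
  if (is.null(probs)) probs <- rep(0.5, length(events))
  e <- todag:::emptyEdgeFrame()
  if (nrow(edgeDf)) {
    e <- data.frame(source = edgeDf$source, target = edgeDf$target,
                    weight = edgeDf$weight,
                    cond_prob = if (is.null(edgeDf$cond_prob)) edgeDf$weight
                                else edgeDf$cond_prob,
                    source_count = 1L, target_count = 1L, joint_count = 1L,
                    path_joint = NA_real_,
                    waiting_time = if (is.null(edgeDf$waiting_time))
                      NA_real_ else edgeDf$waiting_time,
                    speed_category = if (is.null(edgeDf$speed_category))
                      NA_character_ else edgeDf$speed_category,
                    stringsAsFactors = FALSE)
  }
  methods::new("TodagGraph",
               nodes = data.frame(event = events, count = 1L, prob = probs,
                                  stringsAsFactors = FALSE),
               edges = e, ties = todag:::emptyTieFrame(),
               config = todagConfig(), timing = list(),
               seed = NA_integer_, nSamples = as.integer(nSamples))
}

## Hand-built three-node chain APG used by several cases.
chainAPG <- function() {
  methods::new("GoldStandardAPG",
               nodeIDs = c("E1", "E2", "E3"), root = "E1",
               edges = data.frame(parent = c("E1", "E2"),
                                  child = c("E2", "E3"),
                                  stringsAsFactors = FALSE),
               nodeProb = c(E1 = NA_real_, E2 = NA_real_, E3 = NA_real_),
               pathJoint = c(E1 = NA_real_, E2 = NA_real_, E3 = NA_real_))
}

## Random Bernoulli matrix + inferred graph, warnings silenced (path caps).
inferRandom <- function(nSamples, nEvents, freq, seed) {
  m <- randomBinaryMatrix(nSamples, nEvents, freq, seed = seed,
                          exact = FALSE)
  suppressWarnings(inferTodag(m, seed = seed))
}
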
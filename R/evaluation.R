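## AUROC by the rank-sum (Mann-Whitney) statistic with midrank tie
## correction; equivalent to the trapezoidal area under the ROC curve.
.midrankAUROC <- function(scores, labels) {
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (as.numeric(nPos) * nNeg)
}

## igraph view of the directed edge set (vertices = all graph nodes).
.asIgraph <- function(graph, directed = TRUE) {
  igraph::graph_from_data_frame(
    graph@edges[, c("source", "target", "weight")],
    directed = directed, vertices = graph@nodes$event)
}

#' Edge-recovery AUROC against a gold standard
#'
#' Scores every ordered node pair (i, j), i != j, with the inferred edge's
#' weight (0 when no edge was inferred) and computes the area under the ROC
#' curve against the gold standard's directed edges, by the midrank
#' (Mann-Whitney) statistic. Reverse directions of true edges count as
#' negatives, so direction recovery is part of the task.
#'
#' @param graph a [TodagGraph-class].
#' @param gold a [GoldStandardAPG-class] over the same node set.
#' @return A [BenchmarkResult-class].
#' @export
edgeRecoveryAUROC <- function(graph, gold) {
  stopifnot(is(graph, "TodagGraph"), is(gold, "GoldStandardAPG"))
  nodes <- graph@nodes$event
  extra <- setdiff(nodes, gold@nodeIDs)
  missing <- setdiff(gold@nodeIDs, nodes)
  if (length(extra) || length(missing))
    stop("node sets differ; only in graph: {",
         paste(extra, collapse = ", "), "}, only in gold: {",
         paste(missing, collapse = ", "), "}")
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  scores <- matrix(0, n, n)
  e <- graph@edges
  if (nrow(e))
    scores[cbind(idx[e$source], idx[e$target])] <- e$weight
  labels <- matrix(FALSE, n, n)
  ge <- gold@edges
  if (nrow(ge))
    labels[cbind(idx[ge$parent], idx[ge$child])] <- TRUE
  offDiag <- !diag(n)
  s <- scores[offDiag]
  y <- labels[offDiag]
  nPos <- sum(y)
  nNeg <- sum(!y)
  if (nPos == 0L || nNeg == 0L)
    stop("AUROC undefined: need at least one gold edge and one non-edge")
  aur <- .midrankAUROC(s, y)
  inferred <- scores > 0
  tp <- sum(inferred & labels & offDiag)
  fp <- sum(inferred & !labels & offDiag)
  fn <- sum(!inferred & labels & offDiag)
  tn <- sum(!inferred & !labels & offDiag)
  new("BenchmarkResult", auroc = aur, nGoldEdges = as.integer(nPos),
      nCandidatePairs = as.integer(nPos + nNeg), tp = as.integer(tp),
      fp = as.integer(fp), fn = as.integer(fn), tn = as.integer(tn))
}

#' Degree assortativity
#'
#' Pearson correlation between the total (in + out) degrees of the two
#' endpoints of each edge, computed on the undirected skeleton (each edge
#' contributes both endpoint orderings). Negative values indicate high-degree
#' nodes attaching preferentially to low-degree nodes.
#'
#' @param graph a [TodagGraph-class] with at least one edge.
#' @return The correlation in `[-1, 1]`, or `NA` with a warning when every
#'   endpoint degree is identical (zero variance).
#' @export
degreeAssortativity <- function(graph) {
  stopifnot(is(graph, "TodagGraph"))
  e <- graph@edges
  if (nrow(e) == 0L) stop("graph has no edges")
  idx <- stats::setNames(seq_len(nrow(graph@nodes)), graph@nodes$event)
  ends <- cbind(idx[e$source], idx[e$target])
  deg <- tabulate(ends, nbins = nrow(graph@nodes))
  x <- c(deg[ends[, 1L]], deg[ends[, 2L]])
  y <- c(deg[ends[, 2L]], deg[ends[, 1L]])
  if (stats::var(x) == 0) {
    warning("assortativity undefined: all endpoint degrees are equal")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Transitivity (clustering coefficient)
#'
#' Global and per-node local clustering coefficients of the undirected
#' skeleton, plus the median of the local distribution. Nodes of degree < 2
#' have local transitivity 0.
#'
#' @param graph a [TodagGraph-class] with at least 3 nodes.
#' @return A list with elements `global`, `local` (named per node) and
#'   `median`.
#' @export
graphTransitivity <- function(graph) {
  stopifnot(is(graph, "TodagGraph"), nrow(graph@nodes) >= 3L)
  g <- igraph::as_undirected(.asIgraph(graph), mode = "collapse")
  glob <- igraph::transitivity(g, type = "global")
  if (is.nan(glob)) glob <- 0
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  loc[is.nan(loc)] <- 0
  names(loc) <- graph@nodes$event
  list(global = glob, local = loc, median = stats::median(loc))
}

#' Kleinberg hub and authority scores (HITS)
#'
#' Power iteration of the HITS fixed point (`authority = A' hub`,
#' `hub = A authority`, L2-normalized each step) until the change falls below
#' `tolerance` or the iteration cap is reached; final scores are normalized so
#' the maximum is 1. Hubs point to many authorities; authorities are pointed
#' to by many hubs.
#'
#' @param graph a [TodagGraph-class].
#' @param iterations iteration cap.
#' @param tolerance L2 convergence threshold.
#' @return A list with named numeric vectors `hub` and `authority`.
#' @export
hubAuthorityScores <- function(graph, iterations = 1000L,
                               tolerance = 1e-8) {
  stopifnot(is(graph, "TodagGraph"))
  n <- nrow(graph@nodes)
  zero <- stats::setNames(numeric(n), graph@nodes$event)
  if (nrow(graph@edges) == 0L) {
    warning("graph has no edges; all hub/authority scores are zero")
    return(list(hub = zero, authority = zero))
  }
  idx <- stats::setNames(seq_len(n), graph@nodes$event)
  A <- matrix(0, n, n)
  A[cbind(idx[graph@edges$source], idx[graph@edges$target])] <- 1
  h <- rep(1 / sqrt(n), n)
  a <- numeric(n)
  for (i in seq_len(iterations)) {
    a2 <- drop(crossprod(A, h))
    a2 <- a2 / max(sqrt(sum(a2^2)), .Machine$double.eps)
    h2 <- drop(A %*% a2)
    h2 <- h2 / max(sqrt(sum(h2^2)), .Machine$double.eps)
    delta <- sqrt(sum((h2 - h)^2)) + sqrt(sum((a2 - a)^2))
    h <- h2
    a <- a2
    if (delta < tolerance) break
  }
  normTo1 <- function(v) if (max(v) > 0) v / max(v) else v
  list(hub = stats::setNames(normTo1(h), graph@nodes$event),
       authority = stats::setNames(normTo1(a), graph@nodes$event))
}

#' Per-node degree and strength table across weight thresholds
#'
#' For each threshold, degrees and strengths are computed on the sub-graph of
#' edges with `weight >= threshold`; strength is the sum of incident edge
#' weights. Degree/strength ratio columns carry `NA` when the strength is 0.
#'
#' @param graph a [TodagGraph-class].
#' @param weightThresholds numeric vector of thresholds.
#' @return A data.frame with columns `threshold`, `event`, `in_degree`,
#'   `out_degree`, `in_strength`, `out_strength`, `in_degree_strength_ratio`,
#'   `out_degree_strength_ratio`.
#' @export
degreeStrengthTable <- function(graph, weightThresholds = 0) {
  stopifnot(is(graph, "TodagGraph"))
  nodes <- graph@nodes$event
  idx <- stats::setNames(seq_along(nodes), nodes)
  out <- lapply(weightThresholds, function(th) {
    e <- graph@edges[graph@edges$weight >= th, , drop = FALSE]
    indeg <- tabulate(idx[e$target], nbins = length(nodes))
    outdeg <- tabulate(idx[e$source], nbins = length(nodes))
    instr <- vapply(seq_along(nodes), function(i)
      sum(e$weight[idx[e$target] == i]), numeric(1))
    outstr <- vapply(seq_along(nodes), function(i)
      sum(e$weight[idx[e$source] == i]), numeric(1))
    data.frame(threshold = th, event = nodes,
               in_degree = indeg, out_degree = outdeg,
               in_strength = instr, out_strength = outstr,
               in_degree_strength_ratio =
                 ifelse(instr > 0, indeg / instr, NA_real_),
               out_degree_strength_ratio =
                 ifelse(outstr > 0, outdeg / outstr, NA_real_),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Neighborhood-induced subgraph
#'
#' The subgraph induced by all nodes within undirected distance
#' `order` of `center`, subsequently restricted to edges with
#' `weight >= minWeight`.
#'
#' @param graph a [TodagGraph-class].
#' @param center event id.
#' @param order neighborhood radius (0 gives the single node).
#' @param minWeight edge weight threshold.
#' @return A [TodagGraph-class] on the neighborhood's nodes.
#' @export
inducedSubgraph <- function(graph, center, order = 1L, minWeight = 0) {
  stopifnot(is(graph, "TodagGraph"), order >= 0)
  nodes <- graph@nodes$event
  if (!center %in% nodes) stop("unknown center node: ", center)
  keep <- center
  frontier <- center
  e <- graph@edges
  d <- 0L
  while (d < order && length(frontier)) {
    nb <- unique(c(e$target[e$source %in% frontier],
                   e$source[e$target %in% frontier]))
    frontier <- setdiff(nb, keep)
    keep <- c(keep, frontier)
    d <- d + 1L
  }
  sub <- e[e$source %in% keep & e$target %in% keep &
             e$weight >= minWeight, , drop = FALSE]
  rownames(sub) <- NULL
  g <- graph
  g@nodes <- graph@nodes[nodes %in% keep, , drop = FALSE]
  rownames(g@nodes) <- NULL
  g@edges <- sub
  g@ties <- graph@ties[graph@ties$event1 %in% keep &
                         graph@ties$event2 %in% keep, , drop = FALSE]
  rownames(g@ties) <- NULL
  validObject(g)
  g
}
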
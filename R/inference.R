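#' Build the complete candidate edge set (step 2)
#'
#' For every unordered event pair with positive joint probability and strictly
#' different frequencies, one candidate edge is created from the more frequent
#' event (source) to the less frequent one (target), with
#' \deqn{w(v_{src}, v_{tgt}) = \frac{p_{tgt|src}}{p_{src} + p_{tgt}}}
#' and the conditional probability \eqn{p_{tgt|src}} stored on the edge. Pairs
#' with zero joint probability produce no edge (a dependency edge requires a
#' non-null conditional); pairs with exactly equal frequencies (integer-count
#' comparison) are undirected ties and are returned separately.
#'
#' Orienting from the more to the less frequent event makes every edge point
#' strictly "downhill" in frequency, so the candidate set is acyclic by
#' construction.
#'
#' @param stats an [EventStats-class].
#' @return A list with elements `candidates` (edge data.frame with columns
#'   `source`, `target`, `weight`, `cond_prob`, `source_count`, `target_count`,
#'   `joint_count`, `path_joint`, `waiting_time`, `speed_category`) and `ties`
#'   (data.frame with `event1`, `event2`, `joint_count`).
#' @seealso [filterEdges()], [inferTodag()].
#' @export
buildCompleteGraph <- function(stats) {
  stopifnot(is(stats, "EventStats"))
  ids <- stats@eventIDs
  cnt <- stats@counts
  J <- stats@jointCounts
  N <- stats@nSamples
  pair <- which(upper.tri(J) & J > 0L, arr.ind = TRUE)
  if (nrow(pair) == 0L)
    return(list(candidates = emptyEdgeFrame(), ties = emptyTieFrame()))
  ci <- cnt[pair[, 1L]]
  cj <- cnt[pair[, 2L]]
  jc <- J[pair]
  tie <- ci == cj
  ties <- data.frame(event1 = ids[pair[tie, 1L]], event2 = ids[pair[tie, 2L]],
                     joint_count = jc[tie], stringsAsFactors = FALSE)
  di <- !tie
  if (!any(di))
    return(list(candidates = emptyEdgeFrame(), ties = ties))
  srcFirst <- ci[di] > cj[di]
  isrc <- ifelse(srcFirst, pair[di, 1L], pair[di, 2L])
  itgt <- ifelse(srcFirst, pair[di, 2L], pair[di, 1L])
  jcd <- jc[di]
  csrc <- cnt[isrc]
  ctgt <- cnt[itgt]
  cond <- jcd / csrc
  weight <- as.numeric(jcd) * N / (as.numeric(csrc) * (csrc + ctgt))
  candidates <- data.frame(
    source = ids[isrc], target = ids[itgt], weight = weight, cond_prob = cond,
    source_count = as.integer(csrc), target_count = as.integer(ctgt),
    joint_count = as.integer(jcd), path_joint = NA_real_,
    waiting_time = NA_real_, speed_category = NA_character_,
    stringsAsFactors = FALSE)
  list(candidates = candidates, ties = ties)
}

#' Confidence interval for a conditional probability (step 3)
#'
#' The `"wilson"` variant solves \eqn{(p_c - p)^2 = z^2 p(1-p)/n} for `p`
#' (the Wilson score interval, with `z` the standard-normal quantile of order
#' `(1+gamma)/2`), incorporating the sampling variance `p(1-p)/n` of an
#' estimated frequency. The `"literal"` variant solves
#' \eqn{(p_c - p)^2 = z_\gamma} with \eqn{z_\gamma} the quantile of order
#' `gamma`, clamping the roots to `[0,1]`; for any usual `gamma` the half-width
#' \eqn{\sqrt{z_\gamma}} exceeds 1, so this variant is degenerate and is kept
#' only for comparison.
#'
#' @param pCond conditional probability estimate(s) in `[0,1]` (vectorized).
#' @param n sample count (`>= 1`).
#' @param gamma confidence level in (0,1).
#' @param variant `"wilson"` or `"literal"`.
#' @return A matrix with one row per element of `pCond` and columns `p_min`,
#'   `p_max` (always `p_min <= p_max`).
#' @examples
#' confidenceInterval(0.5, 100)  # approximately (0.404, 0.596)
#' @export
confidenceInterval <- function(pCond, n, gamma = 0.95,
                               variant = c("wilson", "literal")) {
  variant <- match.arg(variant)
  stopifnot(all(pCond >= 0 & pCond <= 1), n >= 1, gamma > 0, gamma < 1)
  if (variant == "wilson") {
    z <- stats::qnorm((1 + gamma) / 2)
    denom <- 1 + z^2 / n
    center <- (pCond + z^2 / (2 * n)) / denom
    half <- z * sqrt(pCond * (1 - pCond) / n + z^2 / (4 * n^2)) / denom
    lo <- center - half
    hi <- center + half
  } else {
    zg <- stats::qnorm(gamma)
    half <- sqrt(max(zg, 0))
    lo <- pmax(0, pCond - half)
    hi <- pmin(1, pCond + half)
  }
  cbind(p_min = lo, p_max = hi)
}

#' Filter candidate edges (step 3)
#'
#' In the default `"basic"` mode all candidates are retained: pairs with zero
#' joint probability and exact frequency ties were already excluded at
#' construction. The `"ci_sum"` mode applies the removal condition
#' \eqn{p_{tgt|src} < p_{src} + p_{tgt} + (p_{max} - p_{min})} literally (it
#' empties the graph whenever `p_src + p_tgt >= 1` and is provided for
#' exploration only); `"ci_product"` replaces the sum baseline with the
#' independence baseline \eqn{p_{src} \cdot p_{tgt}}.
#'
#' @param candidates candidate edge data.frame from [buildCompleteGraph()].
#' @param stats the [EventStats-class] the candidates came from.
#' @param config an [InferenceConfig-class].
#' @return The retained edge data.frame; its `cond_prob` column holds the
#'   stored step-3 conditionals later used as exponential rates.
#' @export
filterEdges <- function(candidates, stats, config = todagConfig()) {
  stopifnot(is.data.frame(candidates), is(stats, "EventStats"),
            is(config, "InferenceConfig"))
  if (config@filterMode == "basic" || nrow(candidates) == 0L)
    return(candidates)
  N <- stats@nSamples
  ps <- candidates$source_count / N
  pt <- candidates$target_count / N
  ci <- confidenceInterval(candidates$cond_prob, N, config@gamma,
                           config@ciVariant)
  width <- ci[, "p_max"] - ci[, "p_min"]
  baseline <- if (config@filterMode == "ci_sum") ps + pt else ps * pt
  keep <- candidates$cond_prob >= baseline + width
  candidates[keep, , drop = FALSE]
}

## Assemble a TodagGraph from stats + retained edges + ties.
.newTodagGraph <- function(stats, edges, ties, config,
                           seed = NA_integer_) {
  nodes <- data.frame(event = stats@eventIDs,
                      count = as.integer(stats@counts),
                      prob = stats@counts / stats@nSamples,
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  new("TodagGraph", nodes = nodes, edges = edges, ties = ties,
      config = config, timing = list(), seed = as.integer(seed),
      nSamples = stats@nSamples)
}

## Shared depth-first enumeration of simple root-to-node paths.
## `onStep(edgeIdx, support2, pathEdges, condSum)` is called for every path
## prefix, where the prefix's terminal edge is edgeIdx, support2 the logical
## sample-support of the intersection over all path nodes, pathEdges the edge
## indices along the prefix and condSum the sum of conditionals over them.
## Returns list(visited = logical per edge, budgetHit, overflowNodes).
.walkPaths <- function(graph, matrix, onStep, pathCap, stepBudget = 2e5) {
  edges <- graph@edges
  nodes <- graph@nodes$event
  nix <- seq_along(nodes)
  names(nix) <- nodes
  src <- nix[edges$source]
  tgt <- nix[edges$target]
  X <- matrix@occurrence[, nodes, drop = FALSE] > 0L
  outEdges <- split(seq_len(nrow(edges)), factor(src, levels = nix))
  indeg <- tabulate(tgt, nbins = length(nodes))
  outdeg <- tabulate(src, nbins = length(nodes))
  roots <- which(indeg == 0L & outdeg > 0L)

  env <- new.env(parent = emptyenv())
  env$steps <- 0L
  env$budgetHit <- FALSE
  env$pathCount <- integer(length(nodes))
  env$overflow <- logical(length(nodes))
  env$visited <- logical(nrow(edges))
  env$pathEdges <- integer(0)

  visit <- function(u, support, condSum) {
    for (eidx in outEdges[[u]]) {
      if (env$budgetHit) return(invisible())
      env$steps <- env$steps + 1L
      if (env$steps > stepBudget) {
        env$budgetHit <- TRUE
        return(invisible())
      }
      v <- tgt[[eidx]]
      s2 <- support & X[, v]
      env$visited[eidx] <- TRUE
      env$pathEdges <- c(env$pathEdges, eidx)
      cs <- condSum + edges$cond_prob[[eidx]]
      onStep(eidx, s2, env$pathEdges, cs)
      env$pathCount[v] <- env$pathCount[v] + 1L
      if (env$pathCount[v] > pathCap) {
        env$overflow[v] <- TRUE
      } else {
        visit(v, s2, cs)
      }
      env$pathEdges <- env$pathEdges[-length(env$pathEdges)]
    }
    invisible()
  }
  for (r in roots) {
    if (env$budgetHit) break
    visit(r, X[, r], 0)
  }
  list(visited = env$visited, budgetHit = env$budgetHit,
       overflowNodes = nodes[env$overflow], tgt = tgt)
}

#' Update edge probabilities with path-conditional joints (step 4)
#'
#' For every simple path from a root (in-degree-0 node) to a node `k`, the
#' path's terminal edge records the joint probability of `k` together with all
#' its predecessors on that path,
#' \eqn{p_{k \cap (k-1) \cap \dots \cap (k-n_k)}}, replacing the pairwise
#' conditional view with the full non-memoryless one. When several paths share
#' a terminal edge, the edge stores the maximum (most supported path). Graph
#' topology is unchanged.
#'
#' Path enumeration is capped (per node by `pathCap` of the graph's config,
#' plus a global work bound); edges whose enumeration was cut keep the
#' pairwise joint probability, with a warning.
#'
#' @param graph a [TodagGraph-class].
#' @param matrix the [CooccurrenceMatrix-class] the graph was inferred from.
#' @return The graph with its edges' `path_joint` column filled in.
#' @export
updatePathProbabilities <- function(graph, matrix) {
  stopifnot(is(graph, "TodagGraph"), is(matrix, "CooccurrenceMatrix"))
  edges <- graph@edges
  if (nrow(edges) == 0L) return(graph)
  N <- nSamples(matrix)
  pj <- rep(-Inf, nrow(edges))
  walk <- .walkPaths(graph, matrix,
                     onStep = function(eidx, s2, pathEdges, condSum) {
                       v <- sum(s2) / N
                       if (v > pj[[eidx]]) pj[[eidx]] <<- v
                     },
                     pathCap = graph@config@pathCap)
  pairwise <- edges$joint_count / N
  fallback <- !walk$visited |
    graph@nodes$event[walk$tgt] %in% walk$overflowNodes
  pj[fallback] <- pairwise[fallback]
  if (walk$budgetHit || length(walk$overflowNodes))
    warning("path enumeration capped; ", sum(fallback),
            " edge(s) keep the pairwise joint probability")
  edges$path_joint <- pj
  graph@edges <- edges
  graph
}

#' Prune low-probability paths (step 4, optional)
#'
#' With `path_prune = "literal"`, every root-to-node path is tested against
#' \eqn{p_{k \cap (k-1) \cap \dots \cap (k-n_k)} < \sum_h p_{k-h|k-(h+1)}}
#' (the sum running over the path's edges); an edge is removed only when every
#' enumerated path through it fails the test. Because the right-hand side is a
#' sum of probabilities and easily exceeds 1, this condition is destructive on
#' chain structures and the default is `"off"` (no change).
#'
#' @param graph a [TodagGraph-class] on which [updatePathProbabilities()] has
#'   run.
#' @param matrix the source [CooccurrenceMatrix-class].
#' @param config an [InferenceConfig-class]; only its `pathPrune` and
#'   `pathCap` fields are used.
#' @return The (possibly reduced) graph.
#' @export
prunePaths <- function(graph, matrix, config = graph@config) {
  stopifnot(is(graph, "TodagGraph"), is(config, "InferenceConfig"))
  if (config@pathPrune == "off" || nrow(graph@edges) == 0L) return(graph)
  N <- nSamples(matrix)
  keep <- logical(nrow(graph@edges))
  walk <- .walkPaths(graph, matrix,
                     onStep = function(eidx, s2, pathEdges, condSum) {
                       joint <- sum(s2) / N
                       if (!(joint < condSum)) keep[pathEdges] <<- TRUE
                     },
                     pathCap = config@pathCap)
  ## edges the enumeration never reached are retained (no evidence against)
  keep[!walk$visited] <- TRUE
  if (walk$budgetHit)
    warning("path enumeration capped during pruning; unreached edges retained")
  graph@edges <- graph@edges[keep, , drop = FALSE]
  rownames(graph@edges) <- NULL
  validObject(graph)
  graph
}

#' Infer a timed oncogenetic DAG
#'
#' Runs the full six-step procedure: exact frequency estimation, complete
#' candidate graph construction oriented from more to less frequent events,
#' edge filtering, path-conditional probability update, optional path pruning,
#' exponential waiting-time sampling (rate = stored conditional probability)
#' and fast/moderate/slow categorization.
#'
#' Topology is deterministic for a fixed matrix and config; waiting times are
#' deterministic given `seed`.
#'
#' @param matrix a [CooccurrenceMatrix-class].
#' @param config an [InferenceConfig-class].
#' @param timing a [TimingConfig-class] for speed categorization.
#' @param seed integer RNG seed for waiting-time sampling, or NULL.
#' @return A [TodagGraph-class].
#' @examples
#' m <- CooccurrenceMatrix(cbind(E1 = c(1, 1, 0), E2 = c(1, 0, 0)))
#' g <- inferTodag(m, seed = 1)
#' graphEdges(g)[, c("source", "target", "weight")]
#' @export
inferTodag <- function(matrix, config = todagConfig(),
                       timing = timingConfig(), seed = NULL) {
  stopifnot(is(matrix, "CooccurrenceMatrix"), is(config, "InferenceConfig"),
            is(timing, "TimingConfig"))
  stats <- estimateEventStats(matrix)
  built <- buildCompleteGraph(stats)
  retained <- filterEdges(built$candidates, stats, config)
  graph <- .newTodagGraph(stats, retained, built$ties, config,
                          seed = if (is.null(seed)) NA_integer_ else seed)
  validObject(graph)
  graph <- updatePathProbabilities(graph, matrix)
  graph <- prunePaths(graph, matrix, config)
  graph <- sampleWaitingTimes(graph, seed = seed)
  if (nrow(graph@edges) > 0L)
    graph <- categorizeEdges(graph, timing)
  graph
}
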
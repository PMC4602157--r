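#' Generate a random accessible pointed graph (APG) topology
#'
#' Builds a random DAG in which every node is reachable from a distinguished
#' root: a random spanning arborescence (each non-root node attaches to a
#' uniformly chosen predecessor in the generation order) plus `nEdges - n + 1`
#' extra edges drawn uniformly from the remaining forward pairs of the same
#' topological order. Node labels `E1..En` follow that order, with `E1` the
#' root.
#'
#' @param nNodes number of nodes (`>= 2`).
#' @param nEdges number of edges, in `nNodes-1 .. nNodes*(nNodes-1)/2`.
#' @param seed integer seed or NULL.
#' @return A [GoldStandardAPG-class] with unassigned probabilities.
#' @examples
#' apg <- generateAPG(10, 30, seed = 1)
#' nrow(goldEdges(apg))
#' @export
generateAPG <- function(nNodes, nEdges, seed = NULL) {
  stopifnot(nNodes >= 2)
  if (nEdges < nNodes - 1 || nEdges > nNodes * (nNodes - 1) / 2)
    stop("nEdges must be in [nNodes-1, nNodes*(nNodes-1)/2]")
  ids <- paste0("E", seq_len(nNodes))
  edges <- withSeed(seed, {
    parent <- vapply(2:nNodes, function(i) sample.int(i - 1L, 1L), integer(1))
    tree <- cbind(parent, 2:nNodes)
    extra <- nEdges - (nNodes - 1L)
    if (extra > 0L) {
      all <- which(upper.tri(diag(nNodes)), arr.ind = TRUE)
      used <- tree[, 1L] + nNodes * (tree[, 2L] - 1L)
      avail <- all[!(all[, 1L] + nNodes * (all[, 2L] - 1L)) %in% used, ,
                   drop = FALSE]
      pick <- avail[sample.int(nrow(avail), extra), , drop = FALSE]
      rbind(tree, pick)
    } else tree
  })
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  new("GoldStandardAPG", nodeIDs = ids, root = ids[[1L]],
      edges = data.frame(parent = ids[edges[, 1L]],
                         child = ids[edges[, 2L]],
                         stringsAsFactors = FALSE),
      nodeProb = stats::setNames(rep(NA_real_, nNodes), ids),
      pathJoint = stats::setNames(rep(NA_real_, nNodes), ids))
}

#' Assign occurrence probabilities to an APG
#'
#' Processing nodes in topological order, each child's probability is the
#' maximum of its parents' probabilities times a factor drawn uniformly from
#' `decayRange`, enforcing the strict parent-greater-than-child constraint
#' that encodes edge direction in the data. Under the nested-support sampling
#' design of [sampleCooccurrence()], the joint probability of every
#' root-to-node path equals the terminal node's probability; that value is
#' recorded per node in `pathJoint`.
#'
#' @param apg a [GoldStandardAPG-class] topology.
#' @param rootProb root occurrence probability in `(0.5, 1]`.
#' @param decayRange length-2 numeric `(low, high)` with
#'   `0 < low <= high < 1`.
#' @param seed integer seed or NULL.
#' @return The APG with `nodeProb` and `pathJoint` filled in.
#' @examples
#' apg <- assignProbabilities(generateAPG(10, 30, seed = 1), seed = 2)
#' range(nodeProb(apg))
#' @export
assignProbabilities <- function(apg, rootProb = 0.9,
                                decayRange = c(0.5, 0.9), seed = NULL) {
  stopifnot(is(apg, "GoldStandardAPG"),
            rootProb > 0.5, rootProb <= 1,
            length(decayRange) == 2L, decayRange[[1L]] > 0,
            decayRange[[1L]] <= decayRange[[2L]], decayRange[[2L]] < 1)
  ids <- apg@nodeIDs
  prob <- stats::setNames(rep(NA_real_, length(ids)), ids)
  prob[apg@root] <- rootProb
  parentsOf <- split(apg@edges$parent, apg@edges$child)
  withSeed(seed, {
    for (v in ids[-1L]) {
      pmaxv <- max(prob[parentsOf[[v]]])
      prob[v] <- pmaxv * stats::runif(1L, decayRange[[1L]], decayRange[[2L]])
    }
  })
  apg@nodeProb <- prob
  apg@pathJoint <- prob
  validObject(apg)
  apg
}

#' Sample a binary co-occurrence table from an APG gold standard
#'
#' Each node's column receives exactly `round(nodeProb * nSamples)` ones. The
#' root's positives are drawn uniformly over all samples; in topological
#' order, each child's positives are drawn uniformly from the intersection of
#' its parents' positive sample sets, realizing the conditional dependency
#' structure (child support nested within every parent's support). When the
#' intersection is smaller than the required count, the count is clipped to
#' the intersection size and a warning summarizes the clipping; clipping also
#' preserves the strict inequality of the assigned probability system (child
#' strictly below its most probable parent in realized counts), since an
#' exactly tied pair would contradict the direction the gold standard encodes.
#'
#' @param apg a [GoldStandardAPG-class] with probabilities assigned.
#' @param nSamples number of samples (`>= 10`).
#' @param seed integer seed or NULL.
#' @return A [CooccurrenceMatrix-class] with events in gold-standard node
#'   order.
#' @export
sampleCooccurrence <- function(apg, nSamples = 100L, seed = NULL) {
  stopifnot(is(apg, "GoldStandardAPG"), nSamples >= 10L)
  if (anyNA(apg@nodeProb))
    stop("assign node probabilities before sampling (assignProbabilities)")
  ids <- apg@nodeIDs
  parentsOf <- split(apg@edges$parent, apg@edges$child)
  x <- matrix(0L, nSamples, length(ids),
              dimnames = list(paste0("S", seq_len(nSamples)), ids))
  clipped <- character(0)
  withSeed(seed, {
    for (v in ids) {
      k0 <- round(apg@nodeProb[[v]] * nSamples)
      k <- k0
      pts <- parentsOf[[v]]
      if (is.null(pts)) {
        avail <- seq_len(nSamples)
      } else {
        avail <- which(rowSums(x[, pts, drop = FALSE]) == length(pts))
        ## realized counts stay strictly below every parent's count: each
        ## gold edge encodes a direction, and a tied or inverted frequency
        ## would contradict the constraint system the benchmark encodes
        minParent <- min(colSums(x[, pts, drop = FALSE]))
        k <- min(k, length(avail), max(minParent - 1L, 0L))
      }
      if (k < k0) clipped <- c(clipped, v)
      if (k > 0L)
        x[avail[sample.int(length(avail), k)], v] <- 1L
    }
  })
  if (length(clipped))
    warning("positive-count clipped to the parents' support intersection for ",
            length(clipped), " node(s): ", .abbrevIDs(clipped))
  CooccurrenceMatrix(x)
}
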
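#' @import methods
NULL

## Central data containers. All probabilities are backed by integer counts so
## that equality comparisons (tie detection during edge orientation) are exact
## integer comparisons, never floating-point.

#' Binary sample-by-event co-occurrence matrix
#'
#' The sole raw input to TO-DAG inference: a labelled binary matrix with tumor
#' samples in rows and genetic events (genes/aberrations) in columns. A cell
#' value of 1 records that the event was observed in that sample.
#'
#' @slot occurrence integer matrix of 0/1 values with unique sample row names
#'   and unique event column names.
#'
#' @seealso [CooccurrenceMatrix()] for construction from a plain matrix,
#'   [readCooccurrence()] for file input.
#' @export
setClass("CooccurrenceMatrix", slots = c(occurrence = "matrix"))

setValidity("CooccurrenceMatrix", function(object) {
  x <- object@occurrence
  if (!is.numeric(x)) return("occurrence values must be numeric 0/1")
  if (nrow(x) < 1L) return("at least one sample is required")
  if (ncol(x) < 2L) return("at least two events are required")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    return("occurrence matrix must carry sample row names and event column names")
  if (anyDuplicated(rownames(x))) return("duplicate sample labels")
  if (anyDuplicated(colnames(x))) return("duplicate event labels")
  bad <- which(!(x == 0L | x == 1L), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    return(sprintf("non-binary value %s at sample '%s', event '%s'",
                   format(x[bad[1L, , drop = FALSE]]),
                   rownames(x)[bad[1L, 1L]], colnames(x)[bad[1L, 2L]]))
  }
  TRUE
})

#' Construct a CooccurrenceMatrix
#'
#' @param occurrence numeric/integer matrix of 0/1 values, samples in rows and
#'   events in columns. Missing dimnames are filled with `S1, S2, ...` and
#'   `E1, E2, ...`.
#' @return A [CooccurrenceMatrix-class] object.
#' @examples
#' m <- CooccurrenceMatrix(matrix(c(1, 1, 0, 1, 0, 0), nrow = 3,
#'                                dimnames = list(NULL, c("E1", "E2"))))
#' nSamples(m)
#' @export
CooccurrenceMatrix <- function(occurrence) {
  occurrence <- as.matrix(occurrence)
  if (is.null(rownames(occurrence)))
    rownames(occurrence) <- paste0("S", seq_len(nrow(occurrence)))
  if (is.null(colnames(occurrence)))
    colnames(occurrence) <- paste0("E", seq_len(ncol(occurrence)))
  storage.mode(occurrence) <- "integer"
  new("CooccurrenceMatrix", occurrence = occurrence)
}

#' Per-event and pairwise event statistics
#'
#' Integer occurrence counts per event and co-occurrence counts per event pair,
#' estimated from a [CooccurrenceMatrix-class]. Event probabilities are exact
#' sample frequencies `count / nSamples`; the diagonal of the joint-count
#' matrix equals the per-event counts.
#'
#' @slot eventIDs character vector of event labels.
#' @slot nSamples integer number of samples the counts refer to.
#' @slot counts named integer vector of per-event occurrence counts.
#' @slot jointCounts symmetric integer matrix of pairwise co-occurrence counts.
#'
#' @seealso [estimateEventStats()], [eventProb()], [jointProb()],
#'   [conditionalProb()].
#' @export
setClass("EventStats",
         slots = c(eventIDs = "character", nSamples = "integer",
                   counts = "integer", jointCounts = "matrix"))

setValidity("EventStats", function(object) {
  n <- length(object@eventIDs)
  if (object@nSamples < 1L) return("nSamples must be >= 1")
  if (length(object@counts) != n) return("counts length mismatch")
  if (!all(dim(object@jointCounts) == c(n, n)))
    return("jointCounts dimension mismatch")
  if (!isTRUE(all.equal(object@jointCounts, t(object@jointCounts))))
    return("jointCounts must be symmetric")
  if (any(diag(object@jointCounts) != object@counts))
    return("diagonal of jointCounts must equal counts")
  jmax <- outer(object@counts, object@counts, pmin)
  if (any(object@jointCounts > jmax))
    return("joint counts cannot exceed the smaller marginal count")
  TRUE
})

#' Configuration of the TO-DAG inference procedure
#'
#' @slot gamma confidence level in (0,1) for the edge-filter confidence
#'   interval (default 0.95).
#' @slot ciVariant `"wilson"` (score interval including the `p(1-p)/n`
#'   sampling-variance term) or `"literal"` (roots of `(p_c - p)^2 - z_gamma`,
#'   clamped to `[0,1]`).
#' @slot filterMode `"basic"` (retain all candidate edges; zero-joint pairs and
#'   exact frequency ties were already excluded), `"ci_sum"` (remove the edge
#'   when `cond < p_src + p_tgt + (p_max - p_min)`), or `"ci_product"`
#'   (independence baseline, `cond < p_src * p_tgt + (p_max - p_min)`).
#' @slot pathPrune `"off"` or `"literal"` (remove root-to-node paths whose
#'   terminal joint probability falls below the sum of the conditionals along
#'   the path; an edge is dropped only when every path through it fails).
#' @slot tiePolicy `"drop"` (exclude exact-equal-frequency pairs from the DAG,
#'   recording them as undirected ties) or `"keep_undirected"` (same DAG; the
#'   tie list is intended for reporting either way).
#' @slot minWeight report-time weight threshold in `[0,1]`.
#' @slot pathCap maximum number of enumerated root-to-node paths per node
#'   before falling back to the pairwise conditional for that node's edges.
#' @export
setClass("InferenceConfig",
         slots = c(gamma = "numeric", ciVariant = "character",
                   filterMode = "character", pathPrune = "character",
                   tiePolicy = "character", minWeight = "numeric",
                   pathCap = "numeric"))

setValidity("InferenceConfig", function(object) {
  if (object@gamma <= 0 || object@gamma >= 1) return("gamma must be in (0,1)")
  if (!object@ciVariant %in% c("wilson", "literal"))
    return("ciVariant must be 'wilson' or 'literal'")
  if (!object@filterMode %in% c("basic", "ci_sum", "ci_product"))
    return("filterMode must be 'basic', 'ci_sum' or 'ci_product'")
  if (!object@pathPrune %in% c("off", "literal"))
    return("pathPrune must be 'off' or 'literal'")
  if (!object@tiePolicy %in% c("drop", "keep_undirected"))
    return("tiePolicy must be 'drop' or 'keep_undirected'")
  if (object@minWeight < 0 || object@minWeight > 1)
    return("minWeight must be in [0,1]")
  if (object@pathCap < 1) return("pathCap must be >= 1")
  TRUE
})

#' @rdname InferenceConfig-class
#' @param gamma,ciVariant,filterMode,pathPrune,tiePolicy,minWeight,pathCap see
#'   the corresponding slots.
#' @return An [InferenceConfig-class] object.
#' @export
todagConfig <- function(gamma = 0.95,
                        ciVariant = c("wilson", "literal"),
                        filterMode = c("basic", "ci_sum", "ci_product"),
                        pathPrune = c("off", "literal"),
                        tiePolicy = c("drop", "keep_undirected"),
                        minWeight = 0, pathCap = 1e4) {
  new("InferenceConfig", gamma = gamma, ciVariant = match.arg(ciVariant),
      filterMode = match.arg(filterMode), pathPrune = match.arg(pathPrune),
      tiePolicy = match.arg(tiePolicy), minWeight = minWeight,
      pathCap = pathCap)
}

#' Configuration of waiting-time categorization
#'
#' @slot mode `"quantile"` (thresholds are the 1st and 3rd quartiles of the
#'   graph's waiting-time distribution) or `"absolute"` (thresholds supplied).
#' @slot t1,t2 duration thresholds in arbitrary units; required (with
#'   `t1 < t2`) when `mode = "absolute"`.
#' @slot quantileConvention quartile interpolation rule; `"linear"` is linear
#'   interpolation between order statistics (`stats::quantile` type 7).
#' @export
setClass("TimingConfig",
         slots = c(mode = "character", t1 = "numeric", t2 = "numeric",
                   quantileConvention = "character"))

setValidity("TimingConfig", function(object) {
  if (!object@mode %in% c("quantile", "absolute"))
    return("mode must be 'quantile' or 'absolute'")
  if (object@mode == "absolute") {
    if (is.na(object@t1) || is.na(object@t2))
      return("absolute mode requires t1 and t2")
    if (!(object@t1 < object@t2)) return("t1 must be < t2")
  }
  if (!identical(object@quantileConvention, "linear"))
    return("only the 'linear' quantile convention is implemented")
  TRUE
})

#' @rdname TimingConfig-class
#' @param mode,t1,t2,quantileConvention see the corresponding slots.
#' @return A [TimingConfig-class] object.
#' @export
timingConfig <- function(mode = c("quantile", "absolute"),
                         t1 = NA_real_, t2 = NA_real_,
                         quantileConvention = "linear") {
  new("TimingConfig", mode = match.arg(mode), t1 = t1, t2 = t2,
      quantileConvention = quantileConvention)
}

#' Inferred timed oncogenetic DAG
#'
#' Nodes are genetic events with their occurrence probabilities; directed edges
#' point from the more frequent to the less frequent event of a dependent pair
#' and carry the step-2 weight, the stored conditional probability, the
#' path-updated joint probability, a sampled exponential waiting time and a
#' fast/moderate/slow speed category.
#'
#' @slot nodes data.frame with columns `event`, `count`, `prob`.
#' @slot edges data.frame with columns `source`, `target`, `weight`,
#'   `cond_prob`, `source_count`, `target_count`, `joint_count`, `path_joint`,
#'   `waiting_time`, `speed_category`.
#' @slot ties data.frame of unordered event pairs with exactly equal
#'   frequencies and positive joint probability (columns `event1`, `event2`,
#'   `joint_count`), kept out of the DAG.
#' @slot config the [InferenceConfig-class] used.
#' @slot timing list recording the categorization mode and thresholds used.
#' @slot seed integer RNG seed used for waiting-time sampling (NA if none).
#' @slot nSamples integer sample count of the source matrix.
#' @seealso [inferTodag()], [graphNodes()], [graphEdges()], [graphTies()].
#' @export
setClass("TodagGraph",
         slots = c(nodes = "data.frame", edges = "data.frame",
                   ties = "data.frame", config = "InferenceConfig",
                   timing = "list", seed = "integer", nSamples = "integer"))

setValidity("TodagGraph", function(object) {
  e <- object@edges
  need <- c("source", "target", "weight", "cond_prob")
  if (!all(need %in% names(e))) return("edges is missing required columns")
  if (nrow(e) > 0L) {
    if (any(e$source == e$target)) return("self-loop edge found")
    if (anyDuplicated(paste(e$source, e$target, sep = "\r")))
      return("duplicate directed edge found")
    if (any(e$cond_prob <= 0)) return("retained edges must have cond_prob > 0")
    unknown <- setdiff(c(e$source, e$target), object@nodes$event)
    if (length(unknown))
      return(paste("edge endpoints not in node table:",
                   paste(unknown, collapse = ", ")))
    if (!.edgesAreAcyclic(e)) return("directed edge set contains a cycle")
  }
  TRUE
})

## Kahn's algorithm on an edge data.frame.
.edgesAreAcyclic <- function(edges) {
  nodes <- unique(c(edges$source, edges$target))
  idx <- seq_along(nodes)
  names(idx) <- nodes
  src <- idx[edges$source]
  tgt <- idx[edges$target]
  indeg <- tabulate(tgt, nbins = length(nodes))
  queue <- which(indeg == 0L)
  removed <- 0L
  active <- rep(TRUE, nrow(edges))
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    removed <- removed + 1L
    out <- which(active & src == v)
    active[out] <- FALSE
    for (w in tgt[out]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  removed == length(nodes)
}

#' Gold-standard accessible pointed graph (APG)
#'
#' A directed acyclic benchmark graph with a distinguished root from which
#' every node is reachable, per-node occurrence probabilities satisfying the
#' parent-greater-than-child constraint that encodes edge direction, and
#' per-path joint probabilities.
#'
#' @slot nodeIDs character node labels in a topological order (root first).
#' @slot root the root node label.
#' @slot edges data.frame with columns `parent`, `child`.
#' @slot nodeProb named numeric occurrence probability per node (NA until
#'   [assignProbabilities()] runs).
#' @slot pathJoint named numeric joint probability of each root-to-node path,
#'   indexed by terminal node (under the nested-support design every path to a
#'   node shares its joint, equal to the node's own probability).
#' @seealso [generateAPG()], [assignProbabilities()], [sampleCooccurrence()].
#' @export
setClass("GoldStandardAPG",
         slots = c(nodeIDs = "character", root = "character",
                   edges = "data.frame", nodeProb = "numeric",
                   pathJoint = "numeric"))

setValidity("GoldStandardAPG", function(object) {
  n <- length(object@nodeIDs)
  e <- object@edges
  if (anyDuplicated(object@nodeIDs)) return("duplicate node labels")
  if (!object@root %in% object@nodeIDs) return("root not among nodes")
  if (!all(c("parent", "child") %in% names(e)))
    return("edges must have parent and child columns")
  if (nrow(e)) {
    if (!all(c(e$parent, e$child) %in% object@nodeIDs))
      return("edge endpoint not among nodes")
    if (any(e$parent == e$child)) return("self-loop in APG")
    if (!.edgesAreAcyclic(data.frame(source = e$parent, target = e$child)))
      return("APG edges contain a cycle")
    ## reachability from root
    reach <- object@root
    repeat {
      nxt <- unique(c(reach, e$child[e$parent %in% reach]))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    if (length(reach) < n) return("not every node is reachable from the root")
  } else if (n > 1L) {
    return("not every node is reachable from the root")
  }
  pr <- object@nodeProb
  if (!all(is.na(pr))) {
    if (any(pr <= 0 | pr > 1, na.rm = TRUE))
      return("node probabilities must lie in (0,1]")
    ## multiplicative-decay assignment guarantees child < max over parents
    ## (a multi-parent node may outrank its least probable parent)
    if (nrow(e)) {
      mx <- tapply(pr[e$parent], e$child, max)
      bad <- !is.na(mx) & !(pr[names(mx)] < mx)
      if (any(bad))
        return("node_prob(child) must be below the max of its parents'")
    }
  }
  TRUE
})

#' Edge-recovery benchmark result
#'
#' AUROC of inferred edge-weight scores against a gold standard's directed
#' edges over all ordered node pairs, with confusion counts at the operating
#' point "an edge was inferred".
#'
#' @slot auroc area under the ROC curve in `[0,1]`.
#' @slot nGoldEdges,nCandidatePairs integer counts.
#' @slot tp,fp,fn,tn integer confusion counts.
#' @seealso [edgeRecoveryAUROC()].
#' @export
setClass("BenchmarkResult",
         slots = c(auroc = "numeric", nGoldEdges = "integer",
                   nCandidatePairs = "integer", tp = "integer",
                   fp = "integer", fn = "integer", tn = "integer"))

setValidity("BenchmarkResult", function(object) {
  if (object@auroc < 0 || object@auroc > 1) return("auroc must be in [0,1]")
  if (object@tp + object@fn != object@nGoldEdges)
    return("tp + fn must equal the number of gold edges")
  if (object@tp + object@fp + object@fn + object@tn !=
      object@nCandidatePairs)
    return("confusion counts must sum to the number of candidate pairs")
  TRUE
})
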
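#' Estimate event statistics from a co-occurrence matrix
#'
#' Computes the exact per-event occurrence frequencies \eqn{p_i} and pairwise
#' co-occurrence frequencies \eqn{p_{i \cap j}} as integer counts over the
#' sample set. All downstream equality comparisons (tie detection during edge
#' orientation) are made on these integer counts, so no floating-point
#' tolerance is ever involved.
#'
#' @param matrix a [CooccurrenceMatrix-class].
#' @return An [EventStats-class] object.
#' @examples
#' m <- CooccurrenceMatrix(cbind(E1 = c(1, 1, 0), E2 = c(1, 0, 0)))
#' eventProb(estimateEventStats(m))
#' @export
estimateEventStats <- function(matrix) {
  stopifnot(is(matrix, "CooccurrenceMatrix"))
  x <- matrix@occurrence
  if (nrow(x) == 0L) stop("cannot estimate probabilities from zero samples")
  counts <- colSums(x)
  joint <- crossprod(x)
  storage.mode(joint) <- "integer"
  new("EventStats", eventIDs = colnames(x), nSamples = nrow(x),
      counts = stats::setNames(as.integer(counts), colnames(x)),
      jointCounts = joint)
}

#' Conditional probability of one event given another
#'
#' \eqn{p_{target|given} = p_{target \cap given} / p_{given}}, computed from
#' integer counts.
#'
#' @param stats an [EventStats-class].
#' @param target,given event labels or indices.
#' @return The conditional probability in `[0,1]`.
#' @examples
#' m <- CooccurrenceMatrix(cbind(E1 = c(1, 1, 0), E2 = c(1, 0, 0)))
#' conditionalProb(estimateEventStats(m), "E2", "E1")  # 0.5
#' @export
conditionalProb <- function(stats, target, given) {
  stopifnot(is(stats, "EventStats"))
  ti <- resolveEvents(target, stats@eventIDs)
  gi <- resolveEvents(given, stats@eventIDs)
  stopifnot(length(ti) == 1L, length(gi) == 1L)
  if (stats@counts[gi] == 0L)
    stop("conditional probability undefined: conditioning event '",
         stats@eventIDs[gi], "' occurs in zero samples")
  unname(stats@jointCounts[ti, gi] / stats@counts[gi])
}

#' Joint probability of a set of events
#'
#' Fraction of samples in which every event of the set occurs; monotone
#' non-increasing under set inclusion.
#'
#' @param matrix a [CooccurrenceMatrix-class].
#' @param events non-empty vector of event labels or indices.
#' @return The joint occurrence probability in `[0,1]`.
#' @examples
#' tri <- triangularMatrix(4)
#' jointOverSet(tri, c("E1", "E2", "E3"))  # 2/4
#' @export
jointOverSet <- function(matrix, events) {
  stopifnot(is(matrix, "CooccurrenceMatrix"), length(events) >= 1L)
  idx <- resolveEvents(events, eventIDs(matrix))
  x <- matrix@occurrence[, idx, drop = FALSE]
  sum(rowSums(x) == length(idx)) / nrow(x)
}
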
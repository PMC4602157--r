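#' @describeIn CooccurrenceMatrix-class sample labels
#' @param x a `CooccurrenceMatrix`.
#' @export
setMethod("sampleIDs", "CooccurrenceMatrix",
          function(x) rownames(x@occurrence))

#' @describeIn CooccurrenceMatrix-class event labels
#' @export
setMethod("eventIDs", "CooccurrenceMatrix",
          function(x) colnames(x@occurrence))

#' @describeIn CooccurrenceMatrix-class number of samples
#' @export
setMethod("nSamples", "CooccurrenceMatrix", function(x) nrow(x@occurrence))

#' @describeIn CooccurrenceMatrix-class number of events
#' @export
setMethod("nEvents", "CooccurrenceMatrix", function(x) ncol(x@occurrence))

#' @describeIn CooccurrenceMatrix-class underlying 0/1 integer matrix
#' @param ... ignored.
#' @export
setMethod("as.matrix", "CooccurrenceMatrix", function(x, ...) x@occurrence)

#' @describeIn CooccurrenceMatrix-class matrix dimensions
#' @export
setMethod("dim", "CooccurrenceMatrix", function(x) dim(x@occurrence))

setMethod("show", "CooccurrenceMatrix", function(object) {
  cat(sprintf("CooccurrenceMatrix: %d samples x %d events (%d positive entries)\n",
              nSamples(object), nEvents(object), sum(object@occurrence)))
  cat("events:", .abbrevIDs(eventIDs(object)), "\n")
})

#' @describeIn EventStats-class event labels
#' @param x an `EventStats`.
#' @export
setMethod("eventIDs", "EventStats", function(x) x@eventIDs)

#' @describeIn EventStats-class number of samples
#' @export
setMethod("nSamples", "EventStats", function(x) x@nSamples)

#' @describeIn EventStats-class number of events
#' @export
setMethod("nEvents", "EventStats", function(x) length(x@eventIDs))

#' @describeIn EventStats-class exact per-event frequencies
#' @export
setMethod("eventProb", "EventStats", function(x) x@counts / x@nSamples)

#' @describeIn EventStats-class exact pairwise co-occurrence frequencies
#' @export
setMethod("jointProb", "EventStats", function(x) x@jointCounts / x@nSamples)

setMethod("show", "EventStats", function(object) {
  p <- eventProb(object)
  cat(sprintf("EventStats: %d events over %d samples\n",
              nEvents(object), nSamples(object)))
  cat(sprintf("event frequencies: min %.3f, median %.3f, max %.3f\n",
              min(p), stats::median(p), max(p)))
})

#' @describeIn TodagGraph-class node table
#' @param x a `TodagGraph`.
#' @export
setMethod("graphNodes", "TodagGraph", function(x) x@nodes)

#' @describeIn TodagGraph-class directed edge table
#' @export
setMethod("graphEdges", "TodagGraph", function(x) x@edges)

#' @describeIn TodagGraph-class undirected equal-frequency tie table
#' @export
setMethod("graphTies", "TodagGraph", function(x) x@ties)

#' @describeIn TodagGraph-class number of events (nodes)
#' @export
setMethod("nEvents", "TodagGraph", function(x) nrow(x@nodes))

#' @describeIn TodagGraph-class number of samples of the source matrix
#' @export
setMethod("nSamples", "TodagGraph", function(x) x@nSamples)

#' @describeIn TodagGraph-class event labels
#' @export
setMethod("eventIDs", "TodagGraph", function(x) x@nodes$event)

setMethod("show", "TodagGraph", function(object) {
  cat(sprintf("TodagGraph: %d nodes, %d directed edges, %d undirected ties\n",
              nrow(object@nodes), nrow(object@edges), nrow(object@ties)))
  if (nrow(object@edges)) {
    cat(sprintf("edge weights: [%.4f, %.4f]\n",
                min(object@edges$weight), max(object@edges$weight)))
    if (!all(is.na(object@edges$waiting_time)))
      cat(sprintf("waiting times sampled (seed %s); categories: %s\n",
                  object@seed,
                  paste(names(table(object@edges$speed_category)),
                        table(object@edges$speed_category),
                        sep = "=", collapse = ", ")))
  }
})

#' @describeIn GoldStandardAPG-class node labels (topological order)
#' @param x a `GoldStandardAPG`.
#' @export
setMethod("eventIDs", "GoldStandardAPG", function(x) x@nodeIDs)

#' @describeIn GoldStandardAPG-class directed gold edges
#' @export
setMethod("goldEdges", "GoldStandardAPG", function(x) x@edges)

#' @describeIn GoldStandardAPG-class per-node occurrence probabilities
#' @export
setMethod("nodeProb", "GoldStandardAPG", function(x) x@nodeProb)

setMethod("show", "GoldStandardAPG", function(object) {
  cat(sprintf("GoldStandardAPG: %d nodes, %d edges, root '%s'\n",
              length(object@nodeIDs), nrow(object@edges), object@root))
  if (!all(is.na(object@nodeProb)))
    cat(sprintf("node probabilities: [%.4f, %.4f]\n",
                min(object@nodeProb), max(object@nodeProb)))
  else cat("node probabilities: unassigned\n")
})

#' @describeIn BenchmarkResult-class AUROC value
#' @param x a `BenchmarkResult`.
#' @export
setMethod("auroc", "BenchmarkResult", function(x) x@auroc)

setMethod("show", "BenchmarkResult", function(object) {
  cat(sprintf("BenchmarkResult: AUROC %.4f over %d ordered pairs (%d gold edges)\n",
              object@auroc, object@nCandidatePairs, object@nGoldEdges))
  cat(sprintf("at the inferred-edge operating point: TP %d, FP %d, FN %d, TN %d\n",
              object@tp, object@fp, object@fn, object@tn))
})

.abbrevIDs <- function(ids, max = 6L) {
  if (length(ids) <= max) return(paste(ids, collapse = ", "))
  paste0(paste(ids[seq_len(max)], collapse = ", "), ", ... (",
         length(ids), " total)")
}
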
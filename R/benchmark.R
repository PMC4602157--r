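#' Run the APG gold-standard benchmark
#'
#' For each replicate: generate a random APG topology, assign probabilities by
#' multiplicative decay, sample a binary co-occurrence table, infer a TO-DAG
#' and score edge recovery by AUROC over all ordered node pairs. Replicate
#' seeds are derived deterministically from `seed` (replicate r uses
#' `seed * 1000 + r` offsets for the topology/probability/sampling/inference
#' stages), so a single master seed reproduces the whole run.
#'
#' @param nNodes,nEdges gold-standard size.
#' @param reps number of replicates.
#' @param nSamples samples per synthetic co-occurrence table.
#' @param seed master seed.
#' @param rootProb,decayRange probability-assignment parameters, see
#'   [assignProbabilities()].
#' @param config inference configuration.
#' @return A data.frame with one row per replicate (`rep`, `seed`, `auroc`,
#'   `n_gold_edges`, `n_inferred_edges`, `tp`, `fp`) plus attributes
#'   `mean_auroc` and `sd_auroc`.
#' @examples
#' \donttest{
#' b <- runBenchmark(10, 30, reps = 3, seed = 1)
#' attr(b, "mean_auroc")
#' }
#' @export
runBenchmark <- function(nNodes, nEdges, reps = 10L, nSamples = 100L,
                         seed = 1L, rootProb = 0.9,
                         decayRange = c(0.5, 0.9),
                         config = todagConfig()) {
  stopifnot(reps >= 1L)
  rows <- lapply(seq_len(reps), function(r) {
    base <- (seed * 1000L + r * 4L) %% .Machine$integer.max
    apg <- generateAPG(nNodes, nEdges, seed = base)
    apg <- assignProbabilities(apg, rootProb = rootProb,
                               decayRange = decayRange, seed = base + 1L)
    mat <- suppressWarnings(
      sampleCooccurrence(apg, nSamples = nSamples, seed = base + 2L))
    graph <- suppressWarnings(
      inferTodag(mat, config = config, seed = base + 3L))
    res <- edgeRecoveryAUROC(graph, apg)
    data.frame(rep = r, seed = base, auroc = res@auroc,
               n_gold_edges = res@nGoldEdges,
               n_inferred_edges = nrow(graphEdges(graph)),
               tp = res@tp, fp = res@fp)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_auroc") <- mean(out$auroc)
  attr(out, "sd_auroc") <- stats::sd(out$auroc)
  out
}
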
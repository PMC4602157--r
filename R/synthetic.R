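#' Random binary co-occurrence matrix
#'
#' Generates the uncorrelated random matrices used to characterize the
#' method's behaviour on structure-free input. With `exact = TRUE` each event
#' column receives exactly `round(frequency * nSamples)` ones at uniformly
#' sampled positions, pinning every event's frequency to the imposed value;
#' with `exact = FALSE` entries are i.i.d. Bernoulli(`frequency`), so column
#' frequencies fluctuate around the imposed value as they do under weighted
#' random sampling of entries. Exact mode makes all event frequencies equal,
#' and equal-frequency pairs are undirected ties under the exact-comparison
#' orientation rule — so graphs inferred from exact-mode matrices carry
#' tie pairs only; Bernoulli mode is the one that exercises directed-edge
#' behaviour (see the methods vignette).
#'
#' @param nSamples,nEvents dimensions.
#' @param frequency per-event mutation frequency in `[0,1]`.
#' @param seed integer seed or NULL.
#' @param exact exact per-column counts (default) or i.i.d. Bernoulli entries.
#' @return A [CooccurrenceMatrix-class] with samples `S1..` and events `E1..`.
#' @examples
#' colSums(as.matrix(randomBinaryMatrix(50, 4, 0.5, seed = 1)))  # all 25
#' @export
randomBinaryMatrix <- function(nSamples, nEvents, frequency = 0.5,
                               seed = NULL, exact = TRUE) {
  stopifnot(nSamples >= 1, nEvents >= 2, frequency >= 0, frequency <= 1)
  x <- withSeed(seed, {
    if (exact) {
      k <- round(frequency * nSamples)
      m <- matrix(0L, nSamples, nEvents)
      for (j in seq_len(nEvents))
        if (k > 0L) m[sample.int(nSamples, k), j] <- 1L
      m
    } else {
      matrix(as.integer(stats::runif(nSamples * nEvents) < frequency),
             nSamples, nEvents)
    }
  })
  dimnames(x) <- list(paste0("S", seq_len(nSamples)),
                      paste0("E", seq_len(nEvents)))
  CooccurrenceMatrix(x)
}

#' Lower-triangular co-occurrence matrix
#'
#' The nested design in which sample `i` carries events `1..i`: event `j` has
#' frequency `(n - j + 1) / n` and every event's support is nested in that of
#' all earlier events.
#'
#' @param n number of samples = number of events (`n >= 2`).
#' @return A [CooccurrenceMatrix-class].
#' @examples
#' as.matrix(triangularMatrix(3))
#' @export
triangularMatrix <- function(n) {
  stopifnot(n >= 2)
  x <- matrix(0L, n, n, dimnames = list(paste0("S", seq_len(n)),
                                        paste0("E", seq_len(n))))
  x[lower.tri(x, diag = TRUE)] <- 1L
  CooccurrenceMatrix(x)
}

#' Step-wise filled triangular matrix
#'
#' Starting from [triangularMatrix()], each step converts the first remaining
#' 0 of rows `1 .. n-1-step` into a 1, progressively raising every event's
#' mutation frequency until the matrix is entirely filled. `step = 0` is the
#' triangular matrix; `step = n - 1` is the all-ones matrix. After step
#' `n - 2` (the penultimate state) columns `1..n-1` are full of 1s and only
#' cell `(1, n)` is still 0, so all events but the last occur in every sample.
#'
#' @param n matrix size (`n >= 2`).
#' @param step number of fill steps already applied, in `0 .. n-1`.
#' @return A [CooccurrenceMatrix-class].
#' @examples
#' as.matrix(stepwiseFill(3, 1))
#' @export
stepwiseFill <- function(n, step) {
  stopifnot(n >= 2)
  if (step < 0 || step > n - 1) stop("step must be in 0 .. n-1")
  x <- as.matrix(triangularMatrix(n))
  s <- 0L
  while (s < step) {
    for (i in seq_len(n - 1L - s)) {
      zero <- which(x[i, ] == 0L)
      if (length(zero)) x[i, zero[[1L]]] <- 1L
    }
    s <- s + 1L
  }
  CooccurrenceMatrix(x)
}

## Build one block of a block-diagonal design.
.buildBlock <- function(spec, blockIndex) {
  stopifnot(is.list(spec), !is.null(spec$nSamples), !is.null(spec$nEvents))
  pattern <- if (is.null(spec$pattern)) "triangular" else spec$pattern
  if (pattern == "triangular") {
    if (spec$nSamples != spec$nEvents)
      stop("triangular blocks require nSamples == nEvents (block ",
           blockIndex, ")")
    as.matrix(triangularMatrix(spec$nSamples))
  } else if (pattern == "random") {
    freq <- if (is.null(spec$frequency)) 0.5 else spec$frequency
    as.matrix(randomBinaryMatrix(spec$nSamples, spec$nEvents, freq,
                                 seed = spec$seed,
                                 exact = !isFALSE(spec$exact)))
  } else stop("unknown block pattern '", pattern, "'")
}

#' Block-diagonal dataset of disjoint sample sets
#'
#' Emulates cohorts whose sub-types share no genetic event: each block's
#' samples carry only that block's events, all off-block entries are zero, so
#' cross-block joint probabilities vanish and inference must return one
#' sub-network per block.
#'
#' @param blockSpecs list (length `>= 2`) of per-block specs: each a list with
#'   `nSamples`, `nEvents`, optional `pattern` (`"triangular"`, the default,
#'   or `"random"`), `frequency`, `seed`, `exact`.
#' @return A [CooccurrenceMatrix-class] with consecutively numbered samples
#'   and events across blocks.
#' @examples
#' d <- disjointDataset(list(list(nSamples = 10, nEvents = 10),
#'                           list(nSamples = 10, nEvents = 10)))
#' dim(d)
#' @export
disjointDataset <- function(blockSpecs) {
  stopifnot(is.list(blockSpecs))
  if (length(blockSpecs) < 2L)
    stop("at least two blocks are required for a disjoint design")
  blocks <- lapply(seq_along(blockSpecs),
                   function(i) .buildBlock(blockSpecs[[i]], i))
  ns <- vapply(blocks, nrow, integer(1))
  ne <- vapply(blocks, ncol, integer(1))
  x <- matrix(0L, sum(ns), sum(ne))
  ro <- c(0L, cumsum(ns))
  co <- c(0L, cumsum(ne))
  for (i in seq_along(blocks))
    x[(ro[i] + 1L):ro[i + 1L], (co[i] + 1L):co[i + 1L]] <- blocks[[i]]
  dimnames(x) <- list(paste0("S", seq_len(nrow(x))),
                      paste0("E", seq_len(ncol(x))))
  CooccurrenceMatrix(x)
}

#' Disjoint blocks plus events shared by every sample set
#'
#' Appends to a [disjointDataset()] design `sharedEvents` extra event columns
#' positive in all samples of every block, emulating an early event common to
#' otherwise disjoint phenotypes. Inference should return that event as a
#' null-in-degree hub bridging the per-block sub-networks.
#'
#' @param blockSpecs as in [disjointDataset()].
#' @param sharedEvents number of shared event columns to append (0 reduces to
#'   the plain disjoint design).
#' @return A [CooccurrenceMatrix-class]; the shared events are the last
#'   `sharedEvents` columns.
#' @export
sharedEventDataset <- function(blockSpecs, sharedEvents = 1L) {
  stopifnot(sharedEvents >= 0L)
  if (sharedEvents == 0L) return(disjointDataset(blockSpecs))
  base <- as.matrix(disjointDataset(blockSpecs))
  shared <- matrix(1L, nrow(base), sharedEvents)
  x <- cbind(base, shared)
  dimnames(x) <- list(rownames(base), paste0("E", seq_len(ncol(x))))
  CooccurrenceMatrix(x)
}
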
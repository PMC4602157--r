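#' Draw exponential waiting times by inverse-transform sampling
#'
#' \eqn{\Delta t = -\ln(u)/\lambda} with `u` uniform on (0,1); the workhorse
#' behind [sampleWaitingTimes()], exposed so the sampling distribution can be
#' examined directly.
#'
#' @param n number of draws.
#' @param rate positive exponential rate(s), recycled to length `n`.
#' @param seed integer seed or NULL (use the ambient RNG).
#' @return Numeric vector of `n` non-negative waiting times.
#' @examples
#' mean(rWaitingTimes(1e4, rate = 0.25, seed = 1))  # close to 4
#' @export
rWaitingTimes <- function(n, rate, seed = NULL) {
  stopifnot(all(rate > 0))
  withSeed(seed, -log(stats::runif(n)) / rate)
}

#' Sample per-edge waiting times (step 5)
#'
#' Each edge receives an independent draw from an exponential distribution
#' whose rate is the edge's stored conditional probability
#' \eqn{\lambda = p_{target|source}}: strong conditional dependencies imply
#' short expected waits \eqn{1/\lambda}. Times are in arbitrary units.
#'
#' @param graph a [TodagGraph-class]; every edge must have `cond_prob > 0`.
#' @param seed integer seed for reproducible draws, or NULL.
#' @return The graph with the `waiting_time` edge column filled in and `seed`
#'   recorded.
#' @export
sampleWaitingTimes <- function(graph, seed = NULL) {
  stopifnot(is(graph, "TodagGraph"))
  edges <- graph@edges
  if (nrow(edges) == 0L) {
    graph@seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
    return(graph)
  }
  if (any(edges$cond_prob <= 0))
    stop("all retained edges must have cond_prob > 0 to serve as rates")
  edges$waiting_time <- rWaitingTimes(nrow(edges), edges$cond_prob, seed)
  graph@edges <- edges
  graph@seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  graph
}

#' Categorize edges by waiting time (step 6)
#'
#' Labels each edge `"fast"` (\eqn{\Delta t < t_1}), `"moderate"`
#' (\eqn{t_1 \le \Delta t \le t_2}) or `"slow"` (\eqn{\Delta t > t_2}). In
#' `"quantile"` mode the thresholds are the first and third quartiles of the
#' graph's own waiting-time distribution (linear interpolation between order
#' statistics); in `"absolute"` mode they come from the config (real-data
#' figures use 5 and 20 arbitrary units).
#'
#' @param graph a [TodagGraph-class] with sampled waiting times.
#' @param config a [TimingConfig-class].
#' @return The graph with the `speed_category` edge column filled in and the
#'   thresholds recorded in its `timing` slot.
#' @export
categorizeEdges <- function(graph, config = timingConfig()) {
  stopifnot(is(graph, "TodagGraph"), is(config, "TimingConfig"))
  edges <- graph@edges
  if (nrow(edges) == 0L) {
    warning("graph has no edges; nothing to categorize")
    return(graph)
  }
  if (anyNA(edges$waiting_time))
    stop("waiting times must be sampled before categorization")
  if (config@mode == "quantile") {
    qs <- stats::quantile(edges$waiting_time, c(0.25, 0.75), type = 7,
                          names = FALSE)
    t1 <- qs[[1L]]
    t2 <- qs[[2L]]
  } else {
    t1 <- config@t1
    t2 <- config@t2
  }
  wt <- edges$waiting_time
  edges$speed_category <- ifelse(wt < t1, "fast",
                                 ifelse(wt > t2, "slow", "moderate"))
  graph@edges <- edges
  graph@timing <- list(mode = config@mode, t1 = t1, t2 = t2,
                       quantileConvention = config@quantileConvention)
  graph
}

#' Transition-speed summary by node class
#'
#' Tabulates, for each pair of node classes (e.g. point mutation, loss, gain,
#' break-point), the number of edges between the classes and the percentage of
#' fast, moderate and slow transitions among them.
#'
#' @param graph a [TodagGraph-class] with speed categories assigned.
#' @param nodeClasses named character vector mapping every event id to a class
#'   label.
#' @param ordered if FALSE (default) class pairs are merged regardless of edge
#'   direction (the `A<->B` rows of the published tables); if TRUE, rows are
#'   ordered (source class, target class) pairs.
#' @return A data.frame with columns `class1`, `class2` (or `source_class`,
#'   `target_class` when `ordered`), `n_edges`, `pct_fast`, `pct_moderate`,
#'   `pct_slow`; percentages sum to 100 per row, and empty class pairs are
#'   absent.
#' @export
transitionSpeedSummary <- function(graph, nodeClasses, ordered = FALSE) {
  stopifnot(is(graph, "TodagGraph"))
  edges <- graph@edges
  if (nrow(edges) == 0L) stop("graph has no edges")
  if (anyNA(edges$speed_category))
    stop("speed categories must be assigned first")
  unmapped <- setdiff(unique(c(edges$source, edges$target)),
                      names(nodeClasses))
  if (length(unmapped))
    stop("unmapped node(s): ", paste(unmapped, collapse = ", "))
  sc <- nodeClasses[edges$source]
  tc <- nodeClasses[edges$target]
  if (ordered) {
    key <- paste(sc, tc, sep = "\r")
  } else {
    key <- paste(pmin(sc, tc), pmax(sc, tc), sep = "\r")
  }
  rows <- lapply(split(seq_len(nrow(edges)), key), function(i) {
    cats <- edges$speed_category[i]
    n <- length(i)
    parts <- strsplit(key[i[[1L]]], "\r", fixed = TRUE)[[1L]]
    data.frame(class1 = parts[[1L]], class2 = parts[[2L]], n_edges = n,
               pct_fast = 100 * sum(cats == "fast") / n,
               pct_moderate = 100 * sum(cats == "moderate") / n,
               pct_slow = 100 * sum(cats == "slow") / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (ordered)
    names(out)[1:2] <- c("source_class", "target_class")
  rownames(out) <- NULL
  out
}
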
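## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's .Random.seed is restored afterwards. seed = NULL uses (and
## advances) the ambient RNG.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

## Resolve event identifiers (names or indices) against a label vector.
resolveEvents <- function(events, ids) {
  if (is.character(events)) {
    idx <- match(events, ids)
    if (anyNA(idx))
      stop("unknown event(s): ", paste(events[is.na(idx)], collapse = ", "))
    return(idx)
  }
  events <- as.integer(events)
  if (any(events < 1L | events > length(ids)))
    stop("event index out of range")
  events
}

## Canonical empty edge data.frame used across the package.
emptyEdgeFrame <- function() {
  data.frame(source = character(), target = character(), weight = numeric(),
             cond_prob = numeric(), source_count = integer(),
             target_count = integer(), joint_count = integer(),
             path_joint = numeric(), waiting_time = numeric(),
             speed_category = character(), stringsAsFactors = FALSE)
}

emptyTieFrame <- function() {
  data.frame(event1 = character(), event2 = character(),
             joint_count = integer(), stringsAsFactors = FALSE)
}
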
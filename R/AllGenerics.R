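#' Accessor generics
#'
#' Small accessor family for the package's S4 containers.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @return `sampleIDs`: character vector of sample labels.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname accessors
#' @return `eventIDs`: character vector of event labels.
#' @export
setGeneric("eventIDs", function(x) standardGeneric("eventIDs"))

#' @rdname accessors
#' @return `nSamples`: integer sample count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @return `nEvents`: integer event count.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname accessors
#' @return `eventProb`: named numeric vector of exact event frequencies.
#' @export
setGeneric("eventProb", function(x) standardGeneric("eventProb"))

#' @rdname accessors
#' @return `jointProb`: symmetric numeric matrix of pairwise co-occurrence
#'   frequencies (diagonal = event frequencies).
#' @export
setGeneric("jointProb", function(x) standardGeneric("jointProb"))

#' @rdname accessors
#' @return `graphNodes`: data.frame of nodes (event, count, prob).
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname accessors
#' @return `graphEdges`: data.frame of directed edges with their attributes.
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname accessors
#' @return `graphTies`: data.frame of undirected equal-frequency ties.
#' @export
setGeneric("graphTies", function(x) standardGeneric("graphTies"))

#' @rdname accessors
#' @return `goldEdges`: data.frame of gold-standard directed edges
#'   (parent, child).
#' @export
setGeneric("goldEdges", function(x) standardGeneric("goldEdges"))

#' @rdname accessors
#' @return `nodeProb`: named numeric vector of gold-standard node
#'   probabilities.
#' @export
setGeneric("nodeProb", function(x) standardGeneric("nodeProb"))

#' @rdname accessors
#' @return `auroc`: numeric AUROC value.
#' @export
setGeneric("auroc", function(x) standardGeneric("auroc"))
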
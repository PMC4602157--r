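.sepForPath <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a co-occurrence matrix from delimited text
#'
#' Expects one header row of labels and one leading label column. The
#' delimiter is auto-detected from the extension (`.csv` comma, otherwise
#' tab) unless given. Regardless of the on-disk orientation the returned
#' object is in canonical samples-in-rows form.
#'
#' @param path file path.
#' @param orientation `"samples-rows"` (default; header = event labels) or
#'   `"events-rows"` (transposed on disk; header = sample labels).
#' @param sep field delimiter override.
#' @return A [CooccurrenceMatrix-class].
#' @seealso [writeCooccurrence()]
#' @export
readCooccurrence <- function(path,
                             orientation = c("samples-rows", "events-rows"),
                             sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sepForPath(path, sep)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("file must contain a header row and data rows")
  parts <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(parts)
  bodyWidth <- widths[[2L]]
  if (any(widths[-1L] != bodyWidth))
    stop("ragged rows: row widths differ (rows ",
         paste(which(widths[-1L] != bodyWidth) + 1L, collapse = ", "), ")")
  header <- parts[[1L]]
  ## the corner cell above the label column is optional
  if (length(header) == bodyWidth) header <- header[-1L]
  else if (length(header) != bodyWidth - 1L)
    stop("header width does not match data rows")
  rowLabels <- vapply(parts[-1L], `[[`, character(1), 1L)
  colLabels <- header
  if (anyDuplicated(rowLabels))
    stop("duplicate row label(s): ",
         paste(unique(rowLabels[duplicated(rowLabels)]), collapse = ", "))
  if (anyDuplicated(colLabels))
    stop("duplicate column label(s): ",
         paste(unique(colLabels[duplicated(colLabels)]), collapse = ", "))
  cells <- t(vapply(parts[-1L], function(p) p[-1L],
                    character(bodyWidth - 1L)))
  cells <- matrix(cells, nrow = length(rowLabels))  # guard 2-column case
  bad <- which(matrix(!(cells %in% c("0", "1")), nrow = nrow(cells)),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-binary value '%s' at row '%s', column '%s'",
                 cells[bad[1L, , drop = FALSE]],
                 rowLabels[bad[1L, 1L]], colLabels[bad[1L, 2L]]))
  x <- matrix(as.integer(cells), nrow = length(rowLabels),
              dimnames = list(rowLabels, colLabels))
  if (orientation == "events-rows") x <- t(x)
  CooccurrenceMatrix(x)
}

#' Write a co-occurrence matrix as delimited text
#'
#' Writes in canonical samples-in-rows orientation with a header row of event
#' labels (corner cell `sample_id`); [readCooccurrence()] round-trips the file
#' to an identical matrix.
#'
#' @param matrix a [CooccurrenceMatrix-class].
#' @param path output path (`.csv` switches the delimiter to comma).
#' @param sep field delimiter override.
#' @return Invisibly, `path`.
#' @export
writeCooccurrence <- function(matrix, path, sep = NULL) {
  stopifnot(is(matrix, "CooccurrenceMatrix"))
  validObject(matrix)
  sep <- .sepForPath(path, sep)
  x <- matrix@occurrence
  lines <- c(paste(c("sample_id", colnames(x)), collapse = sep),
             vapply(seq_len(nrow(x)), function(i)
               paste(c(rownames(x)[i], x[i, ]), collapse = sep),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

.speedColor <- c(fast = "green", moderate = "orange", slow = "red")

#' Export an inferred graph to GraphML
#'
#' Writes a GraphML 1.0 document with node attributes `label` and
#' `probability` and edge attributes `weight`, `conditional_probability`,
#' `waiting_time` and `speed_category` (the latter two only when present),
#' plus an auxiliary `color` attribute following the green/orange/red
#' fast/moderate/slow convention.
#'
#' @param graph a [TodagGraph-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGraphML <- function(graph, path) {
  stopifnot(is(graph, "TodagGraph"))
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    c(id = "label", for. = "node", name = "label", type = "string"),
    c(id = "probability", for. = "node", name = "probability",
      type = "double"),
    c(id = "weight", for. = "edge", name = "weight", type = "double"),
    c(id = "conditional_probability", for. = "edge",
      name = "conditional_probability", type = "double"),
    c(id = "waiting_time", for. = "edge", name = "waiting_time",
      type = "double"),
    c(id = "speed_category", for. = "edge", name = "speed_category",
      type = "string"),
    c(id = "color", for. = "edge", name = "color", type = "string"))
  for (k in keys)
    xml2::xml_add_child(doc, "key", id = k[["id"]], "for" = k[["for."]],
                        "attr.name" = k[["name"]], "attr.type" = k[["type"]])
  g <- xml2::xml_add_child(doc, "graph", id = "TO-DAG",
                           edgedefault = "directed")
  nodes <- graph@nodes
  nid <- stats::setNames(paste0("n", seq_len(nrow(nodes)) - 1L), nodes$event)
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = nid[[i]])
    xml2::xml_add_child(nd, "data", key = "label", nodes$event[[i]])
    xml2::xml_add_child(nd, "data", key = "probability",
                        format(nodes$prob[[i]], digits = 15))
  }
  e <- graph@edges
  for (i in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(g, "edge",
                              source = nid[[e$source[[i]]]],
                              target = nid[[e$target[[i]]]])
    xml2::xml_add_child(ed, "data", key = "weight",
                        format(e$weight[[i]], digits = 15))
    xml2::xml_add_child(ed, "data", key = "conditional_probability",
                        format(e$cond_prob[[i]], digits = 15))
    if (!is.na(e$waiting_time[[i]]))
      xml2::xml_add_child(ed, "data", key = "waiting_time",
                          format(e$waiting_time[[i]], digits = 15))
    if (!is.na(e$speed_category[[i]])) {
      xml2::xml_add_child(ed, "data", key = "speed_category",
                          e$speed_category[[i]])
      xml2::xml_add_child(ed, "data", key = "color",
                          .speedColor[[e$speed_category[[i]]]])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export an edge table as TSV
#'
#' Writes columns `source`, `target`, `weight`, `conditional_probability`,
#' `waiting_time`, `speed_category`, restricted to edges with
#' `weight >= minWeight`.
#'
#' @param graph a [TodagGraph-class].
#' @param path output path.
#' @param minWeight weight threshold in `[0, 1]` (and beyond: a threshold
#'   above 1 yields an empty table).
#' @return Invisibly, `path`.
#' @export
writeEdgeTable <- function(graph, path, minWeight = 0) {
  stopifnot(is(graph, "TodagGraph"), minWeight >= 0)
  e <- graph@edges[graph@edges$weight >= minWeight, , drop = FALSE]
  out <- data.frame(source = e$source, target = e$target, weight = e$weight,
                    conditional_probability = e$cond_prob,
                    waiting_time = e$waiting_time,
                    speed_category = e$speed_category,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an APG gold standard as TSV
#'
#' The edge list carries columns `parent`, `child`; the node table carries
#' `node`, `probability` in topological order (root first).
#'
#' @param apg a [GoldStandardAPG-class].
#' @param edgePath,nodePath output (or input) paths.
#' @return `writeGoldStandard`: invisibly `edgePath`; `readGoldStandard`: a
#'   [GoldStandardAPG-class].
#' @export
writeGoldStandard <- function(apg, edgePath, nodePath) {
  stopifnot(is(apg, "GoldStandardAPG"))
  utils::write.table(apg@edges, edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(node = apg@nodeIDs, probability = apg@nodeProb[apg@nodeIDs]),
    nodePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edgePath)
}

#' @rdname writeGoldStandard
#' @export
readGoldStandard <- function(edgePath, nodePath) {
  edges <- utils::read.table(edgePath, sep = "\t", header = TRUE,
                             colClasses = "character")
  nodes <- utils::read.table(nodePath, sep = "\t", header = TRUE,
                             colClasses = c("character", "numeric"))
  ids <- nodes$node
  root <- setdiff(ids, edges$child)
  if (length(root) != 1L)
    stop("gold standard must have exactly one root (in-degree-0 node)")
  new("GoldStandardAPG", nodeIDs = ids, root = root,
      edges = data.frame(parent = edges$parent, child = edges$child,
                         stringsAsFactors = FALSE),
      nodeProb = stats::setNames(nodes$probability, ids),
      pathJoint = stats::setNames(nodes$probability, ids))
}
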
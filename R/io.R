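#' Read a graph from a plain-text edge list
#'
#' Each non-blank, non-comment line names one edge by its two endpoint
#' labels. Lines starting with `#` are comments. Fields are separated by
#' whitespace and/or commas unless an explicit delimiter is given. Extra
#' fields after the first two (e.g. weights) are ignored.
#'
#' @param path path to the edge-list file.
#' @param delimiter optional single delimiter; default splits on any run of
#'   whitespace or commas.
#' @param simplify drop (and count) loops and duplicate edges instead of
#'   raising an error.
#' @return a [netgraph][graph_from_edges].
#' @export
read_edge_list <- function(path, delimiter = NULL, simplify = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop(sprintf("no edges in %s", path))
  split_re <- if (is.null(delimiter)) "[,[:space:]]+" else delimiter
  parts <- strsplit(trimws(lines[idx]), split_re)
  bad <- which(vapply(parts, length, integer(1L)) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: need two node labels, got '%s'",
                 idx[bad[1L]], path, lines[idx[bad[1L]]]))
  }
  edges <- cbind(vapply(parts, `[`, character(1L), 1L),
                 vapply(parts, `[`, character(1L), 2L))
  graph_from_edges(edges, simplify = simplify)
}

#' Write a graph as a plain-text edge list
#'
#' @param g a `netgraph`.
#' @param path output file path.
#' @param delimiter field separator, default a single space.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, delimiter = " ") {
  em <- edge_matrix(g)
  writeLines(paste(em[, 1L], em[, 2L], sep = delimiter), path)
  invisible(path)
}

#' GraphML input and output
#'
#' Minimal GraphML support for interoperability: `read_graphml()` reads the
#' first `<graph>` element's nodes and edges (edge direction is ignored; the
#' result is simplified), `write_graphml()` writes an undirected graph.
#'
#' @param path file path.
#' @param g a `netgraph`.
#' @return `read_graphml()` a `netgraph`; `write_graphml()` `path`, invisibly.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  edges <- xml2::xml_find_all(doc, ".//g:graph/g:edge", ns)
  if (length(edges) == 0L) stop(sprintf("no edges in %s", path))
  graph_from_edges(cbind(xml2::xml_attr(edges, "source"),
                         xml2::xml_attr(edges, "target")),
                   simplify = TRUE)
}

#' @rdname read_graphml
#' @export
write_graphml <- function(g, path) {
  stopifnot(inherits(g, "netgraph"))
  em <- edge_matrix(g)
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  gr <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (lab in g$labels) xml2::xml_add_child(gr, "node", id = lab)
  for (k in seq_len(nrow(em))) {
    xml2::xml_add_child(gr, "edge", source = em[k, 1L], target = em[k, 2L])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export per-node values as CSV or JSON
#'
#' @param x a data frame (e.g. from [all_centralities()]).
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
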
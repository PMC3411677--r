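#' Write a network as tab-separated edge list and node table
#'
#' Edge list columns: \code{source_id}, \code{target_id}; node table
#' columns: \code{node_id}, \code{row}, \code{col}, \code{is_focal}. Node
#' ids are 0-based integers; each edge is stored with the smaller id first.
#' The node table preserves isolated nodes, which an edge list alone cannot.
#'
#' @param net a \code{"specnet"} object.
#' @param edges_path path for the edge list TSV.
#' @param nodes_path optional path for the node table TSV.
#' @return \code{net}, invisibly.
#' @export
write_edgelist <- function(net, edges_path, nodes_path = NULL) {
  e <- net$edges - 1L
  utils::write.table(
    data.frame(source_id = e[, 1], target_id = e[, 2]),
    edges_path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(nodes_path)) {
    co <- net$coords
    if (is.null(co)) co <- matrix(NA_integer_, net$n, 2)
    fo <- net$focal
    if (is.null(fo)) fo <- rep(FALSE, net$n)
    utils::write.table(
      data.frame(node_id = seq_len(net$n) - 1L, row = co[, 1],
                 col = co[, 2], is_focal = as.integer(fo)),
      nodes_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(net)
}

#' Read a network from an edge list (and optional node table)
#'
#' Inverse of [write_edgelist()]. Without a node table the node count is
#' inferred as \code{max(id) + 1}, so trailing isolated nodes need the node
#' table to survive a round-trip. Malformed lines, self-loops and duplicate
#' edges are rejected with the offending line number.
#'
#' @param edges_path edge list TSV (\code{source_id}, \code{target_id},
#'   0-based).
#' @param nodes_path optional node table TSV.
#' @return a \code{"specnet"} object.
#' @export
read_edgelist <- function(edges_path, nodes_path = NULL) {
  e <- utils::read.delim(edges_path)
  if (!all(c("source_id", "target_id") %in% names(e)))
    stop("edge list must have columns source_id, target_id")
  bad <- which(is.na(e$source_id) | is.na(e$target_id) |
                 e$source_id < 0 | e$target_id < 0)
  if (length(bad))
    stop("malformed edge at line ", bad[1] + 1L)
  loops <- which(e$source_id == e$target_id)
  if (length(loops)) stop("self-loop at line ", loops[1] + 1L)
  key <- paste(pmin(e$source_id, e$target_id),
               pmax(e$source_id, e$target_id))
  dup <- which(duplicated(key))
  if (length(dup)) stop("duplicate edge at line ", dup[1] + 1L)

  coords <- NULL; focal <- NULL
  if (!is.null(nodes_path)) {
    nt <- utils::read.delim(nodes_path)
    n <- nrow(nt)
    if (nrow(e) && max(e$source_id, e$target_id) >= n)
      stop("edge references a node id absent from the node table")
    if (all(c("row", "col") %in% names(nt)) && !anyNA(nt$row))
      coords <- cbind(row = nt$row, col = nt$col)
    if ("is_focal" %in% names(nt)) focal <- nt$is_focal != 0
  } else {
    n <- if (nrow(e)) max(e$source_id, e$target_id) + 1L else 0L
  }
  as_specnet(n, cbind(e$source_id, e$target_id) + 1L,
             coords = coords, focal = focal)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a network as GraphML
#'
#' Writes the full attributed graph (coordinates and focal flag as node
#' attributes) in GraphML, readable by standard network software.
#'
#' @param net a \code{"specnet"} object.
#' @param path output path.
#' @return \code{net}, invisibly.
#' @export
write_graphml <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns"')
  w('  xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance"')
  w('  xsi:schemaLocation="http://graphml.graphdrawing.org/xmlns http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd">')
  w('  <key id="d0" for="node" attr.name="row" attr.type="int"/>')
  w('  <key id="d1" for="node" attr.name="col" attr.type="int"/>')
  w('  <key id="d2" for="node" attr.name="is_focal" attr.type="boolean"/>')
  w('  <graph id="G" edgedefault="undirected">')
  co <- net$coords
  fo <- if (is.null(net$focal)) rep(FALSE, net$n) else net$focal
  for (v in seq_len(net$n)) {
    w('    <node id="n%d">', v - 1L)
    if (!is.null(co)) {
      w('      <data key="d0">%d</data>', co[v, 1])
      w('      <data key="d1">%d</data>', co[v, 2])
    }
    w('      <data key="d2">%s</data>', if (fo[v]) "true" else "false")
    w('    </node>')
  }
  if (nrow(net$edges))
    for (t in seq_len(nrow(net$edges)))
      w('    <edge source="n%d" target="n%d"/>',
        net$edges[t, 1] - 1L, net$edges[t, 2] - 1L)
  w('  </graph>')
  w('</graphml>')
  invisible(net)
}

#' Catalogue of small test graphs with known measure values
#'
#' Deterministic toy graphs whose structure measures are known in closed
#' form, for validating the measure implementations: a triangle, paths, a
#' star, cycles, a chorded 4-cycle and two-component graphs. Each element
#' is a \code{"specnet"} with an \code{oracle} field holding the exact
#' expected measures (\code{NA} where undefined).
#'
#' @return named list of \code{"specnet"} objects.
#' @export
#' @examples
#' fx <- fixture_graphs()
#' fx$star4$oracle$assortativity  # -1
fixture_graphs <- function() {
  mk <- function(n, edges, clustering, assortativity, fragmentation) {
    g <- as_specnet(n, edges)
    g$oracle <- list(clustering = clustering, assortativity = assortativity,
                     fragmentation = fragmentation,
                     mean_degree = 2 * nrow(g$edges) / n)
    g
  }
  list(
    triangle = mk(3, rbind(c(1, 2), c(2, 3), c(1, 3)), 1, NA, 0),
    path3 = mk(3, rbind(c(1, 2), c(2, 3)), 0, -1, 0),
    path5 = mk(5, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)), 0, -1 / 3, 0),
    star4 = mk(4, rbind(c(1, 2), c(1, 3), c(1, 4)), 0, -1, 0),
    cycle4 = mk(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), 0, NA, 0),
    cycle5 = mk(5, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1)),
                0, NA, 0),
    # 4-cycle A-B-C-D plus chord A-C: local c = (2/3, 1, 2/3, 1)
    chorded4 = mk(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3)),
                  5 / 6, -2 / 3, 0),
    # triangle plus disjoint edge: every edge joins equal degrees
    tri_plus_edge = mk(5, rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5)),
                       3 / 5, 1, 1 - 8 / 20),
    # components {3, 2} as a path + edge
    frag32 = mk(5, rbind(c(1, 2), c(2, 3), c(4, 5)), 0, -1 / 2, 0.6),
    edgeless5 = mk(5, matrix(integer(0), 0, 2), 0, NA, 1)
  )
}
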
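#' Export the connectome for visualisation
#'
#' Writers for the standard interchange formats: a weighted edge-list CSV
#' (`from,to,weight,ipsi,contra[,display_weight]`), an adjacency-matrix
#' CSV, GraphML, and GEXF (for Gephi). Node attributes present on the graph
#' (e.g. `module`, `pc`, `wmdz`, `hub` as attached by
#' [annotate_connectome()]) are carried into GraphML/GEXF so module colour,
#' PC-scaled node size and weight-scaled edge thickness can be mapped in
#' the viewer.
#'
#' @param g Connectome graph.
#' @param path Output file path.
#' @return The graph, invisibly.
#' @name connectome_export
#' @export
write_edge_list <- function(g, path) {
  df <- igraph::as_data_frame(g, what = "edges")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(g)
}

#' @rdname connectome_export
#' @export
write_adjacency <- function(g, path) {
  A <- connectome_weights(g)
  utils::write.csv(A, path, row.names = TRUE, quote = FALSE)
  invisible(g)
}

#' @rdname connectome_export
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}

#' @rdname connectome_export
#' @export
write_gexf <- function(g, path) {
  nodes <- igraph::V(g)$name
  vattrs <- setdiff(igraph::vertex_attr_names(g), "name")
  eattr <- igraph::as_data_frame(g, what = "edges")
  gexf_type <- function(v) {
    if (is.logical(v)) "boolean" else if (is.numeric(v)) "double" else "string"
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://gexf.net/1.3" version="1.3">')
  w('  <graph defaultedgetype="directed" mode="static">')
  if (length(vattrs)) {
    w('    <attributes class="node">')
    for (i in seq_along(vattrs)) {
      w('      <attribute id="%d" title="%s" type="%s"/>', i - 1L,
        esc(vattrs[i]), gexf_type(igraph::vertex_attr(g, vattrs[i])))
    }
    w('    </attributes>')
  }
  w('    <nodes>')
  for (i in seq_along(nodes)) {
    if (length(vattrs)) {
      w('      <node id="%s" label="%s">', esc(nodes[i]), esc(nodes[i]))
      w('        <attvalues>')
      for (j in seq_along(vattrs)) {
        v <- igraph::vertex_attr(g, vattrs[j])[i]
        w('          <attvalue for="%d" value="%s"/>', j - 1L,
          esc(format(v, scientific = FALSE)))
      }
      w('        </attvalues>')
      w('      </node>')
    } else {
      w('      <node id="%s" label="%s"/>', esc(nodes[i]), esc(nodes[i]))
    }
  }
  w('    </nodes>')
  w('    <edges>')
  if (nrow(eattr)) {
    for (i in seq_len(nrow(eattr))) {
      w('      <edge id="%d" source="%s" target="%s" weight="%s"/>',
        i - 1L, esc(eattr$from[i]), esc(eattr$to[i]),
        format(eattr$weight[i], scientific = FALSE))
    }
  }
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
  invisible(g)
}

#' Attach role annotations to the connectome graph
#'
#' Copies the columns of a [node_roles()] table onto the graph as vertex
#' attributes (`module`, `degree`, `strength`, `wmdz`, `pc`, `role`,
#' `hub`), so exports carry them.
#'
#' @param g Connectome graph.
#' @param roles A [node_roles()] table over the same nodes.
#' @return The annotated graph.
#' @export
annotate_connectome <- function(g, roles) {
  idx <- match(igraph::V(g)$name, roles$node)
  if (any(is.na(idx))) stop_input("roles table does not cover all nodes")
  for (col in setdiff(names(roles), "node")) {
    g <- igraph::set_vertex_attr(g, col, value = roles[[col]][idx])
  }
  g
}
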
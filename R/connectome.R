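#' Validate a long-format cell-count table
#'
#' A count table has one row per (injection region, source region, side)
#' with a non-negative integer cell count; `side` is `ipsi` or `contra`
#' relative to the injection site. Self-pairs (injection == source) are
#' rejected, as are duplicate (injection, source, side) rows.
#'
#' @param counts data.frame with columns `injection, source, side, count`.
#' @return The validated data.frame, invisibly usable downstream.
#' @export
validate_counts <- function(counts) {
  req <- c("injection", "source", "side", "count")
  if (!all(req %in% names(counts))) {
    stop_input("count table needs columns: ", paste(req, collapse = ", "))
  }
  if (!all(counts$side %in% c("ipsi", "contra"))) {
    stop_input("'side' must be 'ipsi' or 'contra'")
  }
  if (any(!is.finite(counts$count)) || any(counts$count < 0)) {
    stop_input("counts must be non-negative and finite")
  }
  self <- counts$injection == counts$source
  if (any(self)) {
    stop_input("self-pairs are not allowed (injection == source): ",
               paste(unique(counts$injection[self]), collapse = ", "))
  }
  key <- paste(counts$injection, counts$source, counts$side)
  if (anyDuplicated(key)) {
    stop_input("duplicate (injection, source, side) rows: ",
               paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  counts
}

#' Build the directed weighted connectome from a count table
#'
#' Applies the retrograde-tracing convention: a row
#' `(injection = B, source = A, count = c)` means `c` retrogradely labeled
#' cells were found in region A after an injection in region B, i.e. region
#' A projects to region B — an edge A -> B with weight contribution `c`.
#' Ipsilateral and contralateral contributions are summed into the edge
#' weight and preserved separately as edge attributes `ipsi` and `contra`.
#' Ordered pairs with total count 0 carry no edge, so unweighted degree
#' counts real projections.
#'
#' @param counts A count table (see [validate_counts()]).
#' @param node_set Ordered character vector of region names; every region
#'   appearing in `counts` must be listed. Default [vsb_regions()].
#' @return A directed [igraph::igraph] graph with edge attributes `weight`,
#'   `ipsi`, `contra`.
#' @export
#' @examples
#' counts <- data.frame(injection = "B", source = "A",
#'                      side = "ipsi", count = 12)
#' g <- build_connectome(counts, node_set = c("A", "B"))
#' igraph::E(g)$weight
build_connectome <- function(counts, node_set = vsb_regions()) {
  counts <- validate_counts(counts)
  unknown <- setdiff(unique(c(counts$injection, counts$source)), node_set)
  if (length(unknown)) {
    stop_input("regions absent from the node set: ",
               paste(unknown, collapse = ", "))
  }
  if (nrow(counts) == 0) {
    return(igraph::make_empty_graph(directed = TRUE) +
             igraph::vertices(node_set))
  }
  # projection source -> target(=injection); aggregate the two sides
  key <- paste(counts$source, counts$injection, sep = "\r")
  ipsi <- tapply(ifelse(counts$side == "ipsi", counts$count, 0), key, sum)
  contra <- tapply(ifelse(counts$side == "contra", counts$count, 0), key, sum)
  parts <- do.call(rbind, strsplit(names(ipsi), "\r", fixed = TRUE))
  edges <- data.frame(from = parts[, 1], to = parts[, 2],
                      weight = as.numeric(ipsi + contra),
                      ipsi = as.numeric(ipsi), contra = as.numeric(contra),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$weight > 0, , drop = FALSE]
  edges <- edges[order(match(edges$from, node_set),
                       match(edges$to, node_set)), , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = node_set)
}

#' Classify directed region pairs as absent, unidirectional or bidirectional
#'
#' Over all `n * (n - 1)` ordered region pairs (a, b): the pair is
#' *bidirectional* if both a -> b and b -> a exist, *unidirectional* if
#' a -> b exists but b -> a does not, and *absent* if a -> b does not exist.
#' The three classes always sum to the number of possible ordered pairs.
#'
#' @param g A connectome graph from [build_connectome()].
#' @return A list: `possible`, `absent`, `unidirectional`, `bidirectional`.
#' @export
classify_dyads <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) stop_input("need at least 2 nodes")
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
  diag(A) <- FALSE
  both <- A & t(A)
  one <- A & !t(A)
  possible <- n * (n - 1)
  bidirectional <- sum(both)
  unidirectional <- sum(one)
  list(possible = possible,
       absent = possible - bidirectional - unidirectional,
       unidirectional = unidirectional,
       bidirectional = bidirectional)
}

#' Unweighted node degree (projection counts)
#'
#' Afferent degree counts incoming projections, efferent degree outgoing
#' projections; each existing edge counts 1 regardless of weight. `side`
#' restricts to edges with a nonzero ipsilateral or contralateral
#' component.
#'
#' @param g Connectome graph.
#' @param nodes Nodes to report (default all).
#' @param side `"total"`, `"ipsi"` or `"contra"`.
#' @return data.frame `node, afferent, efferent, total`.
#' @export
node_degree_unweighted <- function(g, nodes = NULL,
                                   side = c("total", "ipsi", "contra")) {
  side <- match.arg(side)
  nodes <- nodes %||% igraph::V(g)$name
  if (!all(nodes %in% igraph::V(g)$name)) {
    stop_input("unknown node(s): ",
               paste(setdiff(nodes, igraph::V(g)$name), collapse = ", "))
  }
  h <- if (side == "total") g else {
    igraph::subgraph_from_edges(
      g, igraph::E(g)[igraph::edge_attr(g, side) > 0],
      delete.vertices = FALSE)
  }
  aff <- igraph::degree(h, v = nodes, mode = "in")
  eff <- igraph::degree(h, v = nodes, mode = "out")
  data.frame(node = nodes, afferent = as.integer(aff),
             efferent = as.integer(eff),
             total = as.integer(aff + eff), row.names = NULL)
}

#' Weighted node strength (summed cell counts)
#'
#' Afferent strength sums the weights (cell counts) of incoming
#' projections, efferent strength the outgoing ones; total strength is
#' their sum ("degree of strength").
#'
#' @inheritParams node_degree_unweighted
#' @return data.frame `node, afferent, efferent, total`.
#' @export
node_strength <- function(g, nodes = NULL,
                          side = c("total", "ipsi", "contra")) {
  side <- match.arg(side)
  nodes <- nodes %||% igraph::V(g)$name
  if (!all(nodes %in% igraph::V(g)$name)) {
    stop_input("unknown node(s): ",
               paste(setdiff(nodes, igraph::V(g)$name), collapse = ", "))
  }
  w <- if (side == "total") igraph::E(g)$weight else
    igraph::edge_attr(g, side)
  aff <- igraph::strength(g, vids = nodes, mode = "in", weights = w)
  eff <- igraph::strength(g, vids = nodes, mode = "out", weights = w)
  data.frame(node = nodes, afferent = as.numeric(aff),
             efferent = as.numeric(eff),
             total = as.numeric(aff + eff), row.names = NULL)
}

#' Map edge counts to a bounded display weight
#'
#' For visualisation, each edge's raw count is mapped linearly onto
#' `[0, w_max]` by `w_max * count / max(count)` (the heaviest edge gets
#' `w_max`, default 0.9). Raw counts are retained in `weight`; the display
#' value is stored in edge attribute `display_weight`. The mapping is
#' monotone: a heavier projection is never drawn thinner.
#'
#' @param g Connectome graph with at least one edge.
#' @param w_max Upper end of the display range (> 0), default 0.9.
#' @return The graph with a `display_weight` edge attribute added.
#' @export
scale_edge_weights <- function(g, w_max = 0.9) {
  check_scalar_number(w_max, "w_max", min = 0, strict_min = TRUE)
  if (igraph::ecount(g) == 0) {
    stop_input("graph has no edges; nothing to scale")
  }
  w <- igraph::E(g)$weight
  igraph::E(g)$display_weight <- w_max * w / max(w)
  g
}

#' Radial innervation summary for one injected region
#'
#' Summarises the afferent counts of one injection: per source region,
#' ipsilateral and contralateral counts grouped by anatomical group and
#' ordered from least to greatest total innervation within each group (ties
#' broken alphabetically). Sources with zero total count are omitted.
#'
#' @param counts Count table.
#' @param injection Injected region to summarise.
#' @param region_groups data.frame `region, group` (default
#'   [vsb_region_groups()]).
#' @return data.frame `group, source, ipsi, contra, total`, ordered.
#' @export
radial_summary <- function(counts, injection,
                           region_groups = vsb_region_groups()) {
  counts <- validate_counts(counts)
  if (!injection %in% counts$injection) {
    stop_input("injection '", injection, "' not present in the count table")
  }
  sub <- counts[counts$injection == injection, , drop = FALSE]
  unknown <- setdiff(unique(sub$source), region_groups$region)
  if (length(unknown)) {
    stop_input("no group mapping for region(s): ",
               paste(unknown, collapse = ", "))
  }
  ip <- tapply(ifelse(sub$side == "ipsi", sub$count, 0), sub$source, sum)
  co <- tapply(ifelse(sub$side == "contra", sub$count, 0), sub$source, sum)
  out <- data.frame(source = names(ip), ipsi = as.numeric(ip),
                    contra = as.numeric(co), stringsAsFactors = FALSE)
  out$total <- out$ipsi + out$contra
  out <- out[out$total > 0, , drop = FALSE]
  out$group <- region_groups$group[match(out$source, region_groups$region)]
  out <- out[order(out$group, out$total, out$source), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("group", "source", "ipsi", "contra", "total")]
}

#' Read or write a count table as CSV
#'
#' Long-format CSV with header `injection,source,side,count`; sides spelled
#' `ipsi`/`contra`.
#'
#' @param counts Count table.
#' @param path CSV file path.
#' @return `read_counts()` returns the validated count table.
#' @name counts_io
#' @export
write_counts <- function(counts, path) {
  utils::write.csv(validate_counts(counts)[, c("injection", "source",
                                               "side", "count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(counts)
}

#' @rdname counts_io
#' @export
read_counts <- function(path) {
  validate_counts(utils::read.csv(path, stringsAsFactors = FALSE))
}
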
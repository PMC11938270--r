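# Weighted adjacency of the directed connectome, fixed node order.
connectome_weights <- function(g) {
  if (igraph::ecount(g) == 0) {
    n <- igraph::vcount(g)
    matrix(0, n, n, dimnames = list(igraph::V(g)$name, igraph::V(g)$name))
  } else {
    as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE))
  }
}

as_weight_matrix <- function(x) {
  if (inherits(x, "igraph")) return(connectome_weights(x))
  W <- as.matrix(x)
  if (nrow(W) != ncol(W)) stop_input("weight matrix must be square")
  if (any(W < 0)) stop_input("edge weights must be non-negative")
  W
}

# Within-module degree Z-score core. W: directed weight matrix;
# m: integer module per node. A node's within-module strength k_i sums the
# weights of its in- and out-edges to same-module nodes; z-scores use the
# population SD over the module (divisor n), the Brain Connectivity
# Toolbox convention. Singleton modules and zero-variance modules give 0.
wmdz_core <- function(W, m, sample_sd = FALSE) {
  S <- W + t(W)
  n <- nrow(S)
  z <- numeric(n)
  for (s in unique(m)) {
    idx <- which(m == s)
    if (length(idx) == 1L) next  # singleton module: 0 by definition
    k <- rowSums(S[idx, idx, drop = FALSE])
    mu <- mean(k)
    sd_s <- if (sample_sd) stats::sd(k) else sqrt(mean((k - mu)^2))
    if (sd_s > 0) z[idx] <- (k - mu) / sd_s
  }
  z
}

# Participation coefficient core: PC_i = 1 - sum_s (K_is / k_i)^2 over all
# modules s (own module included); K_is sums i's in+out edge weights to
# module s and k_i is i's total strength. k_i = 0 gives PC 0.
pc_core <- function(W, m) {
  S <- W + t(W)
  n <- nrow(S)
  k <- rowSums(S)
  acc <- numeric(n)
  for (s in unique(m)) {
    Ks <- rowSums(S[, m == s, drop = FALSE])
    acc <- acc + Ks^2
  }
  pc <- ifelse(k > 0, 1 - acc / k^2, 0)
  # clamp tiny negative round-off
  pmin(pmax(pc, 0), 1)
}

#' Within-module degree Z-score
#'
#' Standardises each node's within-module strength (the summed weights of
#' its in- and out-edges to nodes of its own module) against the mean and
#' standard deviation of that quantity over its module's members. A node in
#' a module by itself has a within-module degree Z-score of 0 by
#' definition, as does every node of a module whose members all have equal
#' within-module strength (zero variance).
#'
#' @param x Connectome graph ([build_connectome()]) or a directed weight
#'   matrix.
#' @param partition A [detect_modules()] result or a module assignment
#'   vector (named by node, or in node order).
#' @param sample_sd Use the sample SD (divisor n - 1) instead of the
#'   default population SD (divisor n).
#' @return Named numeric vector of Z-scores.
#' @export
#' @examples
#' W <- matrix(0, 3, 3); W[1, 2] <- 1; W[2, 3] <- 2
#' wmdz(W, c(1, 1, 2))
wmdz <- function(x, partition, sample_sd = FALSE) {
  W <- as_weight_matrix(x)
  nodes <- rownames(W) %||% as.character(seq_len(nrow(W)))
  m <- partition_assignment(partition, nodes)
  stats::setNames(wmdz_core(W, m, sample_sd = sample_sd), nodes)
}

#' Participation coefficient
#'
#' Measures how evenly a node's edge weight is distributed across modules:
#' `PC_i = 1 - sum_s (K_is / k_i)^2`, where `K_is` is the summed weight of
#' node i's edges (in + out) to module s and `k_i` its total strength. PC
#' is 0 when all of a node's edge weight stays inside its own module and
#' approaches 1 as weight spreads evenly over many modules. A node with no
#' edges has PC 0.
#'
#' @inheritParams wmdz
#' @return Named numeric vector of participation coefficients in [0, 1].
#' @export
participation_coefficient <- function(x, partition) {
  W <- as_weight_matrix(x)
  nodes <- rownames(W) %||% as.character(seq_len(nrow(W)))
  m <- partition_assignment(partition, nodes)
  stats::setNames(pc_core(W, m), nodes)
}

#' Directed participation coefficients
#'
#' In- and out-variants of the participation coefficient, using only
#' afferent (column) or efferent (row) weights respectively.
#'
#' @inheritParams wmdz
#' @return data.frame `node, pc_in, pc_out`.
#' @export
participation_coefficient_directed <- function(x, partition) {
  W <- as_weight_matrix(x)
  nodes <- rownames(W) %||% as.character(seq_len(nrow(W)))
  m <- partition_assignment(partition, nodes)
  one_side <- function(M) {
    k <- rowSums(M)
    acc <- numeric(nrow(M))
    for (s in unique(m)) acc <- acc + rowSums(M[, m == s, drop = FALSE])^2
    ifelse(k > 0, 1 - acc / k^2, 0)
  }
  data.frame(node = nodes, pc_in = one_side(t(W)), pc_out = one_side(W),
             row.names = NULL)
}

#' Hub analysis: rank nodes by degree or strength
#'
#' Ranks nodes by total (afferent + efferent) unweighted degree or weighted
#' strength; the top-ranked node is proposed as the network hub. Ties at
#' the top are reported as co-hubs with a warning, never silently broken.
#'
#' @param g Connectome graph.
#' @param mode `"weighted"` (rank by strength, default) or `"unweighted"`
#'   (rank by degree).
#' @return data.frame `node, afferent, efferent, total, rank, hub`, ordered
#'   by decreasing total; attribute `"hubs"` holds the hub node name(s).
#' @export
hub_analysis <- function(g, mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  if (igraph::vcount(g) == 0) stop_input("graph has no nodes")
  tab <- if (mode == "weighted") node_strength(g) else
    node_degree_unweighted(g)
  tab <- tab[order(-tab$total, tab$node), , drop = FALSE]
  tab$rank <- rank(-tab$total, ties.method = "min")
  hubs <- tab$node[tab$total == max(tab$total)]
  tab$hub <- tab$node %in% hubs
  if (length(hubs) > 1) {
    warning(length(hubs), " nodes tie for the top ", mode,
            " rank; all reported as co-hubs", call. = FALSE)
  }
  rownames(tab) <- NULL
  attr(tab, "hubs") <- hubs
  tab
}

#' Cartographic role classification
#'
#' Assigns every node one organisational role from its participation
#' coefficient: *peripheral* (PC < 0.625; most links within its own
#' module), *non-hub connector* (0.625 <= PC < 0.8), or *connector*
#' (PC >= 0.8). A node whose module contains only itself is an *isolate*
#' regardless of PC.
#'
#' @param pc Named numeric vector of participation coefficients.
#' @param partition Module assignment (see [wmdz()]).
#' @param peripheral_max,connector_min Role boundaries on PC (defaults
#'   0.625 and 0.8, the classical cartography values).
#' @return Character vector of roles (`peripheral`, `non_hub_connector`,
#'   `connector`, `isolate`), named by node.
#' @export
classify_roles <- function(pc, partition,
                           peripheral_max = 0.625, connector_min = 0.8) {
  nodes <- names(pc) %||% as.character(seq_along(pc))
  m <- partition_assignment(partition, nodes)
  sizes <- table(m)
  role <- ifelse(pc < peripheral_max, "peripheral",
                 ifelse(pc < connector_min, "non_hub_connector", "connector"))
  role[sizes[as.character(m)] == 1L] <- "isolate"
  stats::setNames(role, nodes)
}

#' Full node-role table
#'
#' Combines strength, degree, module membership, within-module degree
#' Z-score, participation coefficient, cartographic role and the weighted
#' hub flag into one table, one row per node.
#'
#' @param g Connectome graph.
#' @param partition Module partition over the graph's nodes.
#' @param sample_sd Passed to [wmdz()].
#' @return data.frame `node, module, degree, strength, wmdz, pc, role,
#'   hub`; attribute `"hubs"` as in [hub_analysis()].
#' @export
node_roles <- function(g, partition, sample_sd = FALSE) {
  nodes <- igraph::V(g)$name
  m <- partition_assignment(partition, nodes)
  z <- wmdz(g, m, sample_sd = sample_sd)
  pc <- participation_coefficient(g, m)
  hub_tab <- hub_analysis(g, mode = "weighted")
  deg <- node_degree_unweighted(g)
  str <- node_strength(g)
  out <- data.frame(
    node = nodes, module = m,
    degree = deg$total[match(nodes, deg$node)],
    strength = str$total[match(nodes, str$node)],
    wmdz = as.numeric(z), pc = as.numeric(pc),
    role = as.character(classify_roles(pc, m)),
    hub = nodes %in% attr(hub_tab, "hubs"),
    stringsAsFactors = FALSE
  )
  attr(out, "hubs") <- attr(hub_tab, "hubs")
  out
}

#' Cartography scatter coordinates
#'
#' The three coordinates of the cartographic 3D scatter: participation
#' coefficient (x), total strength (y), and within-module degree Z-score
#' (z), one row per node.
#'
#' @param roles A [node_roles()] table.
#' @return data.frame `node, pc, strength, wmdz`.
#' @export
cartography_coordinates <- function(roles) {
  roles[, c("node", "pc", "strength", "wmdz")]
}

#' Efferent hub analysis over regions outside the target network
#'
#' For every source region outside `target_set` that projects into it,
#' reports the *edge count* (number of distinct target regions it projects
#' to, regardless of weight) and the *weighted edge count* (summed cell
#' counts of those projections), ranked by each. External regions with no
#' projection into the target set are excluded.
#'
#' @param counts Count table over an extended region set (injections within
#'   `target_set`, sources inside and outside it).
#' @param target_set The core network's region names.
#' @return data.frame `region, edge_count, weighted_edge_count,
#'   rank_edges, rank_weighted`, ordered by decreasing weighted edge count.
#' @export
efferent_hub_analysis <- function(counts, target_set = vsb_regions()) {
  counts <- validate_counts(counts)
  ext <- counts[!(counts$source %in% target_set) &
                  counts$injection %in% target_set, , drop = FALSE]
  ext <- ext[ext$count > 0, , drop = FALSE]
  if (!nrow(ext)) {
    stop_input("no external region projects into the target set")
  }
  pair <- unique(ext[, c("source", "injection")])
  edge_count <- table(pair$source)
  weighted <- tapply(ext$count, ext$source, sum)
  out <- data.frame(
    region = names(weighted),
    edge_count = as.integer(edge_count[names(weighted)]),
    weighted_edge_count = as.numeric(weighted),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$weighted_edge_count, out$region), , drop = FALSE]
  out$rank_weighted <- rank(-out$weighted_edge_count, ties.method = "min")
  out$rank_edges <- rank(-out$edge_count, ties.method = "min")
  rownames(out) <- NULL
  out
}
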
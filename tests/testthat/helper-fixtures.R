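# Shared fixtures built in code.

# Count table for a small named graph given an edge list
# (from, to, ipsi, contra); retrograde convention: edge from -> to is a row
# (injection = to, source = from).
counts_from_edges <- function(edges) {
  do.call(rbind, lapply(seq_len(nrow(edges)), function(i) {
    data.frame(
      injection = rep(edges$to[i], 2),
      source = rep(edges$from[i], 2),
      side = c("ipsi", "contra"),
      count = c(edges$ipsi[i], edges$contra[i]),
      stringsAsFactors = FALSE
    )
  }))
}

# Directed weight matrix -> connectome graph via the count-table route.
graph_from_matrix <- function(W, nodes = NULL) {
  n <- nrow(W)
  nodes <- nodes %||% LETTERS[seq_len(n)]
  idx <- which(W > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(build_connectome(
      data.frame(injection = character(), source = character(),
                 side = character(), count = integer()),
      node_set = nodes))
  }
  counts <- data.frame(
    injection = nodes[idx[, 2]],
    source = nodes[idx[, 1]],
    side = "ipsi",
    count = W[idx],
    stringsAsFactors = FALSE
  )
  build_connectome(counts, node_set = nodes)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Small label map with two rectangular regions for imaging tests.
two_region_map <- function(size = 60) {
  labels <- matrix(0L, size, size)
  labels[6:(size / 2 - 5), 6:(size - 5)] <- 1L
  labels[(size / 2 + 5):(size - 5), 6:(size - 5)] <- 2L
  region_label_map(labels, data.frame(
    code = c(1L, 2L), name = c("A", "B"),
    hemisphere = c("ipsi", "contra"), group = "demo",
    stringsAsFactors = FALSE))
}

# Literal per-node evaluation of the within-module degree Z-score: for the
# node's module, enumerate members, sum in+out weights to same-module
# nodes, standardise by the module mean and population SD.
oracle_wmdz <- function(W, m) {
  n <- nrow(W)
  z <- numeric(n)
  for (i in seq_len(n)) {
    members <- which(m == m[i])
    if (length(members) == 1) next
    k <- vapply(members, function(j) {
      sum(W[j, members]) + sum(W[members, j])
    }, numeric(1))
    mu <- mean(k)
    sdv <- sqrt(sum((k - mu)^2) / length(k))
    if (sdv > 0) z[i] <- (k[match(i, members)] - mu) / sdv
  }
  z
}

# Literal per-node evaluation of the participation coefficient:
# 1 - sum over modules of (K_is / k_i)^2, in+out weights.
oracle_pc <- function(W, m) {
  n <- nrow(W)
  pc <- numeric(n)
  for (i in seq_len(n)) {
    ki <- sum(W[i, ]) + sum(W[, i])
    if (ki == 0) next
    tot <- 0
    for (s in unique(m)) {
      js <- which(m == s)
      Kis <- sum(W[i, js]) + sum(W[js, i])
      tot <- tot + (Kis / ki)^2
    }
    pc[i] <- 1 - tot
  }
  pc
}
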
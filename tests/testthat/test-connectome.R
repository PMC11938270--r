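test_that("the retrograde convention maps count rows to reversed edges", {
  counts <- data.frame(injection = "B", source = "A", side = "ipsi",
                       count = 12)
  g <- build_connectome(counts, node_set = c("A", "B"))
  e <- igraph::as_data_frame(g)
  expect_equal(nrow(e), 1)
  expect_equal(e$from, "A")
  expect_equal(e$to, "B")
  expect_equal(e$weight, 12)
})

test_that("ipsi and contra rows sum into the weight and stay as attributes", {
  counts <- data.frame(injection = c("B", "B"), source = c("A", "A"),
                       side = c("ipsi", "contra"), count = c(10, 2))
  g <- build_connectome(counts, node_set = c("A", "B"))
  e <- igraph::as_data_frame(g)
  expect_equal(e$weight, 12)
  expect_equal(e$ipsi, 10)
  expect_equal(e$contra, 2)
})

test_that("an empty table yields the edgeless graph on the full node set", {
  empty <- data.frame(injection = character(), source = character(),
                      side = character(), count = integer())
  g <- build_connectome(empty)
  expect_equal(igraph::vcount(g), 15)
  expect_equal(igraph::ecount(g), 0)
})

test_that("invalid tables are rejected: self rows, duplicates, unknowns", {
  expect_error(build_connectome(
    data.frame(injection = "A", source = "A", side = "ipsi", count = 1),
    node_set = c("A", "B")), "self")
  expect_error(build_connectome(
    data.frame(injection = c("B", "B"), source = c("A", "A"),
               side = c("ipsi", "ipsi"), count = c(1, 2)),
    node_set = c("A", "B")), "duplicate")
  expect_error(build_connectome(
    data.frame(injection = "B", source = "Z", side = "ipsi", count = 1),
    node_set = c("A", "B")), "Z")
  expect_error(build_connectome(
    data.frame(injection = "B", source = "A", side = "left", count = 1),
    node_set = c("A", "B")), "side")
  expect_error(build_connectome(
    data.frame(injection = "B", source = "A", side = "ipsi", count = -1),
    node_set = c("A", "B")), "non-negative")
})

test_that("zero-count pairs carry no edge", {
  counts <- data.frame(injection = c("B", "C"), source = c("A", "A"),
                       side = "ipsi", count = c(0, 5))
  g <- build_connectome(counts, node_set = c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(node_degree_unweighted(g, "A")$efferent, 1)
})

test_that("dyad classification matches brute-force enumeration on 3 nodes", {
  # edges {A->B, B->A, A->C}
  W <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  W["A", "B"] <- 1; W["B", "A"] <- 2; W["A", "C"] <- 3
  g <- graph_from_matrix(W)
  d <- classify_dyads(g)
  # independent brute force over all 6 ordered pairs
  brute <- c(absent = 0, unidirectional = 0, bidirectional = 0)
  for (a in 1:3) for (b in 1:3) {
    if (a == b) next
    cls <- if (W[a, b] > 0 && W[b, a] > 0) "bidirectional"
           else if (W[a, b] > 0) "unidirectional" else "absent"
    brute[cls] <- brute[cls] + 1
  }
  expect_equal(d$possible, 6)
  expect_equal(d$bidirectional, unname(brute["bidirectional"]))
  expect_equal(d$unidirectional, unname(brute["unidirectional"]))
  expect_equal(d$absent, unname(brute["absent"]))
})

test_that("dyad classes always sum to n(n-1) and ignore node labels", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:10, 1)
    W <- matrix(rbinom(n * n, 1, 0.4) * sample(1:9, n * n, TRUE), n, n)
    diag(W) <- 0
    g <- graph_from_matrix(W)
    d <- classify_dyads(g)
    expect_equal(d$absent + d$unidirectional + d$bidirectional, n * (n - 1))
    perm <- sample(n)
    d2 <- classify_dyads(graph_from_matrix(W[perm, perm]))
    expect_equal(d2, d)
  }
})

test_that("degree and strength behave on stars, isolates and scalings", {
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- c(3, 1, 1, 1)   # A sends to all
  W[2:5, 1] <- c(5, 7, 0, 0)   # B, C send back
  g <- graph_from_matrix(W)
  deg <- node_degree_unweighted(g)
  expect_equal(deg$total[deg$node == "A"], 6)  # 4 out + 2 in
  e_row <- deg[deg$node == "E", ]
  expect_equal(unlist(e_row[c("afferent", "efferent", "total")],
                      use.names = FALSE), c(1L, 0L, 1L))
  st <- node_strength(g)
  expect_equal(st$afferent[st$node == "A"], 12)
  expect_equal(st$efferent[st$node == "A"], 6)
  expect_equal(st$total[st$node == "A"], 18)
  # homogeneity: doubling all weights doubles every strength
  st2 <- node_strength(graph_from_matrix(2 * W))
  expect_equal(st2$total, 2 * st$total)
  # with all weights 1, strength reduces to unweighted degree
  W1 <- (W > 0) * 1
  g1 <- graph_from_matrix(W1)
  expect_equal(node_strength(g1)$total,
               as.numeric(node_degree_unweighted(g1)$total))
})

test_that("summed afferent, efferent and edge weights agree (double counting)", {
  for (s in 1:10) {
    set.seed(100 + s)
    out <- generate_count_matrix(synthetic_spec(n_regions = 10, seed = s))
    g <- build_connectome(out$counts, node_set = paste0("R", 1:10))
    st <- node_strength(g)
    total_w <- sum(igraph::E(g)$weight)
    expect_equal(sum(st$afferent), total_w)
    expect_equal(sum(st$efferent), total_w)
  }
})

test_that("display weights scale linearly onto [0, 0.9]", {
  W <- matrix(0, 3, 3); W[1, 2] <- 10; W[2, 3] <- 5
  g <- scale_edge_weights(graph_from_matrix(W))
  e <- igraph::as_data_frame(g)
  expect_equal(sort(e$display_weight), c(0.45, 0.9))
  expect_equal(sort(e$weight), c(5, 10))  # raw counts retained
  # monotone in the raw count
  expect_equal(order(e$weight), order(e$display_weight))
  empty <- graph_from_matrix(matrix(0, 3, 3))
  expect_error(scale_edge_weights(empty), "no edges")
})

test_that("count tables round-trip through CSV without changing the graph", {
  out <- generate_count_matrix(synthetic_spec(n_regions = 8, seed = 5))
  path <- tempfile(fileext = ".csv")
  write_counts(out$counts, path)
  back <- read_counts(path)
  g1 <- build_connectome(out$counts, node_set = paste0("R", 1:8))
  g2 <- build_connectome(back, node_set = paste0("R", 1:8))
  expect_equal(igraph::as_data_frame(g1), igraph::as_data_frame(g2))
})

test_that("radial summaries group, sort ascending and break ties by name", {
  counts <- counts_from_edges(data.frame(
    from = c("X", "Y", "Z", "Q"), to = "INJ",
    ipsi = c(2, 8, 3, 0), contra = c(1, 2, 0, 0)))
  groups <- data.frame(region = c("X", "Y", "Z", "Q"),
                       group = c("g1", "g1", "g2", "g2"))
  out <- radial_summary(counts, "INJ", groups)
  expect_equal(out$source, c("X", "Y", "Z"))  # Q total 0 omitted
  expect_equal(out$total, c(3, 10, 3))
  # tie: equal totals order alphabetically
  counts2 <- counts_from_edges(data.frame(
    from = c("Y", "X"), to = "INJ", ipsi = c(5, 5), contra = c(0, 0)))
  out2 <- radial_summary(counts2, "INJ",
                         data.frame(region = c("X", "Y"), group = "g"))
  expect_equal(out2$source, c("X", "Y"))
  expect_error(radial_summary(counts, "NOPE", groups), "NOPE")
  expect_error(
    radial_summary(counts, "INJ", data.frame(region = "X", group = "g")),
    "group")
})
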
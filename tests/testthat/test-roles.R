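test_that("within-module degree Z-scores match the literal oracle", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- 2; W[2, 3] <- 2; W[3, 2] <- 2; W[1, 4] <- 7
  m <- c(1, 1, 1, 2)
  expect_equal(unname(wmdz(W, m)), oracle_wmdz(W, m))
})

test_that("a module with within-strengths {2,4,6} standardises as expected", {
  # directed edges A->B 2, B->C 2, C->B 2, all in one module, give in+out
  # within-strengths k_A = 2, k_B = 6, k_C = 4
  W <- matrix(0, 3, 3)
  W[1, 2] <- 2; W[2, 3] <- 2; W[3, 2] <- 2
  z <- wmdz(W, c(1, 1, 1))
  k <- c(2, 6, 4)
  sigma <- sqrt(mean((k - mean(k))^2))  # population SD = sqrt(8/3)
  expect_equal(sigma, sqrt(8 / 3))
  expect_equal(unname(z), (k - 4) / sigma)
  # the node with within-strength 6 sits at (6 - 4) / sqrt(8/3) ~ 1.2247
  expect_equal(unname(z[2]), 1.224744871, tolerance = 1e-8)
  # sample-SD variant uses divisor n - 1
  zs <- wmdz(W, c(1, 1, 1), sample_sd = TRUE)
  expect_equal(unname(zs), (k - 4) / 2)
})

test_that("singleton modules and zero-variance modules give WMDz 0", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- 5; W[2, 1] <- 3; W[3, 4] <- 2; W[1, 4] <- 10
  # node 4 alone in its module: 0 regardless of its (cross-module) edges
  z <- wmdz(W, c(1, 1, 1, 2))
  expect_identical(unname(z[4]), 0)
  # all nodes of one module with equal within-strength: all 0
  W2 <- matrix(0, 4, 4)
  W2[1, 2] <- 1; W2[2, 1] <- 1; W2[3, 4] <- 1; W2[4, 3] <- 1
  expect_equal(unname(wmdz(W2, c(1, 1, 2, 2))), rep(0, 4))
})

test_that("WMDz is a z-score: mean 0, population SD 1 per module", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(4:12, 1)
    W <- matrix(rpois(n * n, 4), n, n); diag(W) <- 0
    m <- sample(1:3, n, replace = TRUE)
    z <- wmdz(W, m)
    for (mod in unique(m)) {
      idx <- which(m == mod)
      if (length(idx) < 2) next
      S <- W + t(W)
      k <- rowSums(S[idx, idx, drop = FALSE])
      if (sd(k) == 0) next
      expect_equal(mean(z[idx]), 0, tolerance = 1e-12)
      expect_equal(sqrt(mean((z[idx] - 0)^2)), 1, tolerance = 1e-12)
    }
  }
})

test_that("participation coefficients match hand-computed values", {
  # all edges within own module -> 0
  W <- matrix(0, 4, 4)
  W[1, 2] <- 5; W[2, 1] <- 1
  pc <- participation_coefficient(W, c(1, 1, 2, 2))
  expect_identical(unname(pc[1]), 0)
  # weight split equally between two modules -> 1 - 2 * (1/2)^2 = 0.5
  W2 <- matrix(0, 3, 3)
  W2[1, 2] <- 1; W2[1, 3] <- 1
  pc2 <- participation_coefficient(W2, c(1, 1, 2))
  expect_equal(unname(pc2[1]), 0.5)
  # weights {own: 1, M2: 1, M3: 2}, k = 4 -> 1 - (1+1+4)/16 = 0.625
  W3 <- matrix(0, 4, 4)
  W3[1, 2] <- 1; W3[1, 3] <- 1; W3[1, 4] <- 2
  pc3 <- participation_coefficient(W3, c(1, 1, 2, 3))
  expect_equal(unname(pc3[1]), 0.625)
  # no edges at all -> 0 by convention
  pc4 <- participation_coefficient(matrix(0, 3, 3), c(1, 2, 3))
  expect_equal(unname(pc4), rep(0, 3))
})

test_that("PC stays within [0, 1 - 1/n_modules] on random graphs", {
  for (s in 1:30) {
    set.seed(s)
    n <- sample(3:10, 1)
    W <- matrix(rbinom(n * n, 1, 0.5) * sample(0:2, n * n, TRUE), n, n)
    diag(W) <- 0
    nm <- sample(1:min(4, n), 1)
    m <- sample(seq_len(nm), n, replace = TRUE)
    pc <- participation_coefficient(W, m)
    expect_true(all(pc >= 0))
    expect_true(all(pc <= 1 - 1 / length(unique(m)) + 1e-12))
  }
})

test_that("directed PC variants use only one side of the weights", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- 1; W[3, 1] <- 1   # node 1: out to mod of 2, in from mod of 3
  m <- c(1, 2, 2)
  d <- participation_coefficient_directed(W, m)
  expect_equal(d$pc_out[1], 0)  # all out-weight to one module
  expect_equal(d$pc_in[1], 0)
  W[1, 3] <- 1                  # now out-weight split... both to module 2
  d2 <- participation_coefficient_directed(W, c(1, 2, 3))
  expect_equal(d2$pc_out[1], 0.5)
})

test_that("hub analysis ranks by strength or degree and reports ties", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- 100; W[2, 3] <- 50; W[3, 1] <- 10
  g <- graph_from_matrix(W)
  hw <- hub_analysis(g, "weighted")
  expect_equal(attr(hw, "hubs"), "B")   # strength B = 100 in + 50 out = 150
  expect_equal(hw$node[1], "B")
  # equal weights: weighted hub equals unweighted hub
  W1 <- matrix(0, 4, 4); W1[1, 2:4] <- 1; W1[2, 3] <- 1
  g1 <- graph_from_matrix(W1)
  expect_equal(attr(hub_analysis(g1, "weighted"), "hubs"),
               attr(hub_analysis(g1, "unweighted"), "hubs"))
  # all-equal strengths: every node ties, with a warning
  Wt <- matrix(0, 3, 3); Wt[1, 2] <- 1; Wt[2, 3] <- 1; Wt[3, 1] <- 1
  expect_warning(ht <- hub_analysis(graph_from_matrix(Wt), "weighted"),
                 "co-hubs")
  expect_equal(sort(attr(ht, "hubs")), c("A", "B", "C"))
})

test_that("raising a node's weights never lowers its strength rank", {
  set.seed(42)
  W <- matrix(rpois(36, 5), 6, 6); diag(W) <- 0
  g <- graph_from_matrix(W)
  st <- node_strength(g)
  rank0 <- rank(-st$total)[1]
  W2 <- W
  W2[1, ] <- W[1, ] * 3
  st2 <- node_strength(graph_from_matrix(W2))
  expect_lte(rank(-st2$total)[1], rank0)
})

test_that("roles follow the cartographic thresholds and isolate override", {
  pc <- c(a = 0.3, b = 0.7, c = 0.85, d = 0.99)
  m <- c(a = 1, b = 1, c = 1, d = 2)  # d is a singleton module
  roles <- classify_roles(pc, m)
  expect_equal(unname(roles),
               c("peripheral", "non_hub_connector", "connector", "isolate"))
  # boundaries: half-open at 0.625 and 0.8
  pcb <- c(x = 0.625, y = 0.8, z = 0.624999)
  mb <- c(x = 1, y = 1, z = 1)
  expect_equal(unname(classify_roles(pcb, mb)),
               c("non_hub_connector", "connector", "peripheral"))
  # totality: every node gets exactly one class
  for (s in 1:10) {
    set.seed(s)
    n <- sample(3:12, 1)
    pcs <- runif(n); names(pcs) <- paste0("n", 1:n)
    ms <- sample(1:3, n, TRUE); names(ms) <- names(pcs)
    r <- classify_roles(pcs, ms)
    expect_equal(length(r), n)
    expect_true(all(r %in% c("peripheral", "non_hub_connector",
                             "connector", "isolate")))
  }
})

test_that("node_roles assembles one consistent row per node", {
  out <- generate_count_matrix(synthetic_spec(seed = 8, hub_index = 2))
  g <- build_connectome(out$counts)
  prof <- projection_profile(out$counts)
  part <- detect_modules(prof, k = 3)
  roles <- node_roles(g, part)
  expect_equal(nrow(roles), 15)
  expect_equal(roles$node, vsb_regions())
  expect_equal(sum(roles$hub), length(attr(roles, "hubs")))
  expect_true(all(roles$pc >= 0 & roles$pc <= 1))
  coords <- cartography_coordinates(roles)
  expect_equal(names(coords), c("node", "pc", "strength", "wmdz"))
  expect_equal(nrow(coords), 15)
  # an isolate's cartography point carries wmdz 0
  iso <- roles$node[roles$role == "isolate"]
  if (length(iso)) {
    expect_true(all(coords$wmdz[coords$node %in% iso] == 0))
  }
})

test_that("efferent hub analysis counts and weighs external projections", {
  counts <- counts_from_edges(data.frame(
    from = c("EXT1", "EXT1", "EXT1", "EXT2", "IN3"),
    to = c("IN1", "IN2", "IN3", "IN1", "IN1"),
    ipsi = c(5, 5, 10, 2, 9), contra = c(0, 0, 0, 0, 0)))
  targets <- c("IN1", "IN2", "IN3")
  out <- efferent_hub_analysis(counts, targets)
  expect_equal(out$region, c("EXT1", "EXT2"))
  expect_equal(out$edge_count, c(3L, 1L))
  expect_equal(out$weighted_edge_count, c(20, 2))
  expect_equal(out$rank_weighted, c(1L, 2L))
  # an external region with no projections is excluded
  counts0 <- rbind(counts, data.frame(injection = "IN2", source = "EXT3",
                                      side = "ipsi", count = 0))
  out0 <- efferent_hub_analysis(counts0, targets)
  expect_false("EXT3" %in% out0$region)
  expect_error(
    efferent_hub_analysis(counts[counts$source == "IN3", ], targets),
    "external")
})

test_that("a planted external efferent hub ranks first", {
  set.seed(7)
  targets <- paste0("T", 1:5)
  ext <- paste0("X", 1:4)
  rows <- expand.grid(source = ext, injection = targets,
                      stringsAsFactors = FALSE)
  rows$side <- "ipsi"
  rows$count <- rpois(nrow(rows), 5)
  rows$count[rows$source == "X2"] <- rows$count[rows$source == "X2"] + 50
  out <- efferent_hub_analysis(rows, targets)
  expect_equal(out$region[1], "X2")
})
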
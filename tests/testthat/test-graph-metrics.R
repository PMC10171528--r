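unit_graph <- function(W) as_conn(W)

test_that("shortest paths use inverse weights with exact tie counts", {
  # triangle with unit weights: direct edges of length 1
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  D <- shortest_path_lengths(unit_graph(K3))$D
  expect_equal(unname(D), matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  # chain with half weights: 1/0.5 + 1/0.5 = 4
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5; W[2, 3] <- W[3, 2] <- 0.5
  d <- shortest_path_lengths(unit_graph(W))
  expect_equal(d$D[1, 3], 4)
  expect_equal(connpred:::reconstruct_path(d, 1, 3), c(1, 2, 3))
  # disconnected components are infinitely far apart
  W4 <- matrix(0, 4, 4)
  W4[1, 2] <- W4[2, 1] <- 1; W4[3, 4] <- W4[4, 3] <- 1
  D4 <- shortest_path_lengths(unit_graph(W4))$D
  expect_true(is.infinite(D4[1, 3]))
  # diamond: two equal-length routes counted exactly
  Wd <- matrix(0, 4, 4)
  Wd[1, 2] <- Wd[2, 1] <- Wd[1, 3] <- Wd[3, 1] <- 1
  Wd[2, 4] <- Wd[4, 2] <- Wd[3, 4] <- Wd[4, 3] <- 1
  expect_equal(shortest_path_lengths(unit_graph(Wd))$counts[1, 4], 2)
})

test_that("distances match an independent min-plus closure on random graphs", {
  for (s in 1:10) {
    W <- random_connected_graph(sample(4:8, 1), 0.5, seed = s)
    expect_equal(unname(shortest_path_lengths(as_conn(W))$D),
                 oracle_distances(W), tolerance = 1e-9)
  }
})

test_that("modularity partition recovers planted cliques and flat graphs", {
  # two unit-weight K4 cliques joined by one weak edge
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1
  diag(W) <- 0
  W[4, 5] <- W[5, 4] <- 0.1
  part <- community_partition(unit_graph(W))
  expect_equal(length(unique(part$labels)), 2L)
  expect_equal(length(unique(part$labels[1:4])), 1L)
  expect_equal(length(unique(part$labels[5:8])), 1L)
  expect_gt(part$Q, 0.3)
  expect_lte(part$Q, 1)
  # complete graph: one module, Q = 0
  K6 <- matrix(1, 6, 6); diag(K6) <- 0
  p6 <- community_partition(unit_graph(K6))
  expect_equal(length(unique(p6$labels)), 1L)
  expect_equal(p6$Q, 0, tolerance = 1e-12)
  expect_error(community_partition(connectome(matrix(0, 4, 4), "SC")),
               "edgeless")
})

test_that("partition is invariant to node relabelling", {
  W <- random_connected_graph(8, 0.4, seed = 21)
  p1 <- community_partition(as_conn(W))
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  p2 <- community_partition(as_conn(W[perm, perm]))
  # same grouping up to label renaming
  expect_equal(length(unique(p1$labels)), length(unique(p2$labels)))
  expect_equal(p2$Q, p1$Q, tolerance = 1e-10)
  g1 <- outer(p1$labels[perm], p1$labels[perm], "==")
  g2 <- outer(p2$labels, p2$labels, "==")
  expect_identical(g1, g2)
})

test_that("complete unit-weight graphs saturate the closed forms", {
  n <- 4
  K <- matrix(1, n, n); diag(K) <- 0
  conn <- unit_graph(K)
  dist <- shortest_path_lengths(conn)
  part <- community_partition(conn)
  nm <- node_metrics(conn, dist, part)
  expect_equal(unname(nm[, "node_degree"]), rep(3, n))
  expect_equal(unname(nm[, "node_strength"]), rep(3, n))
  expect_equal(unname(nm[, "clustering_coefficient"]), rep(1, n))
  expect_equal(unname(nm[, "node_eccentricity"]), rep(1, n))
  gm <- global_metrics(conn, dist, part, swp = 0, core_size = n)
  expect_equal(unname(gm["characteristic_path_length"]), 1)
  expect_equal(unname(gm["global_efficiency"]), 1)
  expect_equal(unname(gm["average_clustering_coefficient"]), 1)
  expect_equal(unname(gm["transitivity"]), 1)
})

test_that("star betweenness routes every leaf pair through the centre", {
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- W[2:5, 1] <- 1
  conn <- unit_graph(W)
  dist <- shortest_path_lengths(conn)
  nm <- node_metrics(conn, dist, community_partition(conn))
  expect_equal(unname(nm[, "betweenness_centrality"]), c(6, 0, 0, 0, 0))
  # edge betweenness on a 3-chain: end edge carries 2 shortest paths
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- W3[2, 3] <- W3[3, 2] <- 1
  em <- edge_metrics(unit_graph(W3))
  expect_equal(em$edge_betweenness_centrality[1, 2], 2)
  expect_equal(em$edge_betweenness_centrality[2, 3], 2)
})

test_that("matching index hits its extremes on shared and disjoint neighbourhoods", {
  # i and j share all neighbours -> 1; no shared neighbours -> 0
  W <- matrix(0, 5, 5)
  W[1, 3:5] <- W[3:5, 1] <- 0.5
  W[2, 3:5] <- W[3:5, 2] <- 0.7
  em <- edge_metrics(unit_graph(W))
  expect_equal(em$matching_index[1, 2], 1)
  W2 <- matrix(0, 6, 6)
  W2[1, 3] <- W2[3, 1] <- 0.5
  W2[2, 4] <- W2[4, 2] <- 0.5
  W2[3, 4] <- W2[4, 3] <- 0.5   # connect so graph has structure
  em2 <- edge_metrics(unit_graph(W2))
  expect_equal(em2$matching_index[1, 2], 0)
})

test_that("participation splits evenly across two modules", {
  # node 1 sends half its strength to each module
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 0.5; W[1, 4] <- W[4, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 1; W[4, 5] <- W[5, 4] <- 1
  part <- list(labels = c(1L, 1L, 1L, 2L, 2L), Q = 0)
  nm <- node_metrics(unit_graph(W), shortest_path_lengths(unit_graph(W)),
                     part)
  expect_equal(unname(nm[1, "participation_coefficient"]), 0.5)
})

test_that("isolated and degenerate structures produce documented sentinels", {
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1; W[1, 3] <- W[3, 1] <- 1
  # nodes 4, 5 isolated
  conn <- unit_graph(W)
  nm <- node_metrics(conn, shortest_path_lengths(conn),
                     list(labels = c(1L, 1L, 1L, 2L, 3L), Q = 0))
  expect_equal(unname(nm[4, "node_degree"]), 0)
  expect_equal(unname(nm[4, "clustering_coefficient"]), 0)
  expect_equal(unname(nm[4, "participation_coefficient"]), 0)
  expect_true(is.na(nm[4, "node_eccentricity"]))
  # ring lattice: all strengths equal -> assortativity NaN sentinel
  n <- 8
  R <- matrix(0, n, n)
  for (i in seq_len(n)) { j <- i %% n + 1; R[i, j] <- R[j, i] <- 1 }
  gm <- global_metrics(unit_graph(R), swp = 0, core_size = 1)
  expect_true(is.nan(gm[["assortativity"]]))
})

test_that("every deterministic measure matches the brute-force oracle", {
  for (s in 1:20) {
    n <- 4 + (s %% 5)
    expect_oracle_agreement(random_connected_graph(n, 0.5, seed = 100 + s))
  }
})

test_that("uniform weight rescaling leaves scale-free measures unchanged", {
  W <- random_connected_graph(8, 0.5, seed = 77)
  # rescale into [0,1] still: use c < 1
  c0 <- 0.37
  a <- as_conn(W); b <- as_conn(W * c0)
  pa <- community_partition(a); pb <- community_partition(b)
  na <- node_metrics(a, shortest_path_lengths(a), pa)
  nb <- node_metrics(b, shortest_path_lengths(b), pb)
  expect_equal(nb[, "node_degree"], na[, "node_degree"])
  expect_equal(nb[, "node_strength"], c0 * na[, "node_strength"],
               tolerance = 1e-12)
  expect_equal(nb[, "participation_coefficient"],
               na[, "participation_coefficient"], tolerance = 1e-12)
  expect_equal(edge_metrics(b)$matching_index, edge_metrics(a)$matching_index,
               tolerance = 1e-12)
  ga <- global_metrics(a, partition = pa, swp = 0, core_size = 1)
  gb <- global_metrics(b, partition = pb, swp = 0, core_size = 1)
  expect_equal(gb[["assortativity"]], ga[["assortativity"]],
               tolerance = 1e-12)
  expect_equal(core_periphery_size(b), core_periphery_size(a))
})

test_that("small-world propensity honours its closed-form anchors", {
  # ring lattice: clustering matches its own lattice null, path length is
  # lattice-like, so dC ~ 0 and dL ~ 1 giving phi ~ 1 - sqrt(1/2)
  n <- 20
  R <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in 1:2) {
    j <- (i + k - 1) %% n + 1
    R[i, j] <- R[j, i] <- 1
  }
  phi <- small_world_propensity(unit_graph(R), n_nulls = 10, seed = 4)
  expect_gt(phi, 0.15)
  expect_lt(phi, 0.45)
  expect_equal(phi,
               small_world_propensity(unit_graph(R), n_nulls = 10, seed = 4))
  w <- random_connected_graph(10, 0.5, seed = 5)
  phi2 <- small_world_propensity(as_conn(w), n_nulls = 5, seed = 6)
  expect_gte(phi2, 0)
  expect_lte(phi2, 1)
})

test_that("core-periphery search finds hub cores and full cores", {
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- W[2:5, 1] <- 1
  expect_equal(core_periphery_size(unit_graph(W)), 1L)
  expect_equal(oracle_core_size(W), 1L)
  for (n in c(4, 6)) {
    K <- matrix(1, n, n); diag(K) <- 0
    expect_equal(core_periphery_size(unit_graph(K)), n)
    expect_equal(oracle_core_size(K), n)
  }
  # heuristic at larger n agrees with exhaustive search on a small graph
  W2 <- random_connected_graph(10, 0.4, seed = 31)
  expect_equal(core_periphery_size(as_conn(W2), exhaustive_max = 0L),
               core_periphery_size(as_conn(W2)))
  # relabelling invariance
  p <- sample(10)
  expect_equal(core_periphery_size(as_conn(W2[p, p])),
               core_periphery_size(as_conn(W2)))
})
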
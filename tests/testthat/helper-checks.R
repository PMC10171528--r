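# Shared check: every deterministic measure of the battery against the
# brute-force oracle on one graph (continuous weights assumed, so shortest
# paths are unique and path-dependent measures are well defined).

expect_oracle_agreement <- function(W, tol = 1e-9) {
  conn <- as_conn(W)
  dist <- shortest_path_lengths(conn)
  part <- community_partition(conn)
  nm <- node_metrics(conn, dist, part)
  em <- edge_metrics(conn, dist)
  gm <- global_metrics(conn, dist, part, swp = 0, core_size = 1L)

  D0 <- oracle_distances(W)
  expect_equal(unname(dist$D), D0, tolerance = tol)

  bt <- oracle_betweenness(W, D0)
  expect_equal(unname(nm[, "node_degree"]), rowSums(W > 0), tolerance = tol)
  expect_equal(unname(nm[, "node_strength"]), rowSums(W), tolerance = tol)
  expect_equal(unname(nm[, "clustering_coefficient"]), oracle_onnela(W),
               tolerance = tol)
  expect_equal(unname(nm[, "betweenness_centrality"]), bt$node,
               tolerance = tol)
  expect_equal(unname(nm[, "eigenvector_centrality"]),
               oracle_eigencentrality(W), tolerance = 1e-7)
  expect_equal(unname(nm[, "participation_coefficient"]),
               oracle_participation(W, part$labels), tolerance = tol)
  expect_equal(unname(nm[, "within_module_degree"]),
               oracle_within_module_z(W, part$labels), tolerance = tol)
  ecc0 <- vapply(seq_len(nrow(W)), function(i) {
    d <- D0[i, -i]; d <- d[is.finite(d)]
    if (length(d)) max(d) else NA_real_
  }, numeric(1))
  expect_equal(unname(nm[, "node_eccentricity"]), ecc0, tolerance = tol)
  expect_equal(unname(nm[, "local_efficiency"]), oracle_local_efficiency(W),
               tolerance = tol)

  M0 <- oracle_matching(W)
  expect_equal(unname(em$matching_index), M0, tolerance = tol)
  expect_equal(unname(em$edge_betweenness_centrality), bt$edge,
               tolerance = tol)
  expect_equal(unname(em$path_transitivity),
               oracle_path_transitivity(W, D0, M0), tolerance = tol)

  dfin <- D0[upper.tri(D0)]
  expect_equal(unname(gm["characteristic_path_length"]),
               mean(dfin[is.finite(dfin)]), tolerance = tol)
  expect_equal(unname(gm["global_efficiency"]),
               mean(ifelse(is.finite(1 / dfin), 1 / dfin, 0)),
               tolerance = tol)
  expect_equal(unname(gm["average_clustering_coefficient"]),
               mean(oracle_onnela(W)), tolerance = tol)
  expect_equal(unname(gm["transitivity"]), oracle_transitivity(W),
               tolerance = tol)
  a0 <- oracle_assortativity(W)
  if (is.nan(a0)) expect_true(is.nan(gm[["assortativity"]]))
  else expect_equal(unname(gm["assortativity"]), a0, tolerance = tol)
  expect_equal(unname(gm["modularity_statistic"]),
               oracle_modularity(W, part$labels), tolerance = tol)

  invisible(TRUE)
}
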
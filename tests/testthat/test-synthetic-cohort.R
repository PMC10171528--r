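small_cfg <- function(planted_r2 = 0, sc_density = 0.5, ...) {
  cohort_config(n_subjects = 10L, n_regions = 12L, samples_per_voxel = 100L,
                voxels_per_region = c(5L, 15L), sc_density = sc_density,
                planted_r2 = planted_r2, seed = 42L, ...)
}

test_that("streamline counts satisfy their invariants and are seeded", {
  cfg <- small_cfg()
  sc <- generate_streamline_counts(cfg, 3L)
  expect_true(all(diag(sc$M) == 0))
  expect_true(all(sc$M >= 0))
  expect_true(all(sc$M == round(sc$M)))
  cap <- sc$N * sc$samples_per_voxel
  expect_true(all(sc$M <= cap[row(sc$M)]))
  # deterministic given (config, subject index); distinct across subjects
  sc2 <- generate_streamline_counts(cfg, 3L)
  expect_identical(sc$M, sc2$M)
  expect_false(identical(sc$M, generate_streamline_counts(cfg, 4L)$M))
})

test_that("zero requested density yields an empty count matrix", {
  cfg <- small_cfg(sc_density = 0)
  expect_true(all(generate_streamline_counts(cfg, 1L)$M == 0))
})

test_that("nonzero-pair fraction tracks the configured density", {
  cfg <- cohort_config(n_subjects = 50L, n_regions = 30L,
                       samples_per_voxel = 200L,
                       voxels_per_region = c(5L, 15L),
                       sc_density = 0.3, planted_r2 = 0, seed = 11L)
  frac <- vapply(seq_len(50L), function(i) {
    M <- generate_streamline_counts(cfg, i)$M
    m <- M + t(M)
    mean(m[upper.tri(m)] > 0)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.3), 0.05)
})

test_that("functional matrices are symmetric Fisher-z of valid correlations", {
  cfg <- cohort_config(n_subjects = 5L, n_regions = 20L, planted_r2 = 0,
                       seed = 5L)
  for (i in 1:5) {
    Z <- generate_fc_fisher_z(cfg, i)
    expect_lte(max(abs(Z - t(Z))), 1e-12)
    expect_true(all(diag(Z) == 0))
    expect_true(all(is.finite(Z)))
    expect_true(all(abs(tanh(Z)) < 1))
  }
})

test_that("single noiseless latent factor gives rank-1 |z| structure", {
  cfg <- cohort_config(n_subjects = 2L, n_regions = 8L, fc_latent_dim = 1L,
                       fc_loading_sd = 0, fc_deviation_sd = 0,
                       fc_noise_sd = 0, planted_r2 = 0, seed = 2L)
  Z <- generate_fc_fisher_z(cfg, 1L)
  off <- abs(Z[upper.tri(Z)])
  expect_lt(diff(range(off)), 1e-10)
})

test_that("cohort generation is deterministic and records ground truth", {
  cfg <- small_cfg(planted_r2 = 0.4, planted_feature_set = "raw_sc",
                   n_signal_features = 3L)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$scores$values, co2$scores$values)
  expect_identical(co1$subjects[[5]]$sc_counts$M,
                   co2$subjects[[5]]$sc_counts$M)
  gt <- co1$ground_truth$domains[[1]]
  expect_length(gt$columns, 3L)
  expect_length(gt$beta, 3L)
  expect_gt(gt$noise_sd, 0)
})

test_that("null cohorts carry no planted signal", {
  co <- generate_cohort(small_cfg(planted_r2 = 0))
  expect_length(co$ground_truth$domains[[1]]$columns, 0L)
  expect_equal(dim(co$scores$values), c(10L, 5L))
})

test_that("sample R^2 of the generating predictor matches planted_r2", {
  r2 <- vapply(1:8, function(rep) {
    cfg <- cohort_config(n_subjects = 400L, n_regions = 10L,
                         samples_per_voxel = 200L,
                         voxels_per_region = c(5L, 15L), sc_density = 0.6,
                         planted_r2 = 0.5, planted_feature_set = "raw_sc",
                         n_signal_features = 5L, seed = 100L + rep)
    co <- generate_cohort(cfg)
    conns <- prepare_connectomes(co, "SC", cfg$retain_fraction)
    fm <- assemble_features(conns, "SC", "raw")
    gt <- co$ground_truth$domains[[1]]
    Xs <- scale(fm$X[, unlist(gt$columns), drop = FALSE])
    signal <- drop(Xs %*% unlist(gt$beta))
    y <- co$scores$values[, 1]
    coefficient_of_determination(y, signal + mean(y))
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.5), 0.05)
})

test_that("planted signal on graph-metric features is recoverable in-sample", {
  cfg <- cohort_config(n_subjects = 60L, n_regions = 10L,
                       samples_per_voxel = 200L,
                       voxels_per_region = c(5L, 15L), sc_density = 0.6,
                       planted_r2 = 0.6, planted_feature_set = "node",
                       n_signal_features = 3L, seed = 9L)
  co <- generate_cohort(cfg)
  gt <- co$ground_truth$domains[[1]]
  expect_length(gt$columns, 3L)
  expect_true(all(unlist(gt$features[["measure"]]) %in%
                    c("node_degree", "within_module_degree", "node_strength",
                      "clustering_coefficient", "eigenvector_centrality",
                      "betweenness_centrality", "participation_coefficient",
                      "node_eccentricity", "local_efficiency")))
})
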
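test_that("the coefficient of determination matches its definition", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(coefficient_of_determination(y, y), 1)
  expect_equal(coefficient_of_determination(y, rep(mean(y), 5)), 0)
  expect_lt(coefficient_of_determination(y, rev(y)), 0)
  expect_error(coefficient_of_determination(rep(1, 5), y), "constant")
})

test_that("stratified folds partition subjects and span the outcome range", {
  y <- rnorm(100)
  f <- connpred:::make_folds(y, 10L, seed = 3)
  expect_setequal(unique(f), 1:10)
  expect_true(all(table(f) == 10))
  # every fold sees both tails
  expect_true(all(tapply(y, f, min) < quantile(y, 0.35)))
  expect_true(all(tapply(y, f, max) > quantile(y, 0.65)))
  expect_error(connpred:::make_folds(rnorm(20), 10L, 1), "3 subjects")
})

test_that("cross-validation learns exactly learnable signal", {
  set.seed(21)
  X <- matrix(rnorm(200 * 10), 200, 10)
  y <- X[, 2] - 2 * X[, 7]          # noiseless linear target
  cv <- bbc_cv(X, y, folds = 10, B = 200, seed = 5)
  expect_gte(cv$r2_corrected, 0.95)
  expect_length(cv$r2_bootstrap, 200L)
  expect_length(cv$pooled_predictions, 200L)
  # bookkeeping: B controls the bootstrap count
  cv2 <- bbc_cv(X, y, folds = 5, B = 150, seed = 5)
  expect_length(cv2$r2_bootstrap, 150L)
})

test_that("cross-validation is deterministic given its seed", {
  set.seed(33)
  X <- matrix(rnorm(80 * 6), 80, 6)
  y <- X[, 1] + rnorm(80)
  a <- bbc_cv(X, y, folds = 5, B = 100, n_perm = 50, seed = 9)
  b <- bbc_cv(X, y, folds = 5, B = 100, n_perm = 50, seed = 9)
  expect_identical(a$pooled_predictions, b$pooled_predictions)
  expect_identical(a$r2_bootstrap, b$r2_bootstrap)
  expect_identical(a$p_value, b$p_value)
})

test_that("permutation p-values follow the add-one convention", {
  set.seed(7)
  y <- rnorm(100)
  pred <- y + rnorm(100, sd = 0.05)   # near-perfect: no null can exceed
  pt <- permutation_test(pred, y, n_perm = 1000, seed = 2)
  expect_equal(pt$p_value, 1 / 1001)
  # plain-proportion variant can reach zero
  expect_equal(permutation_test(pred, y, n_perm = 1000, seed = 2,
                                add_one = FALSE)$p_value, 0)
  # reported p is consistent with the returned null distribution
  pred2 <- rnorm(100)
  pt2 <- permutation_test(pred2, y, n_perm = 500, seed = 3)
  expect_equal(pt2$p_value,
               (1 + sum(pt2$null_distribution >= pt2$observed)) / 501)
})

test_that("ties with the observed statistic count as exceedances", {
  # duplicate-valued data make permuted statistics collide with the observed
  y <- rep(c(0, 1), 3)
  pred <- rep(c(0, 1), 3)
  pt <- permutation_test(pred, y, n_perm = 200, seed = 11)
  tied <- sum(abs(pt$null_distribution - pt$observed) < 1e-12)
  expect_gt(tied, 0)
  expect_gte(pt$p_value, (1 + tied) / 201)
})

test_that("rank-sum Z honours the first-argument sign convention", {
  w <- wilcoxon_ranksum(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_gt(w$Z, 0)
  expect_lt(wilcoxon_ranksum(c(1, 2, 3, 4), c(5, 6, 7, 8))$Z, 0)
  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))$Z, 0)
})

test_that("exact rank-sum p-values match exhaustive enumeration", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  w <- wilcoxon_ranksum(a, b, alternative = "less", exact = TRUE)
  expect_equal(w$statistic, 6)
  expect_equal(w$p_value, 0.05)
  # enumeration oracle over all C(6,3) = 20 rank assignments
  combos <- combn(6, 3)
  sums <- colSums(matrix(seq_len(6)[combos], 3))
  expect_equal(mean(sums <= 6), 0.05)
  # agreement with R's reference implementation on random data
  set.seed(14)
  x <- rnorm(12); z <- rnorm(9) + 0.5
  w2 <- wilcoxon_ranksum(x, z, exact = FALSE)
  ref <- suppressWarnings(wilcox.test(x, z, correct = TRUE, exact = FALSE))
  expect_equal(w2$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(wilcoxon_ranksum(x, z)$p_value,
               wilcox.test(x, z, exact = TRUE)$p.value, tolerance = 1e-10)
})

test_that("BIC differences map onto Kass-Raftery evidence bands", {
  expect_equal(delta_bic_category(2), "weak evidence for M2")
  expect_equal(delta_bic_category(10), "positive evidence for M2")
  expect_equal(delta_bic_category(-50), "strong evidence for M1")
  expect_equal(delta_bic_category(200), "very strong evidence for M2")
  expect_equal(delta_bic_category(0.5), "negligible evidence")
})

test_that("model comparison wires BIC evidence and bootstrap contrasts", {
  set.seed(41)
  X <- matrix(rnorm(100 * 6), 100, 6)
  y <- X[, 1] + rnorm(100, sd = 0.5)
  cv1 <- bbc_cv(X, y, folds = 5, B = 150, seed = 1)
  cv2 <- bbc_cv(X[, 3:6], y, folds = 5, B = 150, seed = 1)
  cmp <- compare_models(cv1$full_model$bic, cv2$full_model$bic, cv1, cv2)
  expect_lt(cmp$delta_bic, 0)       # informative model has lower BIC
  expect_match(cmp$category, "M1")
  expect_gt(cmp$wilcoxon_z, 0)      # and the better bootstrap distribution
  cv3 <- bbc_cv(X[1:60, ], y[1:60], folds = 5, B = 150, seed = 1)
  expect_error(compare_models(0, 0, cv1, cv3), "same cohort")
})
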
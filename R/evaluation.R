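## Validation layer: out-of-sample performance with bootstrap bias
## correction, permutation significance, and model-vs-model contrasts.

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. On held-out data
#' this can be negative: a model worse than predicting the mean.
#'
#' @param y observed outcomes (variance > 0).
#' @param y_hat predictions of the same length.
#' @return a single number, at most 1.
#' @export
coefficient_of_determination <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("outcome is constant; R^2 undefined", call. = FALSE)
  1 - sum((y - y_hat)^2) / tss
}

## Outcome-stratified fold assignment: subjects ordered by outcome are cut
## into quantile blocks of size `folds`, and fold labels are shuffled within
## each block, so every fold spans the outcome range.
make_folds <- function(y, folds, seed) {
  n <- length(y)
  if (n < 3 * folds)
    stop("need at least 3 subjects per fold", call. = FALSE)
  with_seed(seed, {
    fold <- integer(n)
    ord <- order(y, stats::runif(n))
    for (b in seq_len(ceiling(n / folds))) {
      blk <- ord[((b - 1L) * folds + 1L):min(b * folds, n)]
      fold[blk] <- sample(folds)[seq_along(blk)]
    }
    fold
  })
}

#' Bootstrap bias-corrected cross-validation of SWR-PCR
#'
#' K-fold cross-validation in which every preprocessing step (imputation of
#' undefined metric values, standardisation, PCA, stepwise selection) is
#' re-estimated inside each training fold, so no information leaks into the
#' held-out fold. Out-of-fold predictions are pooled over subjects; then B
#' bootstrap resamples of subject indices are drawn and the coefficient of
#' determination is computed on each resample's out-of-bag complement from
#' the pooled predictions. The mean of that distribution is the
#' bias-corrected performance estimate. Optionally a permutation test on the
#' pooled predictions is run (see [permutation_test()]).
#'
#' @param X subjects x features matrix or `feature_matrix`.
#' @param y outcome vector.
#' @param folds number of cross-validation folds (default 10).
#' @param B number of bootstrap resamples (default 1000).
#' @param n_perm permutations for the significance test (0 to skip).
#' @param seed integer seed for fold assignment, bootstrap and permutation.
#' @param direction stepwise direction, see [stepwise_bic()].
#' @return object of class `cv_result`: `pooled_predictions`,
#'   `r2_apparent` (in-sample R^2 of the model fitted on all subjects),
#'   `r2_bootstrap`, `r2_corrected`, `permutation_null`, `p_value`,
#'   `full_model` (the all-subject `pcr_model`) and `config`.
#' @export
bbc_cv <- function(X, y, folds = 10L, B = 1000L, n_perm = 0L, seed = 1L,
                   direction = "both") {
  if (inherits(X, "feature_matrix")) X <- X$X
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, folds >= 2, B >= 100)

  fold <- make_folds(y, folds, sub_seed(seed, 1L, 21L))
  pooled <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    imp <- impute_columns(X[tr, , drop = FALSE])
    st <- standardise(imp$X, on_constant = "zero")
    model <- fit_swr_pcr(st$X, y[tr], standardise_features = FALSE,
                         direction = direction)
    te <- impute_columns(X[!tr, , drop = FALSE], means = imp$means)$X
    te <- sweep(sweep(te, 2L, st$center), 2L, st$scale, "/")
    pooled[!tr] <- predict(model, te)
  }

  imp <- impute_columns(X)
  full <- fit_swr_pcr(imp$X, y, direction = direction)
  r2_app <- coefficient_of_determination(y, predict(full, imp$X))

  r2_boot <- with_seed(sub_seed(seed, 2L, 22L), {
    vapply(seq_len(B), function(b) {
      repeat {
        inb <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), unique(inb))
        if (length(oob) >= 2 && stats::sd(y[oob]) > 0) break
      }
      coefficient_of_determination(y[oob], pooled[oob])
    }, numeric(1))
  })
  r2_obs <- coefficient_of_determination(y, pooled)

  perm <- if (n_perm > 0)
    permutation_test(pooled, y, n_perm = n_perm,
                     seed = sub_seed(seed, 3L, 23L))
  else list(null_distribution = numeric(0), p_value = NA_real_)

  structure(list(pooled_predictions = pooled,
                 r2_observed = r2_obs,
                 r2_apparent = r2_app,
                 r2_bootstrap = r2_boot,
                 r2_corrected = mean(r2_boot),
                 permutation_null = perm$null_distribution,
                 p_value = perm$p_value,
                 full_model = full,
                 config = list(folds = folds, B = B, n_perm = n_perm,
                               seed = seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> corrected R^2 = %.3f (apparent %.3f, pooled %.3f)",
              x$r2_corrected, x$r2_apparent, x$r2_observed))
  if (!is.na(x$p_value)) cat(sprintf(", permutation p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

#' Permutation test of predictive performance
#'
#' Shuffles the pairing of pooled out-of-fold predictions with outcomes
#' (sampling without replacement) and recomputes the coefficient of
#' determination each time. The p-value is the proportion of permuted
#' statistics at least as high as the observed one; by default the add-one
#' (Phipson-Smyth) correction is applied so p is never exactly 0, with the
#' plain proportion available via `add_one = FALSE`.
#'
#' @param predictions pooled out-of-sample predictions.
#' @param y observed outcomes.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param add_one apply the add-one correction (default TRUE).
#' @return list with `null_distribution`, `observed` and `p_value`.
#' @export
permutation_test <- function(predictions, y, n_perm = 10000L, seed = 1L,
                             add_one = TRUE) {
  stopifnot(length(predictions) == length(y), n_perm >= 1)
  n <- length(y)
  obs <- coefficient_of_determination(y, predictions)
  tss <- sum((y - mean(y))^2)
  sum_y2 <- sum(y^2); sum_p2 <- sum(predictions^2)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    yp <- y[sample.int(n)]
    1 - (sum_y2 + sum_p2 - 2 * sum(yp * predictions)) / tss
  }, numeric(1)))
  exceed <- sum(null >= obs)
  p <- if (add_one) (1 + exceed) / (1 + n_perm) else exceed / n_perm
  list(null_distribution = null, observed = obs, p_value = p)
}

#' Wilcoxon rank-sum test (first-argument convention)
#'
#' Two-sample rank-sum test for equal medians with midranks for ties. The
#' normal approximation uses the tie-corrected variance and a continuity
#' correction; `Z > 0` means the first sample is stochastically larger. For
#' small tie-free samples an exact p-value from the rank-sum distribution is
#' available.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param alternative `"two.sided"` (default), `"greater"` (a larger) or
#'   `"less"`.
#' @param exact use the exact null distribution. The default (`NULL`)
#'   chooses the exact distribution for tie-free pooled samples of at most
#'   50 values, where the normal approximation is visibly coarse, and the
#'   normal approximation otherwise; `exact = TRUE` with ties falls back to
#'   the normal approximation with a warning.
#' @param continuity apply the 0.5 continuity correction (normal
#'   approximation only).
#' @return list with `Z`, `p_value`, rank-sum `statistic` of `a`, and
#'   `method`.
#' @export
wilcoxon_ranksum <- function(a, b,
                             alternative = c("two.sided", "greater", "less"),
                             exact = NULL, continuity = TRUE) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) >= 2, length(b) >= 2)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  R1 <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2

  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))

  d <- R1 - mu
  if (v <= 0) {
    Z <- 0
  } else {
    cc <- if (continuity) 0.5 * sign(d) else 0
    Z <- (d - cc) / sqrt(v)
  }

  has_ties <- any(ties > 1)
  if (is.null(exact)) exact <- !has_ties && N <= 50
  if (exact && !has_ties) {
    U <- R1 - n1 * (n1 + 1) / 2
    p <- switch(alternative,
      greater = stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE),
      less = stats::pwilcox(U, n1, n2),
      two.sided = min(1, 2 * min(stats::pwilcox(U, n1, n2),
                                 stats::pwilcox(U - 1, n1, n2,
                                                lower.tail = FALSE))))
    method <- "exact"
  } else {
    if (exact && has_ties)
      warning("ties present; falling back to the normal approximation",
              call. = FALSE)
    p <- switch(alternative,
      greater = stats::pnorm(Z, lower.tail = FALSE),
      less = stats::pnorm(Z),
      two.sided = 2 * stats::pnorm(-abs(Z)))
    method <- "normal approximation"
  }
  list(Z = Z, p_value = p, statistic = R1, method = method)
}

#' Kass-Raftery evidence category for a BIC difference
#'
#' `delta_bic = BIC(M1) - BIC(M2)`; a positive difference favours M2. Bands
#' on the magnitude: < 1 negligible, 1-3 weak (barely worth a mention),
#' 3-20 positive, 20-150 strong, > 150 very strong.
#'
#' @param delta_bic numeric BIC difference.
#' @return character label such as `"positive evidence for M2"`.
#' @export
delta_bic_category <- function(delta_bic) {
  m <- abs(delta_bic)
  strength <- if (m < 1) "negligible"
  else if (m <= 3) "weak"
  else if (m <= 20) "positive"
  else if (m <= 150) "strong"
  else "very strong"
  if (strength == "negligible") return("negligible evidence")
  sprintf("%s evidence for %s", strength, if (delta_bic > 0) "M2" else "M1")
}

#' Compare two fitted models: BIC evidence and performance contrast
#'
#' Computes `delta_bic = BIC(M1) - BIC(M2)` with its Kass-Raftery category,
#' and, when both cross-validation results are supplied, a Wilcoxon
#' rank-sum contrast of the two bootstrap R^2 distributions (`Z > 0` means
#' model 1's distribution is larger). Whether a comparison should be run at
#' all -- the better-than-chance gate on both permutation p-values -- is the
#' caller's policy.
#'
#' @param model1_bic,model2_bic in-sample BIC values of the two models.
#' @param cv1,cv2 optional `cv_result` objects for the same subjects.
#' @return object of class `model_comparison`: `delta_bic`, `category`,
#'   `wilcoxon_z`, `wilcoxon_p`.
#' @export
compare_models <- function(model1_bic, model2_bic, cv1 = NULL, cv2 = NULL) {
  delta <- model1_bic - model2_bic
  wz <- wp <- NA_real_
  if (!is.null(cv1) && !is.null(cv2)) {
    stopifnot(inherits(cv1, "cv_result"), inherits(cv2, "cv_result"))
    if (length(cv1$pooled_predictions) != length(cv2$pooled_predictions))
      stop("models were not evaluated on the same cohort", call. = FALSE)
    w <- wilcoxon_ranksum(cv1$r2_bootstrap, cv2$r2_bootstrap)
    wz <- w$Z; wp <- w$p_value
  }
  structure(list(delta_bic = delta, category = delta_bic_category(delta),
                 wilcoxon_z = wz, wilcoxon_p = wp),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> dBIC = %.2f (%s)", x$delta_bic,
              x$category))
  if (!is.na(x$wilcoxon_z))
    cat(sprintf("; Wilcoxon Z = %.2f, p = %.3g", x$wilcoxon_z,
                x$wilcoxon_p))
  cat("\n")
  invisible(x)
}
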
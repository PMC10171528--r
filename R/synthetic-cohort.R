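## Synthetic connectome cohort generator.
##
## Per-subject matrices are a cohort template plus a seeded subject deviation,
## so between-subject variance (what the regression consumes) is controlled
## explicitly. Structural counts emulate probabilistic-tractography output:
## an asymmetric matrix of streamline counts M[i,j] bounded by N[i] seed
## voxels times the streamlines initiated per voxel. Functional matrices are
## Fisher-z transforms of correlation matrices induced by shared latent
## factors, so they carry realistic positive-semidefinite structure rather
## than element-wise noise.

## Cohort-level structural template: seed-voxel counts, the upper-triangle
## edge indicator, and per-edge connection probabilities (heavy-tailed, so
## weight distributions look like streamline densities).
sc_template <- function(config) {
  with_seed(sub_seed(config$seed, 0L, 1L), {
    n <- config$n_regions
    N <- sample(seq(config$voxels_per_region[1], config$voxels_per_region[2]),
                n, replace = TRUE)
    m <- n * (n - 1L) / 2L
    edge <- stats::runif(m) < config$sc_density
    p <- ifelse(edge, pmin(0.8, stats::rlnorm(m, meanlog = log(0.02),
                                              sdlog = 1)), 0)
    list(N = N, p_upper = p)
  })
}

## Cohort-level functional template: region loadings on latent factors.
## Row i is a q-vector with norm < 1; the implied population correlation is
## R = U U' off the diagonal (unit diagonal), which is positive semidefinite.
fc_template <- function(config) {
  with_seed(sub_seed(config$seed, 0L, 2L), {
    n <- config$n_regions
    q <- config$fc_latent_dim
    mag <- pmin(0.95, pmax(0.05, config$fc_loading_mean +
                             config$fc_loading_sd * stats::rnorm(n)))
    dir <- matrix(stats::rnorm(n * q), n, q)
    dir <- dir / sqrt(rowSums(dir^2))
    dir * mag
  })
}

#' Generate one subject's streamline-count matrix
#'
#' Emulates ROI-to-ROI probabilistic tractography output: `M[i, j]` counts
#' streamlines seeded in region i that reached region j, out of
#' `N[i] * samples_per_voxel` initiated. Counts are asymmetric
#' (`M[i, j] != M[j, i]` in general) but correlated across directions because
#' both are binomial draws from the same subject-level connection probability.
#'
#' @param config a [cohort_config()].
#' @param subject_index 1-based subject index; output is deterministic given
#'   `(config$seed, subject_index)`.
#' @return an object of class `streamline_counts`: list with integer matrix
#'   `M` (zero diagonal), integer vector `N` of seed-voxel counts,
#'   `samples_per_voxel`, and `region_labels`.
#' @export
generate_streamline_counts <- function(config, subject_index) {
  stopifnot(inherits(config, "cohort_config"))
  tmpl <- sc_template(config)
  n <- config$n_regions
  spv <- config$samples_per_voxel
  with_seed(sub_seed(config$seed, subject_index, 3L), {
    dev <- exp(config$sc_deviation_sd * stats::rnorm(length(tmpl$p_upper)) -
                 config$sc_deviation_sd^2 / 2)
    p <- pmin(0.9, tmpl$p_upper * dev)
    idx <- upper_tri_pairs(n)
    M <- matrix(0, n, n)
    sz_i <- tmpl$N[idx[, 1L]] * spv
    sz_j <- tmpl$N[idx[, 2L]] * spv
    M[idx] <- stats::rbinom(nrow(idx), sz_i, p)
    M[idx[, c(2L, 1L)]] <- stats::rbinom(nrow(idx), sz_j, p)
    structure(list(M = M, N = tmpl$N, samples_per_voxel = spv,
                   region_labels = region_labels_for(n)),
              class = "streamline_counts")
  })
}

#' Generate one subject's functional connectivity matrix (Fisher-z scale)
#'
#' Correlations arise from a latent-factor model: region time-series load on
#' `fc_latent_dim` shared factors, the population correlation between regions
#' i and j is the inner product of their loading rows, and the matrix is
#' reported on the Fisher-z scale with additive symmetric measurement noise.
#'
#' @inheritParams generate_streamline_counts
#' @return symmetric numeric matrix with zero diagonal; `tanh()` of every
#'   entry is a valid correlation in (-1, 1).
#' @export
generate_fc_fisher_z <- function(config, subject_index) {
  stopifnot(inherits(config, "cohort_config"))
  U0 <- fc_template(config)
  n <- config$n_regions
  with_seed(sub_seed(config$seed, subject_index, 4L), {
    U <- U0 + config$fc_deviation_sd *
      matrix(stats::rnorm(length(U0)), nrow(U0), ncol(U0))
    nrm <- sqrt(rowSums(U^2))
    over <- nrm > 0.95
    if (any(over)) U[over, ] <- U[over, , drop = FALSE] * (0.95 / nrm[over])
    R <- tcrossprod(U)
    diag(R) <- 0
    Z <- atanh(R)
    if (config$fc_noise_sd > 0) {
      E <- matrix(0, n, n)
      idx <- upper_tri_pairs(n)
      E[idx] <- stats::rnorm(nrow(idx), sd = config$fc_noise_sd)
      Z <- Z + E + t(E)
    }
    dimnames(Z) <- list(region_labels_for(n), region_labels_for(n))
    Z
  })
}

## Design matrix on which the signal is planted: computed by running the
## *downstream* modules on the generated matrices, so the ground truth refers
## to quantities the analysis pipeline actually sees.
planted_design <- function(subjects, config) {
  set <- config$planted_feature_set
  rf <- config$retain_fraction
  if (set %in% c("raw_sc", "raw_fc")) {
    conns <- lapply(subjects, function(s) {
      w <- if (set == "raw_sc") sc_weight_matrix(s$sc_counts)
           else fc_from_fisher_z(s$fc_z)
      proportional_threshold(w, rf)
    })
    assemble_features(conns, modality = if (set == "raw_sc") "SC" else "FC",
                      set_name = "raw")
  } else {
    conns <- lapply(subjects, function(s)
      proportional_threshold(sc_weight_matrix(s$sc_counts), rf))
    metrics <- lapply(seq_along(conns), function(i)
      compute_subject_metrics(conns[[i]],
                              seed = sub_seed(config$seed, i, 9L),
                              swp_nulls = 5L))
    assemble_features(conns, modality = "SC", set_name = set,
                      metrics = metrics)
  }
}

#' Generate a full synthetic cohort with planted cognitive signal
#'
#' Generates paired structural/functional matrices for every subject, then
#' builds cognitive domain scores as `y = X beta + eps`, where `X` is the
#' configured feature set computed from the generated matrices by the same
#' code the analysis pipeline uses, `beta` is nonzero on
#' `n_signal_features` columns, and the noise scale is chosen so that
#' `var(X beta) / var(y) = planted_r2` in expectation. The generating
#' features, coefficients and noise sd are stored as ground truth.
#'
#' @param config a [cohort_config()].
#' @return object of class `connectome_cohort`: list with `subjects` (each a
#'   list of `sc_counts` and `fc_z`), `scores` (a `cognitive_scores` object),
#'   `ground_truth` and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- lapply(seq_len(config$n_subjects), function(i)
    list(id = sprintf("sub-%04d", i),
         sc_counts = generate_streamline_counts(config, i),
         fc_z = generate_fc_fisher_z(config, i)))

  nd <- length(config$domain_labels)
  n <- config$n_subjects
  scores <- matrix(NA_real_, n, nd,
                   dimnames = list(vapply(subjects, `[[`, "", "id"),
                                   config$domain_labels))
  gt <- list(planted_feature_set = config$planted_feature_set,
             planted_r2 = config$planted_r2, domains = list())

  if (config$planted_r2 > 0) {
    fm <- planted_design(subjects, config)
    sds <- apply(fm$X, 2, stats::sd)
    usable <- which(sds > 1e-10)
    if (length(usable) < config$n_signal_features)
      stop("planted feature set has fewer non-constant columns (",
           length(usable), ") than `n_signal_features`", call. = FALSE)
    sel <- with_seed(sub_seed(config$seed, 0L, 5L),
                     sort(sample(usable, config$n_signal_features)))
    Xs <- scale(fm$X[, sel, drop = FALSE])
    for (d in seq_len(nd)) {
      with_seed(sub_seed(config$seed, d, 6L), {
        beta <- stats::rnorm(length(sel))
        signal <- drop(Xs %*% beta)
        eps_sd <- stats::sd(signal) *
          sqrt((1 - config$planted_r2) / config$planted_r2)
        scores[, d] <- signal + stats::rnorm(n, sd = eps_sd)
        gt$domains[[d]] <- list(domain = config$domain_labels[d],
                                 features = fm$labels[sel, , drop = FALSE],
                                 columns = sel, beta = beta,
                                 noise_sd = eps_sd)
      })
    }
  } else {
    for (d in seq_len(nd)) {
      scores[, d] <- with_seed(sub_seed(config$seed, d, 6L),
                               stats::rnorm(n))
      gt$domains[[d]] <- list(domain = config$domain_labels[d],
                              features = NULL, columns = integer(0),
                              beta = numeric(0), noise_sd = 1)
    }
  }

  structure(list(subjects = subjects,
                 scores = cognitive_scores(scores, config$domain_labels, gt),
                 ground_truth = gt,
                 config = config),
            class = "connectome_cohort")
}

#' Container for per-subject cognitive domain scores
#'
#' @param values subjects x domains numeric matrix.
#' @param domain_labels character vector of domain names.
#' @param ground_truth optional record of the generating model (present only
#'   for synthetic scores).
#' @return object of class `cognitive_scores`.
#' @export
cognitive_scores <- function(values, domain_labels = colnames(values),
                             ground_truth = NULL) {
  values <- as.matrix(values)
  colnames(values) <- domain_labels
  structure(list(values = values, domain_labels = domain_labels,
                 ground_truth = ground_truth),
            class = "cognitive_scores")
}

#' @export
print.connectome_cohort <- function(x, ...) {
  cat(sprintf("Synthetic connectome cohort: %d subjects, %d regions\n",
              length(x$subjects), x$config$n_regions))
  cat(sprintf("  planted R2 %.2f on '%s' features\n",
              x$config$planted_r2, x$config$planted_feature_set))
  invisible(x)
}
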
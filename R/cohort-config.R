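#' Configuration for a synthetic connectome cohort
#'
#' Bundles every knob of the synthetic cohort generator. The defaults mirror
#' the study conditions the pipeline is designed for: a 249-subject adult
#' cohort on a 278-region functional parcellation, probabilistic tractography
#' initiating 5000 streamlines per seed voxel, and resting-state functional
#' connectivity reported as Fisher-z ROI-to-ROI correlations. All sizes are
#' configurable down to toy scales for testing.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param n_regions number of parcellation regions (graph nodes), at least 4.
#' @param samples_per_voxel streamlines initiated per seed voxel (default 5000).
#' @param voxels_per_region length-2 integer range; each region's seed-voxel
#'   count is drawn uniformly from it.
#' @param sc_density expected fraction of region pairs connected by at least
#'   one streamline, in (0, 1].
#' @param sc_deviation_sd per-subject deviation of connection probabilities
#'   around the cohort template, on the connection-probability scale.
#' @param fc_latent_dim number of latent signal factors shared across regions
#'   that induce the functional correlation structure.
#' @param fc_loading_mean,fc_loading_sd mean and spread of the magnitude of
#'   region loadings on the latent factors; `fc_loading_sd = 0` gives every
#'   region the same coupling strength.
#' @param fc_deviation_sd per-subject deviation of the loading matrix around
#'   the cohort template.
#' @param fc_noise_sd measurement noise added to the Fisher-z matrix.
#' @param planted_r2 fraction of cognitive-score variance explained by the
#'   planted linear signal, in [0, 1).
#' @param planted_feature_set which downstream feature set carries the planted
#'   signal: one of `"raw_sc"`, `"raw_fc"`, `"node"`, `"edge"`, `"global"`.
#' @param n_signal_features number of feature columns with nonzero planted
#'   coefficients.
#' @param retain_fraction proportional-threshold retain fraction used when the
#'   generator computes the features it plants signal on.
#' @param domain_labels names of the cognitive domains scored per subject.
#' @param seed integer seed; all generator output is a pure function of
#'   `(config, seed)`.
#'
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 249L,
                          n_regions = 278L,
                          samples_per_voxel = 5000L,
                          voxels_per_region = c(50L, 150L),
                          sc_density = 0.7,
                          sc_deviation_sd = 0.1,
                          fc_latent_dim = 5L,
                          fc_loading_mean = 0.5,
                          fc_loading_sd = 0.15,
                          fc_deviation_sd = 0.1,
                          fc_noise_sd = 0.1,
                          planted_r2 = 0.3,
                          planted_feature_set = c("raw_sc", "raw_fc",
                                                  "node", "edge", "global"),
                          n_signal_features = 5L,
                          retain_fraction = 0.2,
                          domain_labels = c("Executive Function",
                                            "Self-regulation", "Language",
                                            "Encoding", "Sequence Processing"),
                          seed = 1L) {
  planted_feature_set <- match.arg(planted_feature_set)
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("`n_subjects` must be a positive integer", call. = FALSE)
  if (!is.numeric(n_regions) || n_regions < 4)
    stop("`n_regions` must be an integer >= 4", call. = FALSE)
  if (!is.numeric(samples_per_voxel) || samples_per_voxel < 1)
    stop("`samples_per_voxel` must be a positive integer", call. = FALSE)
  if (length(voxels_per_region) != 2L || any(voxels_per_region < 1) ||
      voxels_per_region[1] > voxels_per_region[2])
    stop("`voxels_per_region` must be a nondecreasing positive range",
         call. = FALSE)
  stopifnot_scalar_in(sc_density, 0, 1, "sc_density")
  stopifnot_scalar_in(planted_r2, 0, 1, "planted_r2", hi_open = TRUE)
  stopifnot_scalar_in(retain_fraction, 0, 1, "retain_fraction", lo_open = TRUE)
  if (fc_noise_sd < 0 || sc_deviation_sd < 0 || fc_deviation_sd < 0)
    stop("noise and deviation scales must be nonnegative", call. = FALSE)
  if (n_signal_features < 1)
    stop("`n_signal_features` must be a positive integer", call. = FALSE)

  structure(list(
    n_subjects = as.integer(n_subjects),
    n_regions = as.integer(n_regions),
    samples_per_voxel = as.integer(samples_per_voxel),
    voxels_per_region = as.integer(voxels_per_region),
    sc_density = sc_density,
    sc_deviation_sd = sc_deviation_sd,
    fc_latent_dim = as.integer(fc_latent_dim),
    fc_loading_mean = fc_loading_mean,
    fc_loading_sd = fc_loading_sd,
    fc_deviation_sd = fc_deviation_sd,
    fc_noise_sd = fc_noise_sd,
    planted_r2 = planted_r2,
    planted_feature_set = planted_feature_set,
    n_signal_features = as.integer(n_signal_features),
    retain_fraction = retain_fraction,
    domain_labels = domain_labels,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d subjects, %d regions, %d streamlines/voxel\n",
              x$n_subjects, x$n_regions, x$samples_per_voxel))
  cat(sprintf("  SC density %.2f; FC latent dim %d (noise sd %.2f)\n",
              x$sc_density, x$fc_latent_dim, x$fc_noise_sd))
  cat(sprintf("  planted signal: R2 = %.2f on %d '%s' features; seed %d\n",
              x$planted_r2, x$n_signal_features, x$planted_feature_set,
              x$seed))
  invisible(x)
}

region_labels_for <- function(n) sprintf("R%03d", seq_len(n))
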
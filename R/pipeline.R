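## End-to-end driver: cohort -> connectomes -> metrics -> feature sets ->
## SWR-PCR -> validation -> model-vs-model comparison.

#' Prepare thresholded connectomes for every subject of a cohort
#'
#' @param cohort a `connectome_cohort`.
#' @param modality `"SC"` or `"FC"`.
#' @param retain_fraction proportional-threshold retain fraction.
#' @return list of thresholded [connectome()]s.
#' @export
prepare_connectomes <- function(cohort, modality = c("SC", "FC"),
                                retain_fraction = 0.2) {
  modality <- match.arg(modality)
  lapply(cohort$subjects, function(s) {
    w <- if (modality == "SC") sc_weight_matrix(s$sc_counts)
         else fc_from_fisher_z(s$fc_z)
    proportional_threshold(w, retain_fraction)
  })
}

#' Run the full prediction study on a cohort
#'
#' For every requested feature family and modality, fits the SWR-PCR model
#' on all subjects (in-sample BIC), validates it with BBC-CV and a
#' permutation test, and contrasts each graph-theory family against the raw
#' connectivity reference of the same modality (BIC difference with
#' Kass-Raftery category; Wilcoxon rank-sum on the bootstrap R^2
#' distributions, run only when both models beat chance at the configured
#' alpha).
#'
#' @param cohort a `connectome_cohort` (see [generate_cohort()]).
#' @param sets feature families to fit (see [assemble_features()]; `"raw"`
#'   is always added as the reference).
#' @param modalities any of `"SC"`, `"FC"`, `"CC"`.
#' @param domain cognitive domain name or index to model (default: all).
#' @param retain_fraction proportional-threshold retain fraction.
#' @param folds,B,n_perm validation configuration, see [bbc_cv()].
#' @param swp_nulls null instances for the small-world propensity.
#' @param alpha better-than-chance gate for the Wilcoxon contrast.
#' @param seed integer seed for every stochastic step.
#' @return object of class `study_result`: nested list
#'   `models[[modality]][[set]][[domain]]` with `fit`, `cv`, and
#'   `comparisons[[modality]][[set]][[domain]]` against raw connectivity.
#' @export
run_study <- function(cohort, sets = c("global", "node"),
                      modalities = c("SC", "FC"), domain = NULL,
                      retain_fraction = 0.2, folds = 10L, B = 1000L,
                      n_perm = 1000L, swp_nulls = 10L, alpha = 0.05,
                      seed = 1L) {
  stopifnot(inherits(cohort, "connectome_cohort"))
  sets <- union("raw", sets)
  base_mods <- intersect(c("SC", "FC"),
                         if ("CC" %in% modalities) c("SC", "FC")
                         else modalities)
  conns <- lapply(stats::setNames(base_mods, base_mods), function(m)
    prepare_connectomes(cohort, m, retain_fraction))

  need_metrics <- any(sets %in% c("global", "node", "edge", "local",
                                  "global_and_local"))
  metrics <- if (need_metrics)
    lapply(stats::setNames(base_mods, base_mods), function(m)
      lapply(seq_along(conns[[m]]), function(i)
        compute_subject_metrics(conns[[m]][[i]],
                                seed = sub_seed(seed, i,
                                                if (m == "SC") 31L else 32L),
                                swp_nulls = swp_nulls)))
  else NULL

  features <- list()
  for (m in base_mods) for (s in sets) {
    features[[m]][[s]] <- assemble_features(conns[[m]], m, s,
                                            metrics = metrics[[m]])
  }
  if ("CC" %in% modalities) for (s in sets)
    features[["CC"]][[s]] <- combine_features(features[["SC"]][[s]],
                                              features[["FC"]][[s]])

  Y <- cohort$scores$values
  domains <- if (is.null(domain)) colnames(Y)
             else colnames(Y)[match(domain, colnames(Y), nomatch = domain)]

  models <- list(); comparisons <- list()
  for (m in names(features)) for (s in sets) {
    fm <- features[[m]][[s]]
    for (d in domains) {
      y <- Y[, d]
      cv <- bbc_cv(fm, y, folds = folds, B = B, n_perm = n_perm,
                   seed = sub_seed(seed, match(d, domains),
                                   40L + match(s, sets)))
      models[[m]][[s]][[d]] <- list(fit = cv$full_model, cv = cv)
    }
  }
  for (m in names(features)) for (s in setdiff(sets, "raw")) for (d in domains) {
    raw <- models[[m]][["raw"]][[d]]
    gt <- models[[m]][[s]][[d]]
    both_beat_chance <- !is.na(raw$cv$p_value) && !is.na(gt$cv$p_value) &&
      raw$cv$p_value < alpha && gt$cv$p_value < alpha
    comparisons[[m]][[s]][[d]] <- compare_models(
      raw$fit$bic, gt$fit$bic,
      cv1 = if (both_beat_chance) raw$cv else NULL,
      cv2 = if (both_beat_chance) gt$cv else NULL)
  }

  structure(list(models = models, comparisons = comparisons,
                 domains = domains, sets = sets,
                 modalities = names(features),
                 config = list(retain_fraction = retain_fraction,
                               folds = folds, B = B, n_perm = n_perm,
                               alpha = alpha, seed = seed)),
            class = "study_result")
}

#' Summarise a study as a long-format data frame
#'
#' @param object a `study_result`.
#' @param ... unused.
#' @return data frame with one row per (modality, set, domain):
#'   in-sample BIC, apparent and corrected R^2, permutation p, and -- for
#'   graph-theory sets -- the BIC difference against raw connectivity, its
#'   evidence category and the Wilcoxon Z.
#' @export
summary.study_result <- function(object, ...) {
  rows <- list()
  for (m in names(object$models)) for (s in names(object$models[[m]]))
    for (d in names(object$models[[m]][[s]])) {
      e <- object$models[[m]][[s]][[d]]
      cmp <- object$comparisons[[m]][[s]][[d]]
      rows[[length(rows) + 1L]] <- data.frame(
        modality = m, set = s, domain = d,
        n_components = length(e$fit$selected),
        bic = e$fit$bic,
        r2_apparent = e$cv$r2_apparent,
        r2_corrected = e$cv$r2_corrected,
        p_perm = e$cv$p_value,
        delta_bic_vs_raw = if (is.null(cmp)) NA_real_ else cmp$delta_bic,
        evidence = if (is.null(cmp)) NA_character_ else cmp$category,
        wilcoxon_z = if (is.null(cmp)) NA_real_ else cmp$wilcoxon_z)
    }
  do.call(rbind, rows)
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  print(summary(x), digits = 3)
  invisible(x)
}
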
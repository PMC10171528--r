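## Feature assembly: turn per-subject connectomes and their graph metrics
## into the predictor matrices the regression consumes.

#' Compute the full metric battery for one subject's connectome
#'
#' @param conn a thresholded [connectome()].
#' @param seed seed for the seeded heuristics (partition, propensity nulls,
#'   core-periphery search).
#' @param swp_nulls null instances per type for the small-world propensity.
#' @return list with `node` (regions x 9 matrix), `edge` (list of three
#'   symmetric matrices), `global` (named length-8 vector) and `partition`.
#' @export
compute_subject_metrics <- function(conn, seed = 1L, swp_nulls = 10L) {
  dist <- shortest_path_lengths(conn)
  part <- community_partition(conn, seed = seed)
  swp <- small_world_propensity(conn, n_nulls = swp_nulls, seed = seed)
  core <- core_periphery_size(conn, seed = seed)
  list(node = node_metrics(conn, dist, part),
       edge = edge_metrics(conn, dist),
       global = global_metrics(conn, dist, part, swp = swp,
                               core_size = core),
       partition = part)
}

feature_matrix <- function(X, labels, set_name, modality) {
  stopifnot(nrow(labels) == ncol(X))
  colnames(X) <- paste(labels$modality, labels$measure, labels$element,
                       sep = "|")
  structure(list(X = X, labels = labels, set_name = set_name,
                 modality = modality),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> set '%s', modality %s: %d subjects x %d features\n",
              x$set_name, x$modality, nrow(x$X), ncol(x$X)))
  invisible(x)
}

edge_element_labels <- function(region_labels, idx) {
  paste(region_labels[idx[, 1L]], region_labels[idx[, 2L]], sep = "-")
}

#' Assemble a predictor matrix from a cohort of connectomes
#'
#' Builds the subjects x features matrix for one modality and one feature
#' family: `"raw"` vectorises the upper triangle of the thresholded weight
#' matrix; `"global"` stacks the 8 global measures; `"node"` stacks all 9
#' node measures for every region; `"edge"` stacks the 3 edge measures over
#' the union of edges surviving thresholding in any subject (subjects
#' lacking an edge contribute 0 there); `"local"` is node plus edge;
#' `"global_and_local"` is all three. Every column carries a
#' (modality, measure, element) label.
#'
#' @param conns list of thresholded [connectome()]s, one per subject, same
#'   region set.
#' @param modality `"SC"` or `"FC"` label recorded on the features.
#' @param set_name one of `"raw"`, `"global"`, `"node"`, `"edge"`,
#'   `"local"`, `"global_and_local"`.
#' @param metrics optional precomputed list from
#'   [compute_subject_metrics()], one per subject (computed here if omitted
#'   and the set needs them).
#' @param seed,swp_nulls passed to [compute_subject_metrics()] when metrics
#'   are computed here.
#' @return a `feature_matrix` object.
#' @export
assemble_features <- function(conns, modality = c("SC", "FC"),
                              set_name = c("raw", "global", "node", "edge",
                                           "local", "global_and_local"),
                              metrics = NULL, seed = 1L, swp_nulls = 10L) {
  modality <- match.arg(modality)
  set_name <- match.arg(set_name)
  n_sub <- length(conns)
  stopifnot(n_sub > 0)
  rl <- conns[[1L]]$region_labels
  n <- length(rl)

  if (set_name == "raw") {
    idx <- upper_tri_pairs(n)
    X <- t(vapply(conns, function(cn) cn$W[idx], numeric(nrow(idx))))
    labels <- data.frame(modality = modality, measure = "raw",
                         element = edge_element_labels(rl, idx))
    return(feature_matrix(X, labels, "raw", modality))
  }

  if (is.null(metrics))
    metrics <- lapply(seq_len(n_sub), function(i)
      compute_subject_metrics(conns[[i]], seed = sub_seed(seed, i),
                              swp_nulls = swp_nulls))

  blocks <- list()
  want <- switch(set_name,
                 global = "global", node = "node", edge = "edge",
                 local = c("node", "edge"),
                 global_and_local = c("global", "node", "edge"))

  if ("global" %in% want) {
    X <- t(vapply(metrics, `[[`, numeric(8L), "global"))
    blocks$global <- feature_matrix(
      X, data.frame(modality = modality, measure = global_metric_names,
                    element = "global"),
      "global", modality)
  }
  if ("node" %in% want) {
    X <- do.call(cbind, lapply(node_metric_names, function(m)
      t(vapply(metrics, function(mt) mt$node[, m], numeric(n)))))
    labels <- data.frame(
      modality = modality,
      measure = rep(node_metric_names, each = n),
      element = rep(rl, times = length(node_metric_names)))
    blocks$node <- feature_matrix(X, labels, "node", modality)
  }
  if ("edge" %in% want) {
    idx <- upper_tri_pairs(n)
    present <- Reduce(`|`, lapply(conns, function(cn) cn$W[idx] > 0))
    eidx <- idx[present, , drop = FALSE]
    X <- do.call(cbind, lapply(edge_metric_names, function(m)
      t(vapply(seq_len(n_sub), function(i) {
        vals <- metrics[[i]]$edge[[m]][eidx]
        vals[conns[[i]]$W[eidx] == 0] <- 0
        vals
      }, numeric(nrow(eidx))))))
    labels <- data.frame(
      modality = modality,
      measure = rep(edge_metric_names, each = nrow(eidx)),
      element = rep(edge_element_labels(rl, eidx),
                    times = length(edge_metric_names)))
    blocks$edge <- feature_matrix(X, labels, "edge", modality)
  }
  out <- Reduce(combine_features, blocks)
  out$set_name <- set_name
  out
}

#' Concatenate feature matrices column-wise
#'
#' Used to build the combined-connectivity (CC) predictors as the SC block
#' followed by the FC block, and the composite local / global-and-local
#' families.
#'
#' @param a,b `feature_matrix` objects with equal, row-aligned subject sets.
#' @return a `feature_matrix`; the modality label becomes `"CC"` when the
#'   two blocks disagree.
#' @export
combine_features <- function(a, b) {
  stopifnot(inherits(a, "feature_matrix"), inherits(b, "feature_matrix"),
            nrow(a$X) == nrow(b$X))
  modality <- if (identical(a$modality, b$modality)) a$modality else "CC"
  set_name <- if (identical(a$set_name, b$set_name)) a$set_name
              else paste(a$set_name, b$set_name, sep = "+")
  feature_matrix(cbind(a$X, b$X), rbind(a$labels, b$labels),
                 set_name, modality)
}

#' Standardise feature columns
#'
#' Centres and scales every column to mean 0 and sd 1, keeping the
#' parameters so held-out subjects can be transformed with training-fold
#' statistics only, and so coefficients can be mapped back to raw units.
#'
#' @param X numeric matrix (or `feature_matrix`).
#' @param center,scale optional parameter vectors (training-fold values);
#'   computed from `X` when `NULL`.
#' @param on_constant what to do with a zero-variance column: `"error"`, or
#'   `"zero"` to scale by 1 (the column becomes identically 0 after
#'   centring, which PCA then ignores).
#' @return list with standardised matrix `X` and the `center` and `scale`
#'   vectors used.
#' @export
standardise <- function(X, center = NULL, scale = NULL,
                        on_constant = c("error", "zero")) {
  on_constant <- match.arg(on_constant)
  if (inherits(X, "feature_matrix")) X <- X$X
  X <- as.matrix(X)
  center <- center %||% colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2L, stats::sd)
    zero <- !is.finite(scale) | scale < 1e-12
    if (any(zero)) {
      if (on_constant == "error")
        stop("zero-variance feature column(s): ",
             paste(utils::head(colnames(X)[zero], 5L), collapse = ", "),
             call. = FALSE)
      scale[zero] <- 1
    }
  }
  list(X = sweep(sweep(X, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

## Replace NA/NaN sentinel entries (e.g. eccentricity of isolated nodes,
## assortativity of regular graphs) by reference column means -- training
## fold means inside cross-validation, cohort means otherwise.
impute_columns <- function(X, means = NULL) {
  X <- as.matrix(X)
  bad <- !is.finite(X)
  if (!any(bad)) return(list(X = X, means = means %||% colMeans(X)))
  if (is.null(means)) {
    means <- vapply(seq_len(ncol(X)), function(j) {
      v <- X[, j][is.finite(X[, j])]
      if (length(v)) mean(v) else 0
    }, numeric(1))
  }
  X[bad] <- means[col(X)[bad]]
  list(X = X, means = means)
}
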
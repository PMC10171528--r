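## Connectivity preparation: raw measurement matrices -> analysis-ready
## weighted, undirected, nonnegative connectomes.

#' Construct a connectome matrix object
#'
#' @param W symmetric nonnegative numeric matrix with zero diagonal.
#' @param modality `"SC"` or `"FC"`.
#' @param region_labels character vector of region names.
#' @param thresholded has a proportional threshold been applied yet?
#' @return object of class `connectome`.
#' @export
connectome <- function(W, modality = c("SC", "FC"),
                       region_labels = NULL, thresholded = FALSE) {
  modality <- match.arg(modality)
  W <- as.matrix(W)
  if (!is_symmetric_num(W))
    stop("connectome matrix must be symmetric", call. = FALSE)
  if (any(diag(W) != 0))
    stop("connectome matrix must have a zero diagonal", call. = FALSE)
  if (any(W < 0) || any(W > 1))
    stop("connectome weights must lie in [0, 1]", call. = FALSE)
  W <- (W + t(W)) / 2  # exact symmetry
  region_labels <- region_labels %||% rownames(W) %||%
    region_labels_for(nrow(W))
  dimnames(W) <- list(region_labels, region_labels)
  structure(list(W = W, modality = modality, region_labels = region_labels,
                 thresholded = isTRUE(thresholded)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  nz <- sum(x$W[upper.tri(x$W)] > 0)
  cat(sprintf("<connectome> %s, %d regions, %d edges%s\n", x$modality,
              nrow(x$W), nz, if (x$thresholded) " (thresholded)" else ""))
  invisible(x)
}

#' Structural connectivity weights from streamline counts
#'
#' The weight between regions i and j is the total streamline count in both
#' directions divided by the maximum attainable count,
#' `W[i,j] = (M[i,j] + M[j,i]) / ((N[i] + N[j]) * samples_per_voxel)`.
#' Swapping i and j leaves the value unchanged, so the result is symmetric,
#' and it reaches 1 exactly when every initiated streamline in either region
#' reaches the other. Normalising by seed size removes the bias of larger
#' regions emitting more streamlines.
#'
#' @param counts a `streamline_counts` object (see
#'   [generate_streamline_counts()]).
#' @return an unthresholded `"SC"` [connectome()].
#' @export
sc_weight_matrix <- function(counts) {
  stopifnot(inherits(counts, "streamline_counts"))
  if (any(counts$N <= 0))
    stop("every region must have at least one seed voxel", call. = FALSE)
  M <- counts$M
  cap <- outer(counts$N, counts$N, "+") * counts$samples_per_voxel
  W <- (M + t(M)) / cap
  diag(W) <- 0
  connectome(W, "SC", counts$region_labels, thresholded = FALSE)
}

#' Functional connectivity weights from a Fisher-z matrix
#'
#' Inverts the Fisher transformation with `tanh()` to recover correlations in
#' (-1, 1), then takes absolute values so negative couplings contribute their
#' magnitude.
#'
#' @param z_matrix symmetric finite matrix of Fisher-z values, zero diagonal.
#' @param tol symmetry tolerance.
#' @return an unthresholded `"FC"` [connectome()] with entries in [0, 1).
#' @export
fc_from_fisher_z <- function(z_matrix, tol = 1e-8) {
  z_matrix <- as.matrix(z_matrix)
  if (!all(is.finite(z_matrix)))
    stop("Fisher-z matrix must be finite", call. = FALSE)
  if (max(abs(z_matrix - t(z_matrix))) > tol * max(1, max(abs(z_matrix))))
    stop("Fisher-z matrix is not symmetric within tolerance", call. = FALSE)
  W <- abs(tanh((z_matrix + t(z_matrix)) / 2))
  diag(W) <- 0
  connectome(W, "FC", rownames(z_matrix), thresholded = FALSE)
}

#' Proportional threshold of a weighted connectome
#'
#' Keeps the strongest `retain_fraction` of candidate off-diagonal weights at
#' their original values and zeroes the rest, applied symmetrically over the
#' upper triangle. For sparse structural matrices only nonzero entries count
#' toward the quota (an absent tract is not a weak edge); for functional
#' matrices every off-diagonal pair is a candidate. Ties at the cut are
#' resolved by (weight descending, row ascending, column ascending), so the
#' surviving edge set is deterministic and nested across retain fractions.
#'
#' The conventional reading of "an 80% proportional threshold" used here is
#' to discard the weakest 80% (retain 0.20); pass `retain_fraction = 0.8` for
#' the opposite reading.
#'
#' @param conn a [connectome()].
#' @param retain_fraction fraction of candidate edges to keep, in (0, 1].
#' @return the thresholded [connectome()].
#' @export
proportional_threshold <- function(conn, retain_fraction = 0.2) {
  stopifnot(inherits(conn, "connectome"))
  stopifnot_scalar_in(retain_fraction, 0, 1, "retain_fraction",
                      lo_open = TRUE)
  W <- conn$W
  n <- nrow(W)
  idx <- upper_tri_pairs(n)
  w <- W[idx]
  cand <- if (conn$modality == "SC") which(w > 0) else seq_along(w)
  k <- ceiling(retain_fraction * length(cand))
  keep <- integer(0)
  if (k > 0 && length(cand) > 0) {
    ord <- cand[order(-w[cand], idx[cand, 1L], idx[cand, 2L])]
    keep <- ord[seq_len(min(k, length(ord)))]
  }
  Wt <- matrix(0, n, n)
  Wt[idx[keep, , drop = FALSE]] <- w[keep]
  Wt <- Wt + t(Wt)
  connectome(Wt, conn$modality, conn$region_labels, thresholded = TRUE)
}
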
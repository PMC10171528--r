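## Node-level battery: nine weighted measures per region.

node_metric_names <- c("node_degree", "within_module_degree", "node_strength",
                       "clustering_coefficient", "eigenvector_centrality",
                       "betweenness_centrality", "participation_coefficient",
                       "node_eccentricity", "local_efficiency")

## Onnela weighted clustering: geometric mean of triangle weights after
## normalising by the largest weight in the graph; 0 for degree < 2.
onnela_clustering <- function(W) {
  n <- nrow(W)
  k <- rowSums(W > 0)
  mx <- max(W)
  if (mx <= 0) return(numeric(n))
  Wr <- (W / mx)^(1 / 3)
  cyc <- diag(Wr %*% Wr %*% Wr)
  C <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
  pmin(pmax(C, 0), 1)
}

## Connected components of the binary graph (labels 1.. in discovery order).
graph_components <- function(W) {
  n <- nrow(W)
  A <- W > 0
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start]) next
    cur <- cur + 1L
    frontier <- start
    comp[start] <- cur
    while (length(frontier)) {
      nb <- which(colSums(A[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

## Leading-eigenvector centrality; computed on the largest connected
## component (leading eigenvector is non-unique otherwise), zeros elsewhere,
## unit Euclidean norm, nonnegative by Perron-Frobenius.
eigenvector_centrality <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  comp <- graph_components(W)
  sizes <- tabulate(comp)
  big <- which(comp == which.max(sizes))
  if (length(big) == 1L || sum(W[big, big]) == 0) return(out)
  v <- eigen(W[big, big], symmetric = TRUE)$vectors[, 1L]
  v <- abs(v)
  out[big] <- v / sqrt(sum(v^2))
  out
}

## Node betweenness: number of shortest paths (multiplicities counted
## exactly) with the node strictly interior, summed over unordered pairs.
betweenness_nodes <- function(dist) {
  D <- dist$D; C <- dist$counts; tol <- dist$tol
  n <- nrow(D)
  B <- numeric(n)
  ut <- upper.tri(D)
  for (v in seq_len(n)) {
    through <- outer(D[, v], D[v, ], "+")
    ok <- is.finite(through) & abs(through - D) <= tol * pmax(1, abs(D))
    ok[v, ] <- FALSE; ok[, v] <- FALSE
    sel <- ok & ut
    if (any(sel)) {
      cnt <- outer(C[, v], C[v, ])
      B[v] <- sum(cnt[sel])
    }
  }
  B
}

## Participation coefficient over a module partition, using strengths:
## P_i = 1 - sum_m (kappa_im / s_i)^2.
participation_coefficient <- function(W, labels) {
  s <- rowSums(W)
  mods <- sort(unique(labels))
  K <- vapply(mods, function(m) rowSums(W[, labels == m, drop = FALSE]),
              numeric(nrow(W)))
  P <- 1 - rowSums((K / pmax(s, .Machine$double.eps))^2)
  ifelse(s > 0, pmin(pmax(P, 0), 1), 0)
}

## Within-module degree z-score on binary degree; modules with no degree
## spread give z = 0.
within_module_degree_z <- function(W, labels) {
  n <- nrow(W)
  A <- (W > 0) * 1
  z <- numeric(n)
  for (m in unique(labels)) {
    idx <- which(labels == m)
    kin <- rowSums(A[idx, idx, drop = FALSE])
    sdk <- stats::sd(kin)
    z[idx] <- if (length(idx) > 1 && isTRUE(sdk > 0)) (kin - mean(kin)) / sdk
              else 0
  }
  z
}

## Local efficiency: global efficiency of the subgraph induced by a node's
## (binary) neighbours, with inverse-weight path lengths; 0 for degree < 2.
local_efficiency <- function(W) {
  n <- nrow(W)
  E <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2L) next
    sub <- W[nb, nb, drop = FALSE]
    D <- shortest_path_lengths(sub)$D
    inv <- 1 / D[upper.tri(D)]
    E[i] <- mean(ifelse(is.finite(inv), inv, 0))
  }
  E
}

#' Node-level graph measures of a weighted connectome
#'
#' Computes the nine-node-measure battery: binary degree, within-module
#' degree z-score, strength, Onnela clustering, eigenvector centrality,
#' weighted betweenness (shortest-path counts on inverse-weight lengths),
#' participation coefficient, eccentricity, and local efficiency.
#' Eccentricity of an isolated node is `NA` (imputed downstream); all other
#' sentinels are 0.
#'
#' @param conn a [connectome()].
#' @param dist result of [shortest_path_lengths()] for the same graph.
#' @param partition result of [community_partition()] for the same graph.
#' @return numeric matrix, regions x 9, columns named as above.
#' @export
node_metrics <- function(conn, dist = shortest_path_lengths(conn),
                         partition = community_partition(conn)) {
  W <- conn$W
  n <- nrow(W)
  D <- dist$D
  ecc <- apply(D, 1, function(d) {
    f <- d[is.finite(d) & d > 0]
    if (length(f)) max(f) else NA_real_
  })
  deg <- rowSums(W > 0)
  ecc[deg == 0] <- NA_real_
  out <- cbind(
    node_degree = deg,
    within_module_degree = within_module_degree_z(W, partition$labels),
    node_strength = rowSums(W),
    clustering_coefficient = onnela_clustering(W),
    eigenvector_centrality = eigenvector_centrality(W),
    betweenness_centrality = betweenness_nodes(dist),
    participation_coefficient = participation_coefficient(W, partition$labels),
    node_eccentricity = ecc,
    local_efficiency = local_efficiency(W)
  )
  rownames(out) <- conn$region_labels
  out
}
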
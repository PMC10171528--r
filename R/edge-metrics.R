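## Edge-level battery: three symmetric regions x regions matrices.

edge_metric_names <- c("edge_betweenness_centrality", "matching_index",
                       "path_transitivity")

## Matching index: weighted overlap of the connectivity neighbourhoods of i
## and j, excluding their mutual connection. Numerator sums W[i,k] + W[j,k]
## over k adjacent to both, denominator over k adjacent to either, which
## reduces to s_i + s_j - 2 W[i,j]. Identical neighbourhoods give 1,
## disjoint neighbourhoods 0.
matching_index <- function(W) {
  A <- (W > 0) * 1
  num <- W %*% A + A %*% W
  den <- outer(rowSums(W), rowSums(W), "+") - 2 * W
  M <- ifelse(den > 0, num / den, 0)
  diag(M) <- 0
  M <- pmin(pmax((M + t(M)) / 2, 0), 1)
  M
}

## Edge betweenness: number of shortest paths (multiplicities exact)
## traversing each edge, paths terminating at the edge's endpoints included.
betweenness_edges <- function(W, dist) {
  D <- dist$D; C <- dist$counts; tol <- dist$tol
  n <- nrow(W)
  B <- matrix(0, n, n)
  edges <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1L]; v <- edges[e, 2L]
    l <- 1 / W[u, v]
    # ordered pairs (s, t) whose shortest path crosses u -> v; each
    # undirected path appears under exactly one ordering of (s, t)
    thr <- outer(D[, u], D[v, ], "+") + l
    ok <- is.finite(thr) & abs(thr - D) <= tol * pmax(1, abs(D))
    diag(ok) <- FALSE
    cnt <- outer(C[, u], C[v, ])
    B[u, v] <- B[v, u] <- sum(cnt[ok])
  }
  B
}

## Path transitivity: for each connected pair, the mean matching index over
## all unordered pairs of nodes on the reconstructed shortest path (endpoints
## included); adjacent path of two nodes reduces to their matching index.
## Disconnected pairs score 0.
path_transitivity_matrix <- function(dist, M) {
  n <- nrow(M)
  P <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      path <- reconstruct_path(dist, i, j)
      if (is.null(path)) next
      pairs <- utils::combn(path, 2L)
      P[i, j] <- P[j, i] <- mean(M[cbind(pairs[1L, ], pairs[2L, ])])
    }
  }
  P
}

#' Edge-level graph measures of a weighted connectome
#'
#' @param conn a [connectome()].
#' @param dist result of [shortest_path_lengths()] for the same graph.
#' @return list of three symmetric matrices: `edge_betweenness_centrality`
#'   (zero where no edge), `matching_index` and `path_transitivity`
#'   (both in [0, 1]).
#' @export
edge_metrics <- function(conn, dist = shortest_path_lengths(conn)) {
  W <- conn$W
  M <- matching_index(W)
  list(edge_betweenness_centrality = betweenness_edges(W, dist),
       matching_index = M,
       path_transitivity = path_transitivity_matrix(dist, M))
}
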
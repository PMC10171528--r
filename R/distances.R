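## All-pairs shortest paths on the inverse-weight graph.
##
## Strong weights mean short travel: the length of an edge with weight w > 0
## is 1/w, and path length is the sum of edge lengths along the route. The
## Floyd-Warshall recursion below also tracks the number of distinct shortest
## paths (equal-length multiplicities counted exactly, up to a floating-point
## tie tolerance) and a successor matrix for path reconstruction. Ties keep
## the earlier intermediate, so reconstruction is deterministic.

#' All-pairs shortest path structure of a weighted connectome
#'
#' Runs the Floyd-Warshall algorithm on edge lengths `1/W[i,j]`.
#'
#' @param conn a [connectome()] (or a bare symmetric weight matrix).
#' @param tol relative tolerance for treating two path lengths as tied.
#' @return object of class `distance_matrix`: list with `D` (lengths, `Inf`
#'   between components, zero diagonal), `counts` (number of shortest paths
#'   per pair), and `nxt` (successor matrix: the node after `i` on the
#'   reconstructed shortest path to `j`, `NA` if unreachable).
#' @export
shortest_path_lengths <- function(conn, tol = .tol_tie) {
  W <- if (inherits(conn, "connectome")) conn$W else as.matrix(conn)
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  C <- ifelse(W > 0, 1, 0)
  diag(C) <- 1
  nxt <- matrix(NA_integer_, n, n)
  nxt[W > 0] <- col(W)[W > 0]
  diag(nxt) <- seq_len(n)

  for (k in seq_len(n)) {
    alt <- outer(D[, k], D[k, ], "+")
    finite <- is.finite(alt)
    eq <- finite & is.finite(D) & abs(alt - D) <= tol * pmax(1, abs(D))
    lt <- finite & (alt < D) & !eq
    eq[k, ] <- FALSE; eq[, k] <- FALSE; diag(eq) <- FALSE
    lt[k, ] <- FALSE; lt[, k] <- FALSE; diag(lt) <- FALSE
    if (any(eq)) {
      ck <- outer(C[, k], C[k, ])
      C[eq] <- C[eq] + ck[eq]
    }
    if (any(lt)) {
      ck <- outer(C[, k], C[k, ])
      C[lt] <- ck[lt]
      D[lt] <- alt[lt]
      nk <- matrix(nxt[, k], n, n)
      nxt[lt] <- nk[lt]
    }
  }
  dimnames(D) <- dimnames(W)
  structure(list(D = D, counts = C, nxt = nxt, tol = tol),
            class = "distance_matrix")
}

## Node sequence of the reconstructed shortest path i -> j (inclusive);
## NULL if unreachable.
reconstruct_path <- function(dist, i, j) {
  if (!is.finite(dist$D[i, j])) return(NULL)
  path <- i
  while (i != j) {
    i <- dist$nxt[i, j]
    path <- c(path, i)
  }
  path
}
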
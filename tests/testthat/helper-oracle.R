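# Independent brute-force oracle for the graph-metric battery.
# Distances come from min-plus matrix closure (not Floyd-Warshall);
# betweenness from explicit enumeration of all shortest paths; everything
# else from direct definitional loops. Intended for n <= 8 with continuous
# weights (ties have probability zero).

oracle_tol <- 1e-9

random_connected_graph <- function(n, density = 0.5, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      W <- matrix(0, n, n)
      # random spanning tree guarantees connectedness
      perm <- sample(n)
      for (i in 2:n) {
        j <- perm[sample(i - 1, 1)]
        W[perm[i], j] <- W[j, perm[i]] <- runif(1, 0.2, 1)
      }
      extra <- which(upper.tri(W) & W == 0)
      add <- extra[runif(length(extra)) < density]
      W[add] <- runif(length(add), 0.2, 1)
      W[lower.tri(W)] <- t(W)[lower.tri(W)]
      if (all(rowSums(W > 0) >= 1)) break
    }
    W
  })
}

oracle_distances <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  repeat {
    D2 <- D
    for (i in seq_len(n)) for (j in seq_len(n))
      D2[i, j] <- min(D[i, j], min(D[i, ] + D[, j]))
    if (identical(D2, D)) break
    D <- D2
  }
  D
}

# All simple shortest paths s -> t (list of node vectors), by pruned DFS.
oracle_shortest_paths <- function(W, s, t, D) {
  target <- D[s, t]
  if (!is.finite(target)) return(list())
  L <- ifelse(W > 0, 1 / W, Inf)
  paths <- list()
  dfs <- function(v, len, path) {
    if (v == t) {
      if (abs(len - target) <= oracle_tol * max(1, target))
        paths[[length(paths) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (u in which(W[v, ] > 0)) {
      if (u %in% path) next
      nl <- len + L[v, u]
      if (nl <= target + oracle_tol * max(1, target))
        dfs(u, nl, c(path, u))
    }
  }
  dfs(s, 0, s)
  paths
}

oracle_betweenness <- function(W, D) {
  n <- nrow(W)
  node_b <- numeric(n)
  edge_b <- matrix(0, n, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    for (p in oracle_shortest_paths(W, s, t, D)) {
      if (length(p) > 2) {
        inner <- p[-c(1, length(p))]
        node_b[inner] <- node_b[inner] + 1
      }
      for (e in seq_len(length(p) - 1)) {
        edge_b[p[e], p[e + 1]] <- edge_b[p[e], p[e + 1]] + 1
        edge_b[p[e + 1], p[e]] <- edge_b[p[e + 1], p[e]] + 1
      }
    }
  }
  list(node = node_b, edge = edge_b)
}

oracle_onnela <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  C <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      if (W[i, j] > 0 && W[i, h] > 0 && W[j, h] > 0)
        acc <- acc + (W[i, j] / mx * W[i, h] / mx * W[j, h] / mx)^(1 / 3)
    }
    C[i] <- acc / (k * (k - 1))
  }
  C
}

oracle_transitivity <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    den <- den + k * (k - 1)
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      if (W[i, j] > 0 && W[i, h] > 0 && W[j, h] > 0)
        num <- num + (W[i, j] / mx * W[i, h] / mx * W[j, h] / mx)^(1 / 3)
    }
  }
  if (den == 0) 0 else num / den
}

oracle_matching <- function(W) {
  n <- nrow(W)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      ai <- W[i, k] > 0; aj <- W[j, k] > 0
      if (ai && aj) num <- num + W[i, k] + W[j, k]
      if (ai || aj) den <- den + W[i, k] + W[j, k]
    }
    M[i, j] <- M[j, i] <- if (den > 0) num / den else 0
  }
  M
}

oracle_participation <- function(W, labels) {
  n <- nrow(W)
  s <- rowSums(W)
  P <- numeric(n)
  for (i in seq_len(n)) {
    if (s[i] == 0) next
    acc <- 0
    for (m in unique(labels))
      acc <- acc + (sum(W[i, labels == m]) / s[i])^2
    P[i] <- 1 - acc
  }
  P
}

oracle_within_module_z <- function(W, labels) {
  n <- nrow(W)
  z <- numeric(n)
  for (m in unique(labels)) {
    idx <- which(labels == m)
    kin <- vapply(idx, function(i) sum(W[i, idx] > 0), numeric(1))
    sdk <- stats::sd(kin)
    if (length(idx) > 1 && isTRUE(sdk > 0))
      z[idx] <- (kin - mean(kin)) / sdk
  }
  z
}

oracle_local_efficiency <- function(W) {
  n <- nrow(W)
  E <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    Ds <- oracle_distances(W[nb, nb, drop = FALSE])
    vals <- 1 / Ds[upper.tri(Ds)]
    E[i] <- mean(ifelse(is.finite(vals), vals, 0))
  }
  E
}

oracle_eigencentrality <- function(W) {
  # power iteration on the largest component
  n <- nrow(W)
  comp <- integer(n); cur <- 0
  for (s0 in seq_len(n)) {
    if (comp[s0]) next
    cur <- cur + 1
    q <- s0; comp[s0] <- cur
    while (length(q)) {
      nb <- which(colSums(W[q, , drop = FALSE] > 0) > 0 & comp == 0)
      comp[nb] <- cur; q <- nb
    }
  }
  big <- which(comp == which.max(tabulate(comp)))
  out <- numeric(n)
  if (length(big) == 1 || sum(W[big, big]) == 0) return(out)
  v <- rep(1, length(big))
  # positive diagonal shift keeps eigenvectors but breaks the +/- lambda
  # symmetry of bipartite graphs, so the iteration always converges
  A <- W[big, big] + diag(length(big))
  for (it in 1:10000) {
    v2 <- drop(A %*% v)
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < 1e-13) { v <- v2; break }
    v <- v2
  }
  out[big] <- abs(v)
  out
}

oracle_modularity <- function(W, labels) {
  two_m <- sum(W)
  s <- rowSums(W)
  q <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(nrow(W)))
    if (labels[i] == labels[j])
      q <- q + W[i, j] - s[i] * s[j] / two_m
  q / two_m
}

oracle_assortativity <- function(W) {
  s <- rowSums(W)
  a <- c(); b <- c()
  n <- nrow(W)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && W[i, j] > 0) { a <- c(a, s[i]); b <- c(b, s[j]) }
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) return(NaN)
  cor(a, b)
}

# Unique-shortest-path transitivity (only valid when every connected pair
# has exactly one shortest path, which holds a.s. for continuous weights).
oracle_path_transitivity <- function(W, D, M) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    paths <- oracle_shortest_paths(W, i, j, D)
    if (length(paths) != 1) next
    p <- paths[[1]]
    prs <- combn(p, 2)
    P[i, j] <- P[j, i] <- mean(M[cbind(prs[1, ], prs[2, ])])
  }
  P
}

oracle_core_size <- function(W) {
  n <- nrow(W)
  wbar <- mean(W[upper.tri(W)])
  best_q <- -Inf; best_size <- 0
  for (code in seq_len(2^n - 1)) {
    core <- which(bitwAnd(code, bitwShiftL(1L, 0:(n - 1))) != 0)
    q <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (i %in% core || j %in% core) q <- q + W[i, j] - wbar
    if (q > best_q + 1e-12 ||
        (abs(q - best_q) <= 1e-12 && length(core) > best_size)) {
      best_q <- q; best_size <- length(core)
    }
  }
  best_size
}

as_conn <- function(W, modality = "SC", thresholded = TRUE)
  connectome(W, modality, thresholded = thresholded)
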
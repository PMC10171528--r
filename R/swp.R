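## Small-world propensity: how far the observed clustering sits from a
## weighted lattice null, and the observed path length from a weight- and
## density-matched random null, combined as
##   phi = 1 - sqrt((dC^2 + dL^2) / 2),
##   dC = (C_latt - C_obs) / (C_latt - C_rand),
##   dL = (L_obs - L_rand) / (L_latt - L_rand),
## with each deviation clamped to [0, 1] before combining. A graph whose
## clustering matches its lattice null and whose path length matches its
## random null scores 1; a graph as unclustered as random and as long-pathed
## as a lattice scores 0.

## Lattice null: the observed weights, strongest first, are laid onto the
## ring positions of smallest circular node distance (|i - j| mod n), ties
## within a distance band shuffled by the seed.
lattice_null <- function(W, seed) {
  n <- nrow(W)
  idx <- upper_tri_pairs(n)
  w <- sort(W[idx][W[idx] > 0], decreasing = TRUE)
  ringd <- pmin(idx[, 2L] - idx[, 1L], n - (idx[, 2L] - idx[, 1L]))
  ord <- with_seed(seed, order(ringd + stats::runif(length(ringd), 0, 0.5)))
  Wl <- matrix(0, n, n)
  sel <- idx[ord[seq_along(w)], , drop = FALSE]
  Wl[sel] <- w
  Wl + t(Wl)
}

## Random null: same number of edges and the same weights, at uniformly
## random off-diagonal positions.
random_null <- function(W, seed) {
  n <- nrow(W)
  idx <- upper_tri_pairs(n)
  w <- W[idx][W[idx] > 0]
  with_seed(seed, {
    pos <- sample(nrow(idx), length(w))
    w <- sample(w)
    Wr <- matrix(0, n, n)
    Wr[idx[pos, , drop = FALSE]] <- w
    Wr + t(Wr)
  })
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

## Deviation ratio with a guard for degenerate nulls: when the null spread
## vanishes, the deviation is 0 if the observed value is on the "good" side
## and 1 otherwise.
delta_ratio <- function(num, den) {
  if (abs(den) < 1e-12) return(if (num <= 0) 0 else 1)
  clamp01(num / den)
}

#' Small-world propensity of a weighted connectome
#'
#' @param conn a [connectome()] (connected on its nonzero part for a
#'   meaningful value; disconnected graphs use finite distances only).
#' @param n_nulls number of null instances per null type; clustering and
#'   path length are averaged across instances.
#' @param seed integer seed driving the null construction.
#' @return a value in [0, 1].
#' @export
small_world_propensity <- function(conn, n_nulls = 10L, seed = 1L) {
  stopifnot(inherits(conn, "connectome"), n_nulls >= 1)
  W <- conn$W
  if (sum(W) == 0) stop("edgeless graph has no small-world propensity",
                        call. = FALSE)
  C_obs <- mean(onnela_clustering(W))
  L_obs <- suppressWarnings(
    characteristic_path_length(shortest_path_lengths(W)$D))

  null_stats <- function(builder, stream) {
    cl <- numeric(n_nulls); pl <- numeric(n_nulls)
    for (r in seq_len(n_nulls)) {
      Wn <- builder(W, sub_seed(seed, r, stream))
      cl[r] <- mean(onnela_clustering(Wn))
      pl[r] <- suppressWarnings(
        characteristic_path_length(shortest_path_lengths(Wn)$D))
    }
    c(C = mean(cl), L = mean(pl, na.rm = TRUE))
  }
  latt <- null_stats(lattice_null, 11L)
  rand <- null_stats(random_null, 12L)

  dC <- delta_ratio(latt["C"] - C_obs, latt["C"] - rand["C"])
  dL <- delta_ratio(L_obs - rand["L"], latt["L"] - rand["L"])
  unname(clamp01(1 - sqrt((dC^2 + dL^2) / 2)))
}
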
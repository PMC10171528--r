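## Global battery: eight scalars per connectome.

global_metric_names <- c("average_clustering_coefficient",
                         "characteristic_path_length",
                         "small_world_propensity", "global_efficiency",
                         "assortativity", "modularity_statistic",
                         "transitivity", "core_size")

## Characteristic path length over finite off-diagonal distances only; a
## thresholded connectome can disconnect, in which case infinite pairs are
## excluded with a warning.
characteristic_path_length <- function(D) {
  d <- D[upper.tri(D)]
  if (any(!is.finite(d)))
    warning("graph is disconnected; characteristic path length computed ",
            "over finite distances only", call. = FALSE)
  d <- d[is.finite(d)]
  if (!length(d)) return(NA_real_)
  mean(d)
}

global_efficiency <- function(D) {
  inv <- 1 / D[upper.tri(D)]
  mean(ifelse(is.finite(inv), inv, 0))
}

## Weighted degree assortativity: Pearson correlation of endpoint strengths
## across edges (both orientations). Undefined (NaN) when endpoint strengths
## have no variance, e.g. on regular graphs.
assortativity_weighted <- function(W) {
  s <- rowSums(W)
  idx <- which(W > 0, arr.ind = TRUE)   # both orientations -> symmetric
  if (nrow(idx) < 2) return(NaN)
  a <- s[idx[, 1L]]; b <- s[idx[, 2L]]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NaN)
  stats::cor(a, b)
}

## Weighted transitivity, ratio form: total normalised triangle intensity
## over total possible triads.
transitivity_weighted <- function(W) {
  k <- rowSums(W > 0)
  den <- sum(k * (k - 1))
  if (den == 0 || max(W) == 0) return(0)
  Wr <- (W / max(W))^(1 / 3)
  sum(diag(Wr %*% Wr %*% Wr)) / den
}

#' Global graph measures of a weighted connectome
#'
#' Computes the eight-global-measure battery: average Onnela clustering,
#' characteristic path length (finite distances only on disconnected
#' graphs), small-world propensity (passed through or computed), global
#' efficiency, weighted degree assortativity (`NaN` sentinel when degrees
#' have zero variance), the modularity statistic of the supplied partition,
#' weighted transitivity, and the size of the core from the core-periphery
#' partition.
#'
#' @param conn a [connectome()].
#' @param dist result of [shortest_path_lengths()].
#' @param partition result of [community_partition()].
#' @param swp small-world propensity value to report; computed via
#'   [small_world_propensity()] when `NULL`.
#' @param core_size core size to report; computed via
#'   [core_periphery_size()] when `NULL`.
#' @param seed seed for the heuristic measures when they are computed here.
#' @param swp_nulls null instances per null type for the propensity.
#' @return named numeric vector of length 8.
#' @export
global_metrics <- function(conn, dist = shortest_path_lengths(conn),
                           partition = community_partition(conn),
                           swp = NULL, core_size = NULL, seed = 1L,
                           swp_nulls = 10L) {
  W <- conn$W
  if (is.null(swp))
    swp <- small_world_propensity(conn, n_nulls = swp_nulls, seed = seed)
  if (is.null(core_size)) core_size <- core_periphery_size(conn, seed = seed)
  c(average_clustering_coefficient = mean(onnela_clustering(W)),
    characteristic_path_length = characteristic_path_length(dist$D),
    small_world_propensity = swp,
    global_efficiency = global_efficiency(dist$D),
    assortativity = assortativity_weighted(W),
    modularity_statistic = partition$Q,
    transitivity = transitivity_weighted(W),
    core_size = as.numeric(core_size))
}
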
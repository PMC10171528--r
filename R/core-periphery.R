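## Two-block core-periphery partition. The quality of a core assignment is
## the total centred weight covered by the ideal core pattern (core-core and
## core-periphery pairs):
##   q(core) = sum_{i<j, i or j in core} (W[i,j] - mean off-diagonal weight).
## Subtracting the mean penalises sweeping weak pairs into the pattern, so a
## hub-and-spoke graph yields a single-node core while a uniformly complete
## graph yields a full core (all assignments tie at q = 0 and ties resolve
## toward the larger core).

core_quality <- function(Wc, core) {
  n <- nrow(Wc)
  peri <- setdiff(seq_len(n), core)
  tot <- sum(Wc[upper.tri(Wc)])
  pp <- if (length(peri) > 1)
    sum(Wc[peri, peri][upper.tri(matrix(0, length(peri), length(peri)))])
  else 0
  tot - pp
}

#' Size of the core of a core-periphery partition
#'
#' Maximises the centred core-coverage quality above, exhaustively for small
#' graphs and by a strength-ordered sweep plus single-node hill climbing for
#' larger ones. Ties prefer the larger core; the search is deterministic
#' given the seed.
#'
#' @param conn a [connectome()] with at least one edge.
#' @param seed integer seed (reserved for stochastic restarts; the default
#'   search is deterministic).
#' @param exhaustive_max largest n for which all 2^n - 1 assignments are
#'   enumerated.
#' @return integer core size in 1..n.
#' @export
core_periphery_size <- function(conn, seed = 1L, exhaustive_max = 12L) {
  W <- if (inherits(conn, "connectome")) conn$W else as.matrix(conn)
  n <- nrow(W)
  if (sum(W) == 0) stop("cannot partition an edgeless graph", call. = FALSE)
  wbar <- mean(W[upper.tri(W)])
  Wc <- W - wbar
  diag(Wc) <- 0
  tol <- 1e-12 * max(1, max(abs(Wc)))

  better <- function(q, sz, bq, bsz) q > bq + tol ||
    (abs(q - bq) <= tol && sz > bsz)

  if (n <= exhaustive_max) {
    best_q <- -Inf; best_size <- 0L
    for (code in seq_len(2^n - 1)) {
      core <- which(bitwAnd(code, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
      q <- core_quality(Wc, core)
      if (better(q, length(core), best_q, best_size)) {
        best_q <- q; best_size <- length(core)
      }
    }
    return(best_size)
  }

  ## strength-ordered sweep over split points, then single-toggle hill climb
  ord <- order(-rowSums(W), seq_len(n))
  best_q <- -Inf; best_core <- integer(0)
  for (k in seq_len(n)) {
    core <- ord[seq_len(k)]
    q <- core_quality(Wc, core)
    if (better(q, k, best_q, length(best_core))) {
      best_q <- q; best_core <- core
    }
  }
  in_core <- logical(n); in_core[best_core] <- TRUE
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      cand <- in_core; cand[i] <- !cand[i]
      if (!any(cand)) next
      q <- core_quality(Wc, which(cand))
      if (better(q, sum(cand), best_q, sum(in_core))) {
        best_q <- q; in_core <- cand; improved <- TRUE
      }
    }
    if (!improved) break
  }
  sum(in_core)
}
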
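#' @keywords internal
"_PACKAGE"

## Tolerances used throughout: symmetry / identity checks are done at 1e-12
## relative scale; shortest-path tie detection at 1e-10 (sums of inverse
## weights accumulate rounding in a different order on each route).
.tol_sym <- 1e-12
.tol_tie <- 1e-10

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions never clobber the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a distinct 31-bit sub-seed from a base seed and a stream index.
sub_seed <- function(seed, index, stream = 0L) {
  (as.numeric(seed) * 7919 + as.numeric(index) * 104729 +
     as.numeric(stream) * 1299709) %% 2147483629 + 1
}

is_symmetric_num <- function(M, tol = .tol_sym) {
  is.matrix(M) && nrow(M) == ncol(M) &&
    max(abs(M - t(M))) <= tol * max(1, max(abs(M)))
}

stopifnot_scalar_in <- function(x, lo, hi, name, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) stop(sprintf("`%s` must be a single number in %s%g, %g%s",
                        name, if (lo_open) "(" else "[", lo, hi,
                        if (hi_open) ")" else "]"), call. = FALSE)
  invisible(x)
}

upper_tri_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
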
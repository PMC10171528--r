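## Principal component regression with embedded stepwise selection
## (SWR-PCR). Predictors are first orthogonalised by PCA; the component
## scores enter a bidirectional stepwise search driven by BIC with a strict
## zero improvement threshold; the selected coefficients are finally
## projected back to the original feature space.

#' Bayesian information criterion for a Gaussian linear model
#'
#' Profile-likelihood form `n * log(RSS / n) + k * log(n)`, with `k`
#' counting the intercept and slope terms (the error variance is profiled
#' out identically across compared models, so it is omitted from `k`). Only
#' differences between models fitted to the same outcome are meaningful.
#'
#' @param rss residual sum of squares, nonnegative.
#' @param n_obs number of observations.
#' @param n_params number of mean parameters (intercept included).
#' @return the BIC value; an RSS of (numerically) zero returns a large
#'   negative sentinel with a warning.
#' @export
bic <- function(rss, n_obs, n_params) {
  stopifnot(rss >= 0, n_obs > n_params)
  if (rss < .Machine$double.eps * n_obs) {
    warning("residual sum of squares is numerically zero; returning -Inf ",
            "sentinel", call. = FALSE)
    return(-.Machine$double.xmax / 2)
  }
  n_obs * log(rss / n_obs) + n_params * log(n_obs)
}

#' Orthogonalise a predictor matrix by PCA
#'
#' @param X standardised subjects x features matrix (or `feature_matrix`).
#' @param rank_tol relative singular-value tolerance below which components
#'   are treated as null-space and dropped.
#' @return list with `scores` (orthogonal columns, centred), `loadings`
#'   (orthonormal columns), and `center` (column means removed before
#'   rotation); `X_centred = scores %*% t(loadings)` up to rank truncation.
#' @export
pca_orthogonalise <- function(X, rank_tol = 1e-8) {
  if (inherits(X, "feature_matrix")) X <- X$X
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("PCA needs at least 3 subjects", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  keep <- which(pc$sdev > rank_tol * pc$sdev[1L])
  if (!length(keep)) stop("predictor matrix has rank 0", call. = FALSE)
  keep <- keep[keep <= max(1L, min(nrow(X) - 1L, ncol(X)))]
  list(scores = pc$x[, keep, drop = FALSE],
       loadings = pc$rotation[, keep, drop = FALSE],
       center = pc$center)
}

#' Stepwise regression over principal component scores
#'
#' Greedy bidirectional search starting from the intercept-only model. At
#' each step every single-component addition and removal is evaluated; the
#' move with the largest strict BIC decrease is applied; the search stops
#' when no move strictly decreases BIC (the zero-threshold rule). Ties are
#' broken toward the smaller model, then the lower component index. Because
#' PCA scores are orthogonal and centred, each component's contribution to
#' the residual sum of squares is separable, which the implementation
#' exploits; non-orthogonal score matrices fall back to explicit least
#' squares.
#'
#' @param scores centred matrix of component scores.
#' @param y outcome vector, row-aligned with `scores`.
#' @param direction `"both"` (default) or `"forward"` (no removals).
#' @return list with `selected` (component indices in selection order),
#'   `beta_pc`, `intercept`, `bic`, `rss` and the BIC `trajectory`.
#' @export
stepwise_bic <- function(scores, y, direction = c("both", "forward")) {
  direction <- match.arg(direction)
  scores <- as.matrix(scores)
  n <- length(y)
  stopifnot(nrow(scores) == n)
  p <- ncol(scores)

  ybar <- mean(y)
  yc <- y - ybar
  tss <- sum(yc^2)

  G <- crossprod(scores)
  ortho <- max(abs(G - diag(diag(G), nrow = p))) <=
    1e-8 * max(1, max(abs(diag(G)))) &&
    max(abs(colMeans(scores))) <= 1e-8
  ss <- diag(G)
  usable <- ss > 1e-12 * max(1, max(ss))
  by <- drop(crossprod(scores, yc))
  gain <- ifelse(usable, by^2 / pmax(ss, .Machine$double.eps), 0)

  rss_of <- function(sel) {
    if (!length(sel)) return(tss)
    if (ortho) return(max(tss - sum(gain[sel]), 0))
    fit <- stats::lm.fit(cbind(1, scores[, sel, drop = FALSE]), y)
    sum(fit$residuals^2)
  }

  selected <- integer(0)
  cur_rss <- tss
  cur_bic <- bic(cur_rss, n, 1L)
  trajectory <- cur_bic

  repeat {
    moves <- list()
    if (direction == "both") for (c0 in selected)
      moves[[length(moves) + 1L]] <- list(drop = c0, k = length(selected))
    for (c0 in setdiff(which(usable), selected))
      moves[[length(moves) + 1L]] <- list(add = c0, k = length(selected) + 2L)
    if (!length(moves)) break

    best <- NULL
    for (mv in moves) {
      sel <- if (!is.null(mv$add)) c(selected, mv$add)
             else setdiff(selected, mv$drop)
      if (length(sel) + 2L > n) next  # keep n_obs > n_params
      b <- suppressWarnings(bic(rss_of(sel), n, length(sel) + 1L))
      cand <- list(sel = sel, bic = b, size = length(sel),
                   idx = mv$add %||% mv$drop)
      if (is.null(best) ||
          b < best$bic - 1e-12 ||
          (abs(b - best$bic) <= 1e-12 &&
           (cand$size < best$size ||
            (cand$size == best$size && cand$idx < best$idx))))
        best <- cand
    }
    if (is.null(best) || best$bic >= cur_bic) break  # strict decrease only
    selected <- best$sel
    cur_bic <- best$bic
    cur_rss <- rss_of(selected)
    trajectory <- c(trajectory, cur_bic)
  }

  beta_pc <- if (!length(selected)) numeric(0)
  else if (ortho) by[selected] / ss[selected]
  else stats::lm.fit(cbind(1, scores[, selected, drop = FALSE]),
                     y)$coefficients[-1L]
  intercept <- if (!length(selected) || ortho) ybar
  else stats::lm.fit(cbind(1, scores[, selected, drop = FALSE]),
                     y)$coefficients[1L]

  list(selected = selected, beta_pc = unname(beta_pc),
       intercept = unname(intercept), bic = cur_bic, rss = cur_rss,
       trajectory = trajectory)
}

#' Fit the full SWR-PCR model
#'
#' Standardises features (optional), orthogonalises by PCA, runs the
#' stepwise BIC search over component scores, and back-projects the
#' selected-component coefficients to per-feature weights.
#'
#' @param X subjects x features matrix or `feature_matrix`.
#' @param y outcome vector.
#' @param standardise_features centre/scale columns first (default TRUE).
#' @param direction stepwise direction, see [stepwise_bic()].
#' @return object of class `pcr_model` with elements `column_means`,
#'   `column_scales`, `loadings`, `pca_center`, `candidate_components`,
#'   `selected`, `beta_pc`, `intercept`, `beta_original`, `bic`, `rss`,
#'   `n_obs`.
#' @export
fit_swr_pcr <- function(X, y, standardise_features = TRUE,
                        direction = "both") {
  labels <- if (inherits(X, "feature_matrix")) X$labels else NULL
  if (inherits(X, "feature_matrix")) X <- X$X
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (standardise_features) {
    st <- standardise(X, on_constant = "zero")
  } else {
    st <- list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  }
  pca <- pca_orthogonalise(st$X)
  sw <- stepwise_bic(pca$scores, y, direction = direction)
  model <- structure(list(
    column_means = st$center, column_scales = st$scale,
    loadings = pca$loadings, pca_center = pca$center,
    candidate_components = ncol(pca$scores),
    selected = sw$selected, beta_pc = sw$beta_pc,
    intercept = sw$intercept, bic = sw$bic, rss = sw$rss,
    trajectory = sw$trajectory, n_obs = nrow(X),
    feature_labels = labels
  ), class = "pcr_model")
  model$beta_original <- backproject(model)
  model
}

#' Back-project component coefficients to feature space
#'
#' The fitted coefficients over selected principal components are mapped to
#' per-feature coefficients via the loading matrix; predictions from either
#' parameterisation are identical.
#'
#' @param model a `pcr_model`.
#' @return numeric vector of per-(standardised-)feature coefficients.
#' @export
backproject <- function(model) {
  p <- nrow(model$loadings)
  if (!length(model$selected)) return(numeric(p))
  drop(model$loadings[, model$selected, drop = FALSE] %*% model$beta_pc)
}

#' Predict from a fitted SWR-PCR model
#'
#' @param object a `pcr_model`.
#' @param newdata subjects x features matrix on the original feature scale.
#' @param space `"original"` (default) uses the back-projected coefficients;
#'   `"pc"` routes through component scores. Both give identical values.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pcr_model <- function(object, newdata, space = c("original", "pc"),
                              ...) {
  space <- match.arg(space)
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$X
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2L, object$column_means), 2L, object$column_scales,
              "/")
  Xc <- sweep(Xs, 2L, object$pca_center)
  if (space == "original") {
    drop(object$intercept + Xc %*% object$beta_original)
  } else {
    if (!length(object$selected))
      return(rep(object$intercept, nrow(X)))
    sc <- Xc %*% object$loadings[, object$selected, drop = FALSE]
    drop(object$intercept + sc %*% object$beta_pc)
  }
}

#' @export
print.pcr_model <- function(x, ...) {
  cat(sprintf(
    "<pcr_model> %d/%d components selected, BIC %.2f (n = %d)\n",
    length(x$selected), x$candidate_components, x$bic, x$n_obs))
  invisible(x)
}
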
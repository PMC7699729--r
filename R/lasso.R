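# Sparse association between connectivity features and the cognitive score.

# Standardize columns to mean 0 and unit variance with the 1/M denominator
# (so lambda_max = max_j |x_j' z| / M and the objective is
# (1/(2M)) RSS + lambda ||b||_1, comparable across fold sizes).  Constant
# columns get scale 0 and are pinned at coefficient 0.
standardizeX <- function(x) {
  ctr <- colMeans(x)
  xs <- sweep(x, 2L, ctr, "-")
  scl <- sqrt(colMeans(xs^2))
  ok <- scl > 0
  xs[, ok] <- sweep(xs[, ok, drop = FALSE], 2L, scl[ok], "/")
  xs[, !ok] <- 0
  list(x = xs, center = ctr, scale = scl, active = ok)
}

lambdaMax <- function(xs, zc) max(abs(crossprod(xs, zc))) / length(zc)

#' Log-spaced Lasso penalty grid
#'
#' 100 (by default) log-spaced values from lambda_max (the smallest penalty
#' with an all-zero solution) down to \code{ratio * lambda_max}.
#'
#' @param x feature matrix (or \linkS4class{FeatureMatrix}).
#' @param z response vector.
#' @param nLambda grid length.
#' @param ratio smallest-to-largest penalty ratio.
#' @return Descending numeric vector of penalties.
#' @export
lambdaGrid <- function(x, z, nLambda = 100L, ratio = 1e-3) {
  if (is(x, "FeatureMatrix")) x <- x@values
  std <- standardizeX(x)
  lm <- lambdaMax(std$x, z - mean(z))
  if (lm == 0) lm <- 1e-12
  exp(seq(log(lm), log(lm * ratio), length.out = nLambda))
}

#' Fit the Lasso at one or more penalties
#'
#' Minimizes \deqn{\frac{1}{2M} \|z - \beta_0 - X\beta\|_2^2 +
#' \lambda \|\beta\|_1} over columns standardized with the training data, by
#' cyclic coordinate descent with soft-thresholding updates, warm starts
#' along a descending penalty path, and a KKT stopping rule at tolerance
#' \code{tol}.  Coefficients are exact zeros and are returned on the
#' standardized scale; \code{coef(fit, scale = "original")} back-transforms.
#'
#' @param x a \linkS4class{FeatureMatrix} or numeric matrix (rows =
#'   subjects).
#' @param z response vector (the training-fold generalized score).
#' @param lambda a single penalty, or a descending vector of penalties of
#'   which the last is kept as the fit's operating point.
#' @param tol convergence tolerance on the largest per-sweep coefficient
#'   update; KKT violations at the solution are of the same order and are
#'   reported in attribute \code{"kkt"}.
#' @param maxIter maximum coordinate-descent sweeps per penalty.
#' @return A \linkS4class{LassoFit}; the full path is in attribute
#'   \code{"betaPath"} (P x L matrix, standardized scale) and the largest
#'   KKT violation per penalty in attribute \code{"kkt"}.
#' @export
fitLasso <- function(x, z, lambda, tol = 1e-7, maxIter = 2000L) {
  labels <- if (is(x, "FeatureMatrix")) x@featureLabels else
    colnames(x) %||% sprintf("f%04d", seq_len(ncol(x)))
  if (is(x, "FeatureMatrix")) x <- x@values
  x <- as.matrix(x)
  if (anyNA(x) || anyNA(z) || any(!is.finite(x)) || any(!is.finite(z)))
    stop("non-finite values in the Lasso inputs")
  if (any(lambda < 0)) stop("lambda must be non-negative")
  if (nrow(x) != length(z)) stop("rows of x must match length of z")
  if (is.unsorted(rev(lambda), strictly = FALSE) && length(lambda) > 1L)
    stop("lambda path must be descending")
  std <- standardizeX(x)
  zc <- z - mean(z)
  out <- .lassoPathCpp(std$x, zc, as.numeric(lambda), std$active, tol,
                       as.integer(maxIter))
  beta <- out$beta
  last <- length(lambda)
  fit <- new("LassoFit", beta = beta[, last], intercept = mean(z),
             lambda = lambda[last], lambdaPath = data.frame(),
             center = std$center, scale = std$scale,
             responseCenter = mean(z), featureLabels = labels)
  attr(fit, "betaPath") <- beta
  attr(fit, "kkt") <- out$kkt
  fit
}

#' Tune the Lasso penalty on an inner validation split
#'
#' Splits the round's training data into sub-training and validation parts
#' (stratified by diagnosis when given), fits the descending penalty path on
#' the sub-training part with warm starts, picks the penalty maximizing the
#' validation Pearson correlation between predicted and actual scores (ties
#' broken toward the sparser, larger penalty), and refits on the full
#' training data at the selected penalty.
#'
#' @param x training \linkS4class{FeatureMatrix} or matrix.
#' @param z training response.
#' @param grid descending penalty grid; defaults to
#'   \code{\link{lambdaGrid}} computed on the sub-training part.
#' @param valFraction fraction of subjects held out for validation.
#' @param seed RNG seed for the split.
#' @param diagnosis optional labels for stratifying the split.
#' @param nLambda,ratio grid parameters when \code{grid} is NULL.
#' @return A \linkS4class{LassoFit} whose \code{lambdaPath} records the grid
#'   and validation correlations.
#' @export
tuneLambda <- function(x, z, grid = NULL, valFraction = 0.25, seed = 1L,
                       diagnosis = NULL, nLambda = 100L, ratio = 1e-3) {
  if (!is.null(grid) && !length(grid)) stop("empty lambda grid")
  if (valFraction <= 0 || valFraction >= 1)
    stop("valFraction must lie in (0, 1)")
  xm <- if (is(x, "FeatureMatrix")) x@values else as.matrix(x)
  m <- nrow(xm)
  val <- withSeed(seed, {
    if (is.null(diagnosis)) {
      sample.int(m, max(1L, round(valFraction * m)))
    } else {
      unlist(lapply(split(seq_len(m), diagnosis), function(idx)
        idx[sample.int(length(idx),
                       max(1L, round(valFraction * length(idx))))]),
        use.names = FALSE)
    }
  })
  if (length(val) < 3L) stop("validation part smaller than 3 subjects")
  if (m - length(val) < 2L) stop("sub-training part too small")

  if (is.null(grid))
    grid <- lambdaGrid(xm[-val, , drop = FALSE], z[-val], nLambda, ratio)
  subfit <- fitLasso(x = xm[-val, , drop = FALSE], z = z[-val], lambda = grid)
  betaPath <- attr(subfit, "betaPath")
  # validation predictions for every penalty at once
  xv <- sweep(xm[val, , drop = FALSE], 2L, subfit@center, "-")
  ok <- subfit@scale > 0
  xv[, ok] <- sweep(xv[, ok, drop = FALSE], 2L, subfit@scale[ok], "/")
  xv[, !ok] <- 0
  preds <- xv %*% betaPath + subfit@responseCenter
  rs <- apply(preds, 2L, function(p) evaluateR(z[val], p, warn = FALSE))
  sel <- which.max(rs)          # which.max takes the first (largest) penalty
  refit <- fitLasso(x, z, lambda = grid[seq_len(sel)])
  refit@lambdaPath <- data.frame(lambda = grid, rValidation = rs)
  attr(refit, "betaPath") <- NULL
  refit
}

#' Held-out correlation between actual and predicted scores
#'
#' The Pearson correlation coefficient between the actual generalized scores
#' and the model predictions.  A zero-variance prediction (an all-zero
#' model) returns 0 with a warning, since the correlation is undefined
#' there.
#'
#' @param zTrue actual scores.
#' @param zPred predicted scores.
#' @param warn emit the zero-variance warning.
#' @return Correlation in [-1, 1].
#' @export
evaluateR <- function(zTrue, zPred, warn = TRUE) {
  if (length(zTrue) != length(zPred)) stop("score vectors differ in length")
  if (length(zTrue) < 3L) stop("need at least 3 observations")
  if (sd(zTrue) == 0) stop("actual scores have zero variance")
  if (sd(zPred) == 0) {
    if (warn) warning("zero-variance prediction; returning r = 0")
    return(0)
  }
  cor(zTrue, zPred)
}
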
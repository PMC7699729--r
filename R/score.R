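#' Fit the generalized cognitive score model
#'
#' Standardizes each clinical index with training-fold mean and SD, takes the
#' leading eigenvector of the training correlation matrix as the loading
#' vector c1, and orients it so the loading on \code{signAnchor} is positive
#' (so the score increases with impairment when the anchor is a
#' higher-is-worse instrument).  Explained variance is the leading eigenvalue
#' over the number of indices; per-index contributions are \eqn{100 c_{1s}^2}.
#'
#' With \code{standardize = FALSE} the PCA is run on the raw covariance
#' matrix instead (centering only), and explained variance is the leading
#' eigenvalue over the total variance.
#'
#' @param yTrain a \linkS4class{ClinicalTable} (the training fold).
#' @param signAnchor name of the index whose loading is forced positive.
#' @param standardize correlation-matrix (TRUE, default) or covariance-matrix
#'   PCA.
#' @return A \linkS4class{ScoreModel}.
#' @export
fitScore <- function(yTrain, signAnchor = "ADAS-Cog-13", standardize = TRUE) {
  validObject(yTrain)
  y <- yTrain@values
  s <- ncol(y)
  if (nrow(y) < s + 1L)
    stop("training fold must have at least S + 1 = ", s + 1L, " subjects")
  if (!signAnchor %in% yTrain@indexNames)
    stop("sign anchor '", signAnchor, "' is not a clinical index")
  ctr <- colMeans(y)
  sdv <- apply(y, 2L, sd)
  if (any(sdv == 0))
    stop("zero-variance clinical index: ",
         paste(yTrain@indexNames[sdv == 0], collapse = ", "))
  scl <- if (standardize) sdv else rep(1, s)
  ys <- sweep(sweep(y, 2L, ctr, "-"), 2L, scl, "/")
  cv <- crossprod(ys) / (nrow(y) - 1L)
  ei <- eigen(cv, symmetric = TRUE)
  c1 <- ei$vectors[, 1L]
  if (c1[match(signAnchor, yTrain@indexNames)] < 0) c1 <- -c1
  ev <- ei$values[1L] / sum(ei$values)
  new("ScoreModel", center = ctr, scale = scl, loadings = c1,
      explainedVariance = ev, contributions = 100 * c1^2,
      signAnchor = signAnchor, indexNames = yTrain@indexNames,
      trainScores = drop(ys %*% c1), standardized = standardize)
}

#' Project subjects onto the generalized score axis
#'
#' Applies the training-fold standardization and loading vector to new
#' clinical data; passing the training fold back in reproduces the fit-time
#' training scores exactly.
#'
#' @param model a \linkS4class{ScoreModel}.
#' @param y a \linkS4class{ClinicalTable} with the same indices.
#' @return Numeric score vector Z, named by subject.
#' @export
transformScore <- function(model, y) {
  if (!identical(y@indexNames, model@indexNames))
    stop("clinical index names do not match the score model")
  ys <- sweep(sweep(y@values, 2L, model@center, "-"), 2L, model@scale, "/")
  setNames(drop(ys %*% model@loadings), y@subjectIDs)
}
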
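#' Accessors for connectoscore classes
#'
#' Small, read-only accessors for the S4 containers; use these instead of
#' reaching into slots.
#'
#' @param object an object of the matching class.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("connWeights", "ConnectivityMatrix", function(object) object@weights)
#' @rdname accessors
#' @export
setMethod("roiLabels", "ConnectivityMatrix", function(object) object@roiLabels)
#' @rdname accessors
#' @export
setMethod("roiLabels", "CohortDataset",
          function(object) object@connectomes[[1L]]@roiLabels)

#' @rdname accessors
#' @export
setMethod("subjectIDs", "ConnectivityMatrix", function(object) object@subjectID)
#' @rdname accessors
#' @export
setMethod("subjectIDs", "ClinicalTable", function(object) object@subjectIDs)
#' @rdname accessors
#' @export
setMethod("subjectIDs", "CohortDataset",
          function(object) object@clinical@subjectIDs)
#' @rdname accessors
#' @export
setMethod("subjectIDs", "FeatureMatrix", function(object) object@subjectIDs)

#' @rdname accessors
#' @export
setMethod("nSubjects", "ClinicalTable", function(object) nrow(object@values))
#' @rdname accessors
#' @export
setMethod("nSubjects", "CohortDataset",
          function(object) length(object@connectomes))
#' @rdname accessors
#' @export
setMethod("nSubjects", "FeatureMatrix", function(object) nrow(object@values))

#' @rdname accessors
#' @export
setMethod("featureLabels", "FeatureMatrix",
          function(object) object@featureLabels)
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("clinicalValues", "ClinicalTable", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("indexNames", "ClinicalTable", function(object) object@indexNames)
#' @rdname accessors
#' @export
setMethod("diagnosis", "ClinicalTable", function(object) object@diagnosis)
#' @rdname accessors
#' @export
setMethod("diagnosis", "CohortDataset",
          function(object) object@clinical@diagnosis)
#' @rdname accessors
#' @export
setMethod("clinicalData", "CohortDataset", function(object) object@clinical)
#' @rdname accessors
#' @export
setMethod("connectomes", "CohortDataset", function(object) object@connectomes)

#' @rdname accessors
#' @export
setMethod("scoreLoadings", "ScoreModel", function(object)
  setNames(object@loadings, object@indexNames))
#' @rdname accessors
#' @export
setMethod("explainedVariance", "ScoreModel",
          function(object) object@explainedVariance)
#' @rdname accessors
#' @export
setMethod("indexContributions", "ScoreModel", function(object)
  setNames(object@contributions, object@indexNames))

#' @rdname accessors
#' @export
setMethod("clusterNMI", "ClusterValidation", function(object) object@nmi)
#' @rdname accessors
#' @export
setMethod("permutationP", "ClusterValidation", function(object) object@pValue)

#' @rdname accessors
#' @export
setMethod("stabilityTable", "StabilityReport", function(object) object@table)
#' @rdname accessors
#' @export
setMethod("stableFeatures", "StabilityReport",
          function(object) object@stableFeatures)

#' @rdname accessors
#' @export
setMethod("trueSeverity", "SyntheticCohort", function(object)
  object@trueSeverity)
#' @rdname accessors
#' @export
setMethod("plantedFeatures", "SyntheticCohort", function(object)
  object@plantedFeatures)

#' @rdname accessors
#' @export
setMethod("resultTable", "ExperimentResult", function(object) object@rTable)
#' @rdname accessors
#' @export
setMethod("stabilityTable", "ExperimentResult",
          function(object) object@stability)

#' Extract Lasso coefficients
#'
#' @param object a \linkS4class{LassoFit}.
#' @param scale "standardized" (as fitted) or "original" (back-transformed to
#'   the raw feature scale, with matching intercept as attribute
#'   \code{"intercept"}).
#' @param ... ignored.
#' @return Named coefficient vector.
#' @export
setMethod("coef", "LassoFit", function(object, scale = c("standardized",
                                                         "original"), ...) {
  scale <- match.arg(scale)
  b <- setNames(object@beta, object@featureLabels)
  if (scale == "standardized") {
    attr(b, "intercept") <- object@responseCenter
    return(b)
  }
  ok <- object@scale > 0
  raw <- b
  raw[ok] <- b[ok] / object@scale[ok]
  int <- object@responseCenter - sum(raw[ok] * object@center[ok])
  attr(raw, "intercept") <- int
  raw
})

#' Predict from a Lasso fit
#'
#' @param object a \linkS4class{LassoFit}.
#' @param newdata a \linkS4class{FeatureMatrix} or numeric matrix with the
#'   same columns the model was fitted on.
#' @param ... ignored.
#' @return Numeric vector of predictions.
#' @export
setMethod("predict", "LassoFit", function(object, newdata, ...) {
  x <- if (is(newdata, "FeatureMatrix")) newdata@values else as.matrix(newdata)
  if (ncol(x) != length(object@beta))
    stop("newdata has ", ncol(x), " columns; model expects ",
         length(object@beta))
  xs <- sweep(x, 2L, object@center, "-")
  ok <- object@scale > 0
  xs[, ok] <- sweep(xs[, ok, drop = FALSE], 2L, object@scale[ok], "/")
  xs[, !ok] <- 0
  drop(xs %*% object@beta) + object@responseCenter
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix '", object@subjectID, "': ",
      nrow(object@weights), " regions, ",
      sum(object@weights[upper.tri(object@weights)] > 0), " edges\n", sep = "")
})

setMethod("show", "CohortDataset", function(object) {
  tab <- table(factor(object@clinical@diagnosis, c("NC", "MCI", "AD")))
  cat("CohortDataset: ", length(object@connectomes), " subjects (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "), ",
      length(roiLabels(object)), " regions, ",
      length(object@clinical@indexNames), " clinical indices\n", sep = "")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix ", object@variant, ": ", nrow(object@values), " x ",
      ncol(object@values), "\n", sep = "")
})

setMethod("show", "ScoreModel", function(object) {
  cat("ScoreModel (", if (object@standardized) "correlation" else "covariance",
      "-matrix PCA): ", length(object@loadings), " indices, explained variance ",
      sprintf("%.3f", object@explainedVariance), ", anchor '",
      object@signAnchor, "'\n", sep = "")
})

setMethod("show", "ClusterValidation", function(object) {
  cat("ClusterValidation: ", object@nComponents, " components, NMI ",
      sprintf("%.3f", object@nmi), ", p = ", object@pValue, " (",
      length(object@nullNmi), " permutations)\n", sep = "")
})

setMethod("show", "LassoFit", function(object) {
  cat("LassoFit: lambda = ", signif(object@lambda, 4), ", ",
      sum(object@beta != 0), "/", length(object@beta),
      " nonzero coefficients\n", sep = "")
})

setMethod("show", "StabilityReport", function(object) {
  cat("StabilityReport: ", nrow(object@table), " features, ",
      length(object@stableFeatures), " stable",
      if (object@nullModel) " [null model]", "\n", sep = "")
})

setMethod("show", "SyntheticCohort", function(object) {
  show(object@dataset)
  cat("  planted features: ", nrow(object@plantedFeatures), "\n", sep = "")
})

setMethod("show", "ExperimentResult", function(object) {
  cat("ExperimentResult: ", nrow(object@scoreSummary), " rounds\n", sep = "")
  if (nrow(object@rTable)) {
    agg <- aggregate(r ~ variant + target, object@rTable, mean)
    gs <- agg[agg$target == "generalized_score", , drop = FALSE]
    for (i in seq_len(nrow(gs)))
      cat("  mean r (generalized score, ", gs$variant[i], "): ",
          sprintf("%.3f", gs$r[i]), "\n", sep = "")
  }
})
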
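#' Edge-weight feature matrix X1
#'
#' One row per subject holding the strict upper triangle of its connectivity
#' matrix in row-major order (i < j, i ascending then j), giving
#' P = N(N-1)/2 features labelled "<roi_i>--<roi_j>".
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @return A \linkS4class{FeatureMatrix} with variant "X1".
#' @export
buildX1 <- function(cohort) {
  validObject(cohort)
  rois <- roiLabels(cohort)
  n <- length(rois)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]   # row-major i<j
  labels <- paste0(rois[ut[, 1L]], "--", rois[ut[, 2L]])
  vals <- t(vapply(cohort@connectomes,
                   function(cm) cm@weights[ut], numeric(nrow(ut))))
  new("FeatureMatrix", values = unname(vals), featureLabels = labels,
      subjectIDs = subjectIDs(cohort), variant = "X1")
}

#' Node-metric feature matrix X2
#'
#' One row per subject holding the three node-level graph metrics for every
#' region, grouped in blocks: strength ("S-<roi>"), eigenvector centrality
#' ("eig-<roi>"), local efficiency ("E-<roi>"); P = 3N features.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param lengths link-length convention for \code{\link{localEfficiency}}.
#' @return A \linkS4class{FeatureMatrix} with variant "X2".
#' @export
buildX2 <- function(cohort, lengths = "inverse") {
  validObject(cohort)
  rois <- roiLabels(cohort)
  n <- length(rois)
  labels <- c(paste0("S-", rois), paste0("eig-", rois), paste0("E-", rois))
  vals <- t(vapply(cohort@connectomes, function(cm) {
    c(unname(nodeStrength(cm)),
      unname(eigenvectorCentrality(cm)$vector),
      unname(localEfficiency(cm, lengths)))
  }, numeric(3L * n)))
  new("FeatureMatrix", values = unname(vals), featureLabels = labels,
      subjectIDs = subjectIDs(cohort), variant = "X2")
}

#' Rebuild a connectivity matrix from one row of X1
#'
#' Inverse of the vectorization used by \code{\link{buildX1}}; mainly a
#' round-trip check.
#'
#' @param x a \linkS4class{FeatureMatrix} with variant "X1".
#' @param subject subject identifier or row index.
#' @param roiLabels the region labels of the original matrices.
#' @return A \linkS4class{ConnectivityMatrix}.
#' @export
connectivityFromX1 <- function(x, subject, roiLabels) {
  stopifnot(x@variant == "X1")
  i <- if (is.character(subject)) match(subject, x@subjectIDs) else subject
  n <- length(roiLabels)
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  w[ut] <- x@values[i, ]
  w <- w + t(w)
  connectivityMatrix(w, roiLabels, subjectID = x@subjectIDs[i])
}

#' Write a feature matrix to CSV
#'
#' Header row of feature labels with a leading subject_id column.
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeFeatureMatrix <- function(x, path) {
  df <- data.frame(subject_id = x@subjectIDs, x@values, check.names = FALSE)
  names(df) <- c("subject_id", x@featureLabels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
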
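#' Construct a ConnectivityMatrix
#'
#' @param weights square numeric matrix of non-negative, symmetric,
#'   zero-diagonal edge weights.
#' @param roiLabels region names; defaults to rownames or ROI001, ROI002, ...
#' @param subjectID subject identifier.
#' @return A validated \linkS4class{ConnectivityMatrix}.
#' @examples
#' w <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
#' connectivityMatrix(w, subjectID = "sub-01")
#' @export
connectivityMatrix <- function(weights, roiLabels = NULL,
                               subjectID = "subject") {
  weights <- as.matrix(weights)
  if (is.null(roiLabels))
    roiLabels <- rownames(weights) %||% sprintf("ROI%03d", seq_len(nrow(weights)))
  dimnames(weights) <- list(roiLabels, roiLabels)
  new("ConnectivityMatrix", weights = weights,
      roiLabels = as.character(roiLabels),
      subjectID = as.character(subjectID))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a ClinicalTable
#'
#' @param values M x S numeric matrix (or data.frame) of index scores.
#' @param indexNames S index names; defaults to column names.
#' @param subjectIDs M subject identifiers; defaults to rownames.
#' @param diagnosis M labels in NC/MCI/AD.
#' @return A validated \linkS4class{ClinicalTable}.
#' @export
clinicalTable <- function(values, indexNames = colnames(values),
                          subjectIDs = rownames(values), diagnosis) {
  values <- as.matrix(values)
  if (is.null(indexNames))
    indexNames <- sprintf("index%02d", seq_len(ncol(values)))
  if (is.null(subjectIDs))
    subjectIDs <- sprintf("sub%04d", seq_len(nrow(values)))
  dimnames(values) <- list(subjectIDs, indexNames)
  new("ClinicalTable", values = values, indexNames = as.character(indexNames),
      subjectIDs = as.character(subjectIDs),
      diagnosis = as.character(diagnosis))
}

#' Construct a CohortDataset
#'
#' @param connectomes list of \linkS4class{ConnectivityMatrix}, aligned with
#'   the clinical table rows.
#' @param clinical a \linkS4class{ClinicalTable}.
#' @return A validated \linkS4class{CohortDataset}.
#' @export
cohortDataset <- function(connectomes, clinical) {
  new("CohortDataset", connectomes = connectomes, clinical = clinical)
}

#' Subset a cohort or clinical table by subject
#'
#' @param x a \linkS4class{CohortDataset} or \linkS4class{ClinicalTable}.
#' @param i integer or logical subject index.
#' @param j,drop,... ignored.
#' @return Object of the same class restricted to the selected subjects.
#' @export
setMethod("[", "ClinicalTable", function(x, i, j, ..., drop = FALSE) {
  new("ClinicalTable", values = x@values[i, , drop = FALSE],
      indexNames = x@indexNames, subjectIDs = x@subjectIDs[i],
      diagnosis = x@diagnosis[i])
})

#' @rdname sub-ClinicalTable-ANY-ANY-ANY-method
#' @export
setMethod("[", "CohortDataset", function(x, i, j, ..., drop = FALSE) {
  new("CohortDataset", connectomes = x@connectomes[i],
      clinical = x@clinical[i])
})

#' @rdname sub-ClinicalTable-ANY-ANY-ANY-method
#' @export
setMethod("[", "FeatureMatrix", function(x, i, j, ..., drop = FALSE) {
  new("FeatureMatrix", values = x@values[i, , drop = FALSE],
      featureLabels = x@featureLabels, subjectIDs = x@subjectIDs[i],
      variant = x@variant)
})
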
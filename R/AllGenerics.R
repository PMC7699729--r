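#' @rdname accessors
#' @export
setGeneric("connWeights", function(object) standardGeneric("connWeights"))
#' @rdname accessors
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))
#' @rdname accessors
#' @export
setGeneric("subjectIDs", function(object) standardGeneric("subjectIDs"))
#' @rdname accessors
#' @export
setGeneric("nSubjects", function(object) standardGeneric("nSubjects"))
#' @rdname accessors
#' @export
setGeneric("featureLabels", function(object) standardGeneric("featureLabels"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("clinicalValues", function(object) standardGeneric("clinicalValues"))
#' @rdname accessors
#' @export
setGeneric("indexNames", function(object) standardGeneric("indexNames"))
#' @rdname accessors
#' @export
setGeneric("diagnosis", function(object) standardGeneric("diagnosis"))
#' @rdname accessors
#' @export
setGeneric("clinicalData", function(object) standardGeneric("clinicalData"))
#' @rdname accessors
#' @export
setGeneric("connectomes", function(object) standardGeneric("connectomes"))
#' @rdname accessors
#' @export
setGeneric("scoreLoadings", function(object) standardGeneric("scoreLoadings"))
#' @rdname accessors
#' @export
setGeneric("explainedVariance",
           function(object) standardGeneric("explainedVariance"))
#' @rdname accessors
#' @export
setGeneric("indexContributions",
           function(object) standardGeneric("indexContributions"))
#' @rdname accessors
#' @export
setGeneric("clusterNMI", function(object) standardGeneric("clusterNMI"))
#' @rdname accessors
#' @export
setGeneric("permutationP", function(object) standardGeneric("permutationP"))
#' @rdname accessors
#' @export
setGeneric("stabilityTable", function(object) standardGeneric("stabilityTable"))
#' @rdname accessors
#' @export
setGeneric("stableFeatures", function(object) standardGeneric("stableFeatures"))
#' @rdname accessors
#' @export
setGeneric("trueSeverity", function(object) standardGeneric("trueSeverity"))
#' @rdname accessors
#' @export
setGeneric("plantedFeatures",
           function(object) standardGeneric("plantedFeatures"))
#' @rdname accessors
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))
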
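#' @useDynLib connectoscore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats aggregate coef cor dnorm predict quantile rbinom rnorm
#'   rpois sd var wilcox.test setNames
NULL

#' Weighted structural connectome of one subject
#'
#' An N x N symmetric, non-negative, zero-diagonal matrix of edge weights
#' (typically streamline counts between atlas regions) together with region
#' labels and a subject identifier.
#'
#' @slot weights numeric N x N matrix of edge weights \eqn{w_{ij}}.
#' @slot roiLabels character vector of N region names.
#' @slot subjectID length-one character identifier.
#' @export
setClass("ConnectivityMatrix",
  representation(weights = "matrix", roiLabels = "character",
                 subjectID = "character"))

setValidity("ConnectivityMatrix", function(object) {
  w <- object@weights
  msg <- character()
  if (!is.numeric(w) || nrow(w) != ncol(w))
    msg <- c(msg, "'weights' must be a square numeric matrix")
  else {
    if (anyNA(w)) msg <- c(msg, "'weights' contains missing values")
    else {
      if (any(w < 0)) msg <- c(msg, "'weights' must be non-negative")
      if (max(abs(w - t(w))) > 1e-8) msg <- c(msg, "'weights' must be symmetric")
      if (any(diag(w) != 0)) msg <- c(msg, "diagonal of 'weights' must be zero")
    }
    if (length(object@roiLabels) != nrow(w))
      msg <- c(msg, "length(roiLabels) must equal nrow(weights)")
  }
  if (length(object@subjectID) != 1L)
    msg <- c(msg, "'subjectID' must have length 1")
  if (length(msg)) msg else TRUE
})

#' Clinical outcome table
#'
#' Subjects x indices matrix of clinical assessment scores, with diagnostic
#' labels (NC, MCI or AD) aligned to the rows.
#'
#' @slot values numeric M x S matrix Y of index scores.
#' @slot indexNames character vector of S index names.
#' @slot subjectIDs character vector of M subject identifiers.
#' @slot diagnosis character vector of M labels in \{NC, MCI, AD\}.
#' @export
setClass("ClinicalTable",
  representation(values = "matrix", indexNames = "character",
                 subjectIDs = "character", diagnosis = "character"))

setValidity("ClinicalTable", function(object) {
  msg <- character()
  if (anyNA(object@values)) msg <- c(msg, "clinical values contain NA")
  if (ncol(object@values) != length(object@indexNames))
    msg <- c(msg, "indexNames must match column count")
  if (ncol(object@values) < 2L)
    msg <- c(msg, "at least 2 clinical indices are required")
  if (nrow(object@values) != length(object@subjectIDs))
    msg <- c(msg, "subjectIDs must match row count")
  if (length(object@diagnosis) != length(object@subjectIDs))
    msg <- c(msg, "diagnosis must match subject count")
  if (!all(object@diagnosis %in% c("NC", "MCI", "AD")))
    msg <- c(msg, "diagnosis labels must be NC, MCI or AD")
  if (length(msg)) msg else TRUE
})

#' Aligned cohort of connectomes and clinical data
#'
#' @slot connectomes list of \linkS4class{ConnectivityMatrix}, one per subject,
#'   in the same order as the clinical table rows.
#' @slot clinical a \linkS4class{ClinicalTable}.
#' @export
setClass("CohortDataset",
  representation(connectomes = "list", clinical = "ClinicalTable"))

setValidity("CohortDataset", function(object) {
  msg <- character()
  if (!all(vapply(object@connectomes, is, logical(1), "ConnectivityMatrix")))
    msg <- c(msg, "all connectomes must be ConnectivityMatrix objects")
  else {
    ids <- vapply(object@connectomes, function(x) x@subjectID, character(1))
    if (!identical(ids, object@clinical@subjectIDs))
      msg <- c(msg, "connectome subject order must match the clinical table")
    labs <- lapply(object@connectomes, function(x) x@roiLabels)
    if (length(labs) > 1L && !all(vapply(labs, identical, logical(1), labs[[1]])))
      msg <- c(msg, "all subjects must share the same ROI labels")
  }
  if (length(msg)) msg else TRUE
})

#' Subjects x features design matrix
#'
#' Either the edge-weight matrix X1 (strict upper triangle of each connectome,
#' P = N(N-1)/2 columns) or the node-metric matrix X2 (strength, eigenvector
#' centrality and local efficiency per region, P = 3N columns).
#'
#' @slot values numeric M x P matrix.
#' @slot featureLabels character vector of P labels.
#' @slot subjectIDs character vector of M subject identifiers.
#' @slot variant "X1" or "X2".
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", featureLabels = "character",
                 subjectIDs = "character", variant = "character"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@featureLabels))
    msg <- c(msg, "featureLabels must match column count")
  if (nrow(object@values) != length(object@subjectIDs))
    msg <- c(msg, "subjectIDs must match row count")
  if (anyNA(object@values)) msg <- c(msg, "feature values contain NA")
  if (!object@variant %in% c("X1", "X2"))
    msg <- c(msg, "variant must be 'X1' or 'X2'")
  if (length(msg)) msg else TRUE
})

#' First-principal-component cognitive score model
#'
#' Standardization parameters and first-PC loadings estimated on a training
#' fold of the clinical table, used to project any subject onto the
#' generalized cognitive score axis.
#'
#' @slot center,scale per-index training mean and scale.
#' @slot loadings unit-norm loading vector c1.
#' @slot explainedVariance fraction of (standardized) variance carried by the
#'   first component.
#' @slot contributions per-index percentage contribution (100 * c1^2).
#' @slot signAnchor index whose loading is constrained positive.
#' @slot indexNames index names, aligned with loadings.
#' @slot trainScores scores of the training subjects at fit time.
#' @slot standardized logical; TRUE for correlation-matrix PCA.
#' @export
setClass("ScoreModel",
  representation(center = "numeric", scale = "numeric", loadings = "numeric",
                 explainedVariance = "numeric", contributions = "numeric",
                 signAnchor = "character", indexNames = "character",
                 trainScores = "numeric", standardized = "logical"))

setValidity("ScoreModel", function(object) {
  msg <- character()
  if (abs(sqrt(sum(object@loadings^2)) - 1) > 1e-8)
    msg <- c(msg, "loadings must have unit Euclidean norm")
  if (any(object@contributions < 0) ||
      abs(sum(object@contributions) - 100) > 1e-6)
    msg <- c(msg, "contributions must be non-negative and sum to 100")
  if (object@explainedVariance <= 0 || object@explainedVariance > 1 + 1e-12)
    msg <- c(msg, "explainedVariance must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Univariate Gaussian mixture fit
#'
#' @slot weights,means,variances mixture parameters (weights sum to 1).
#' @slot labels hard assignment of each observation (argmax responsibility).
#' @slot logLik final log-likelihood of the best EM restart.
#' @slot trace log-likelihood trace of the best restart (non-decreasing).
#' @export
setClass("GmmFit",
  representation(weights = "numeric", means = "numeric", variances = "numeric",
                 labels = "integer", logLik = "numeric", trace = "numeric"))

setValidity("GmmFit", function(object) {
  msg <- character()
  if (abs(sum(object@weights) - 1) > 1e-6)
    msg <- c(msg, "component weights must sum to 1")
  if (any(object@variances <= 0)) msg <- c(msg, "variances must be positive")
  if (length(msg)) msg else TRUE
})

#' Cluster-based validation of the cognitive score
#'
#' GMM clustering of the score, normalized mutual information against
#' diagnostic labels, and a label-permutation null.
#'
#' @slot clusterLabels per-subject cluster assignment.
#' @slot nComponents number of mixture components.
#' @slot nmi observed normalized mutual information.
#' @slot nullNmi NMI values under permuted labels.
#' @slot pValue fraction of null values >= observed.
#' @slot gmm the underlying \linkS4class{GmmFit}.
#' @export
setClass("ClusterValidation",
  representation(clusterLabels = "integer", nComponents = "integer",
                 nmi = "numeric", nullNmi = "numeric", pValue = "numeric",
                 gmm = "GmmFit"))

setValidity("ClusterValidation", function(object) {
  msg <- character()
  if (object@nmi < -1e-12 || object@nmi > 1 + 1e-12)
    msg <- c(msg, "nmi must lie in [0, 1]")
  if (length(object@nullNmi)) {
    p <- mean(object@nullNmi >= object@nmi)
    if (abs(p - object@pValue) > 1e-12)
      msg <- c(msg, "pValue must equal the fraction of null values >= nmi")
  }
  if (length(msg)) msg else TRUE
})

#' L1-penalized regression fit
#'
#' Coefficients are stored on the standardized-predictor scale; use
#' \code{coef(fit, scale = "original")} for the raw-feature scale.
#'
#' @slot beta coefficient vector (standardized scale; exact zeros).
#' @slot intercept intercept on the response scale.
#' @slot lambda penalty at which beta was obtained.
#' @slot lambdaPath data.frame of the tuning path (lambda, validation r),
#'   empty for a direct single-lambda fit.
#' @slot center,scale per-feature standardization from the training data
#'   (scale 0 marks a constant column whose coefficient is fixed at 0).
#' @slot responseCenter training mean of the response.
#' @slot featureLabels feature names aligned with beta.
#' @export
setClass("LassoFit",
  representation(beta = "numeric", intercept = "numeric", lambda = "numeric",
                 lambdaPath = "data.frame", center = "numeric",
                 scale = "numeric", responseCenter = "numeric",
                 featureLabels = "character"))

setValidity("LassoFit", function(object) {
  msg <- character()
  if (any(!is.finite(object@beta))) msg <- c(msg, "beta must be finite")
  if (object@lambda < 0) msg <- c(msg, "lambda must be non-negative")
  if (length(object@beta) != length(object@featureLabels))
    msg <- c(msg, "featureLabels must match beta length")
  if (length(msg)) msg else TRUE
})

#' Frequency-based stability report for a T x P weight matrix
#'
#' @slot table data.frame with one row per feature: label, frequency (fraction
#'   of rounds with a nonzero weight), meanWeight (mean over all rounds, zeros
#'   included), sign, selected.
#' @slot percentile,occurrenceCut thresholds used by the selection step (NA
#'   before selection).
#' @slot stableFeatures labels passing both criteria, ordered by
#'   |meanWeight| descending.
#' @slot nullModel TRUE when the weight matrix was entirely zero.
#' @export
setClass("StabilityReport",
  representation(table = "data.frame", percentile = "numeric",
                 occurrenceCut = "numeric", stableFeatures = "character",
                 nullModel = "logical"))

setValidity("StabilityReport", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("label", "frequency", "meanWeight", "sign", "selected")
  if (!all(need %in% names(tb)))
    msg <- c(msg, "table must have columns label/frequency/meanWeight/sign/selected")
  else {
    if (any(tb$frequency < 0 | tb$frequency > 1))
      msg <- c(msg, "frequencies must lie in [0, 1]")
    if (!all(object@stableFeatures %in% tb$label[tb$frequency > 0]))
      msg <- c(msg, "stable features must have positive frequency")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort with known ground truth
#'
#' @slot dataset the generated \linkS4class{CohortDataset}.
#' @slot trueSeverity per-subject latent severity.
#' @slot plantedFeatures data.frame (label, sign) of X2 feature labels whose
#'   generator-level association with severity is nonzero.
#' @slot config the \linkS4class{SyntheticConfig} used.
#' @export
setClass("SyntheticCohort",
  representation(dataset = "CohortDataset", trueSeverity = "numeric",
                 plantedFeatures = "data.frame", config = "ANY"))

#' Configuration of the synthetic cohort generator
#'
#' See \code{\link{syntheticConfig}} for defaults and semantics.
#' @export
setClass("SyntheticConfig", representation(params = "list"))

setValidity("SyntheticConfig", function(object) {
  p <- object@params
  msg <- character()
  if (any(c(p$n_nc, p$n_mci, p$n_ad, p$n_rois, p$n_indices) <= 0))
    msg <- c(msg, "all counts must be positive")
  if (p$effect_size < 0) msg <- c(msg, "effect_size must be >= 0")
  if (length(intersect(p$planted_negative_rois, p$planted_positive_rois)))
    msg <- c(msg, "planted ROI sets must be disjoint")
  rois <- c(p$planted_negative_rois, p$planted_positive_rois)
  if (length(rois) && (any(rois < 1) || any(rois > p$n_rois)))
    msg <- c(msg, "planted ROI indices out of range")
  if (p$base_density <= 0 || p$base_density > 1)
    msg <- c(msg, "base_density must lie in (0, 1]")
  if (length(p$index_loadings) != p$n_indices)
    msg <- c(msg, "index_loadings must have length n_indices")
  if (length(p$index_noise_sd) != p$n_indices)
    msg <- c(msg, "index_noise_sd must have length n_indices")
  if (length(msg)) msg else TRUE
})

#' Result of a full repeated cross-validation experiment
#'
#' @slot rTable data.frame of held-out correlations: round, variant, target, r,
#'   lambda.
#' @slot B named list (per variant) of T x P weight matrices for the
#'   generalized-score models.
#' @slot stability named list (per variant) of \linkS4class{StabilityReport}.
#' @slot scoreSummary data.frame per round: explained variance, NMI,
#'   permutation p.
#' @slot folds the fold plan used.
#' @slot config the experiment configuration list.
#' @export
setClass("ExperimentResult",
  representation(rTable = "data.frame", B = "list", stability = "list",
                 scoreSummary = "data.frame", folds = "list", config = "list"))
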
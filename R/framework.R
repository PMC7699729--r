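#' Experiment configuration
#'
#' Collects every tunable of the repeated cross-validation experiment into a
#' plain named list (echoed into results for audit).
#'
#' @param vRepeats number of cross-validation repeats V.
#' @param kFolds folds per repeat k; the experiment runs T = V * k rounds.
#' @param seed master seed; per-round child seeds are derived from it.
#' @param indexFilterThreshold mutual-correlation cut for the clinical
#'   battery (applied once, before cross-validation).
#' @param signAnchor index anchoring the score orientation.
#' @param standardizeScore correlation-matrix (TRUE) or covariance PCA.
#' @param variants feature variants to run, subset of c("X1", "X2").
#' @param targets "all" (generalized score plus every clinical index) or
#'   "generalized" only.
#' @param nComponents GMM components for score validation.
#' @param nPerm permutations per round for the NMI null (0 disables the
#'   per-round permutation test).
#' @param nLambda,lambdaRatio penalty grid settings.
#' @param valFraction inner validation fraction for penalty tuning.
#' @param percentile,occurrenceCut stability-selection thresholds.
#' @param efficiencyLengths link-length convention for local efficiency.
#' @return Named list of class "connExperimentConfig".
#' @export
experimentConfig <- function(vRepeats = 10L, kFolds = 10L, seed = 1L,
                             indexFilterThreshold = 0.75,
                             signAnchor = "ADAS-Cog-13",
                             standardizeScore = TRUE,
                             variants = c("X1", "X2"),
                             targets = c("all", "generalized"),
                             nComponents = 3L, nPerm = 1000L,
                             nLambda = 100L, lambdaRatio = 1e-3,
                             valFraction = 0.25, percentile = 99,
                             occurrenceCut = 0.7,
                             efficiencyLengths = "inverse") {
  targets <- match.arg(targets)
  stopifnot(kFolds >= 2L, vRepeats >= 1L,
            indexFilterThreshold > 0, indexFilterThreshold <= 1,
            all(variants %in% c("X1", "X2")))
  structure(list(vRepeats = as.integer(vRepeats), kFolds = as.integer(kFolds),
                 seed = as.integer(seed),
                 indexFilterThreshold = indexFilterThreshold,
                 signAnchor = signAnchor, standardizeScore = standardizeScore,
                 variants = variants, targets = targets,
                 nComponents = as.integer(nComponents),
                 nPerm = as.integer(nPerm), nLambda = as.integer(nLambda),
                 lambdaRatio = lambdaRatio, valFraction = valFraction,
                 percentile = percentile, occurrenceCut = occurrenceCut,
                 efficiencyLengths = efficiencyLengths),
            class = "connExperimentConfig")
}

#' Filter mutually correlated clinical indices
#'
#' Greedy elimination: while any pair of indices has absolute Pearson
#' correlation at or above the threshold, drop from the worst pair the index
#' with the larger mean absolute correlation to all remaining others.  The
#' survivors therefore all have mutual |r| below the threshold.
#'
#' @param y a \linkS4class{ClinicalTable}.
#' @param threshold correlation cut in (0, 1].
#' @return The filtered \linkS4class{ClinicalTable}; dropped index names in
#'   attribute \code{"dropped"}.
#' @export
filterIndices <- function(y, threshold = 0.75) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  keep <- seq_along(y@indexNames)
  dropped <- character(0)
  repeat {
    if (length(keep) < 2L)
      stop("fewer than 2 indices survive the correlation filter")
    r <- abs(cor(y@values[, keep, drop = FALSE]))
    diag(r) <- 0
    if (max(r) < threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1L, ]
    meanAbs <- rowMeans(r)
    drop <- worst[which.max(meanAbs[worst])]
    dropped <- c(dropped, y@indexNames[keep[drop]])
    keep <- keep[-drop]
  }
  out <- new("ClinicalTable", values = y@values[, keep, drop = FALSE],
             indexNames = y@indexNames[keep], subjectIDs = y@subjectIDs,
             diagnosis = y@diagnosis)
  attr(out, "dropped") <- dropped
  out
}

#' Build the repeated cross-validation fold plan
#'
#' V independent shuffles, each split into k folds stratified by diagnosis
#' (with an unstratified fallback and warning when a group is smaller than
#' k), giving T = V * k (train, test) rounds.  Deterministic given the seed.
#'
#' @param dataset a \linkS4class{CohortDataset} (or a diagnosis label
#'   vector).
#' @param v number of repeats.
#' @param k folds per repeat.
#' @param seed RNG seed.
#' @return List of T rounds, each with elements \code{train}, \code{test},
#'   \code{repeatIndex}, \code{foldIndex}.
#' @export
makeFolds <- function(dataset, v = 10L, k = 10L, seed = 1L) {
  labels <- if (is(dataset, "CohortDataset")) diagnosis(dataset)
            else as.character(dataset)
  m <- length(labels)
  if (m < k) stop("cohort smaller than the number of folds")
  rounds <- vector("list", v * k)
  seeds <- childSeeds(seed, v)
  for (rep_ in seq_len(v)) {
    fold <- withSeed(seeds[rep_], foldAssignment(labels, k))
    for (f in seq_len(k)) {
      test <- which(fold == f)
      rounds[[(rep_ - 1L) * k + f]] <-
        list(train = setdiff(seq_len(m), test), test = test,
             repeatIndex = rep_, foldIndex = f)
    }
  }
  rounds
}

#' Run the full repeated cross-validation experiment
#'
#' For every round: fit the generalized-score model on the training fold,
#' optionally validate it by GMM clustering with an NMI permutation null,
#' project the held-out fold, then for each feature variant and each target
#' (the generalized score and, with \code{targets = "all"}, every clinical
#' index) tune and fit the Lasso on the training fold and record the
#' held-out correlation.  Weight vectors of the generalized-score models are
#' stacked into a T x P matrix per variant and summarized by
#' frequency-based stability selection.
#'
#' Every per-round transformation (index standardization, PCA loadings,
#' feature standardization, penalty selection) is derived from training data
#' only.  Fully reproducible from (dataset, config).
#'
#' @param dataset a \linkS4class{CohortDataset}.
#' @param config an \code{\link{experimentConfig}}.
#' @param features optional pre-built named list of
#'   \linkS4class{FeatureMatrix} objects (avoids recomputation).
#' @param verbose print a structured line per round.
#' @return An \linkS4class{ExperimentResult}.
#' @export
runExperiment <- function(dataset, config = experimentConfig(),
                          features = NULL, verbose = FALSE) {
  validObject(dataset)
  clinical <- filterIndices(dataset@clinical, config$indexFilterThreshold)
  anchor <- config$signAnchor
  if (!anchor %in% clinical@indexNames) {
    if (!anchor %in% dataset@clinical@indexNames)
      stop("sign anchor '", anchor, "' is not a clinical index")
    # the configured anchor was removed by the correlation filter: re-anchor
    # to the surviving index most positively correlated with it, preserving
    # the score orientation
    rr <- cor(dataset@clinical@values[, anchor], clinical@values)
    if (max(rr) <= 0)
      stop("no surviving index is positively correlated with the anchor")
    anchor <- clinical@indexNames[which.max(rr)]
    message("sign anchor re-set to '", anchor, "' (original was filtered out)")
  }
  if (is.null(features)) {
    features <- list()
    if ("X1" %in% config$variants) features$X1 <- buildX1(dataset)
    if ("X2" %in% config$variants)
      features$X2 <- buildX2(dataset, config$efficiencyLengths)
  }
  labels <- diagnosis(dataset)
  t_ <- config$vRepeats * config$kFolds
  masterSeeds <- childSeeds(config$seed, 2L)
  folds <- makeFolds(dataset, config$vRepeats, config$kFolds,
                     seed = masterSeeds[1L])
  roundSeeds <- childSeeds(masterSeeds[2L], t_)

  targetNames <- c("generalized_score",
                   if (config$targets == "all") clinical@indexNames)
  rows <- vector("list", t_ * length(config$variants) * length(targetNames))
  bmats <- lapply(features, function(f)
    matrix(0, t_, length(f@featureLabels),
           dimnames = list(NULL, f@featureLabels)))
  scoreSummary <- data.frame(round = seq_len(t_),
                             explainedVariance = NA_real_, nmi = NA_real_,
                             pValue = NA_real_)
  ri <- 0L
  for (t in seq_len(t_)) {
    fold <- folds[[t]]
    seeds <- childSeeds(roundSeeds[t], 2L + length(config$variants) *
                                         length(targetNames))
    yTrain <- clinical[fold$train]
    model <- fitScore(yTrain, anchor, config$standardizeScore)
    scoreSummary$explainedVariance[t] <- model@explainedVariance

    if (config$nPerm > 0L) {
      val <- validateScore(model@trainScores, labels[fold$train],
                           nComponents = config$nComponents,
                           nPerm = config$nPerm, seed = seeds[1L])
      scoreSummary$nmi[t] <- val@nmi
      scoreSummary$pValue[t] <- val@pValue
    }
    zTrain <- model@trainScores
    zTest <- transformScore(model, clinical[fold$test])

    si <- 2L
    for (variant in names(features)) {
      xAll <- features[[variant]]
      xTrain <- xAll@values[fold$train, , drop = FALSE]
      xTest <- xAll@values[fold$test, , drop = FALSE]
      for (target in targetNames) {
        si <- si + 1L
        tr <- if (target == "generalized_score") zTrain
              else clinical@values[fold$train, target]
        te <- if (target == "generalized_score") zTest
              else clinical@values[fold$test, target]
        fit <- tuneLambda(xTrain, tr, valFraction = config$valFraction,
                          seed = seeds[si], diagnosis = labels[fold$train],
                          nLambda = config$nLambda, ratio = config$lambdaRatio)
        r <- evaluateR(te, predict(fit, xTest), warn = FALSE)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(round = t, variant = variant,
                                 target = target, r = r,
                                 lambda = fit@lambda,
                                 stringsAsFactors = FALSE)
        if (target == "generalized_score")
          bmats[[variant]][t, ] <- fit@beta
        if (verbose)
          message(sprintf("round=%d variant=%s target=%s lambda=%.4g r=%.3f",
                          t, variant, target, fit@lambda, r))
      }
    }
  }
  stability <- lapply(names(features), function(variant)
    selectStable(computeStability(bmats[[variant]],
                                  features[[variant]]@featureLabels),
                 percentile = config$percentile,
                 occurrenceCut = config$occurrenceCut))
  names(stability) <- names(features)
  new("ExperimentResult", rTable = do.call(rbind, rows[seq_len(ri)]),
      B = bmats, stability = stability, scoreSummary = scoreSummary,
      folds = folds, config = unclass(config))
}

#' Compare two held-out correlation distributions
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test with normal approximation
#' and tie correction, as used to compare the R distributions of two models
#' across the T rounds.
#'
#' @param rA,rB equal-length numeric vectors of per-round correlations.
#' @return Two-sided p-value.
#' @export
compareModels <- function(rA, rB) {
  if (length(rA) != length(rB)) stop("r vectors must have equal length")
  if (sd(rA) == 0 || sd(rB) == 0)
    stop("constant r vector; rank-sum comparison is not meaningful")
  wilcox.test(rA, rB, exact = FALSE, correct = TRUE)$p.value
}

#' Summarize held-out correlations per variant and target
#'
#' @param result an \linkS4class{ExperimentResult}.
#' @return data.frame with variant, target, meanR, sdR over rounds.
#' @export
summarizeR <- function(result) {
  tab <- result@rTable
  agg <- aggregate(r ~ variant + target, tab,
                   function(v) c(mean = mean(v), sd = sd(v)))
  out <- data.frame(variant = agg$variant, target = agg$target,
                    meanR = agg$r[, "mean"], sdR = agg$r[, "sd"],
                    stringsAsFactors = FALSE)
  out[order(out$variant, -out$meanR), , drop = FALSE]
}
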
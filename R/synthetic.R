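#' Configuration for the synthetic cohort generator
#'
#' Defines a one-factor generative model for a cohort of structural
#' connectomes and clinical indices.  Each subject carries a latent severity
#' drawn from its diagnostic group's normal distribution; every clinical index
#' is a signed loading on that severity plus Gaussian noise, and the edge
#' weights incident to a planted subset of regions are modulated
#' multiplicatively by severity (down for "negative" regions, up for
#' "positive" ones).  Edge weights are Poisson streamline counts over a
#' Bernoulli edge mask, so matrices are integer, symmetric, non-negative and
#' zero-diagonal.
#'
#' Defaults emulate a 191-subject cohort (48 NC, 104 MCI, 39 AD), 120 regions
#' and a 10-index battery.  Group severity means overlap (NC < MCI < AD) so
#' that clustering recovers the groups only imperfectly.  Index loadings
#' carry mixed signs (instruments where higher scores mean worse versus
#' better functioning) and heterogeneous magnitudes, so that the battery is
#' dominated by one severity dimension while every pairwise index
#' correlation stays below the usual 0.75 mutual-correlation screen; the
#' model-implied first-component explained variance is available in closed
#' form from \code{\link{theoreticalMoments}}.
#'
#' @param n_nc,n_mci,n_ad subject counts per diagnostic group.
#' @param n_rois number of regions.
#' @param n_indices number of clinical indices.
#' @param group_severity_means,group_severity_sds named (NC, MCI, AD) latent
#'   severity distribution parameters.
#' @param index_loadings signed per-index loading on the latent factor.
#' @param index_noise_sd per-index residual noise SD (recycled to
#'   \code{n_indices}).
#' @param index_names clinical index names.
#' @param planted_negative_rois,planted_positive_rois disjoint ROI index sets
#'   whose incident edges are scaled down / up with severity.
#' @param effect_size multiplicative modulation per unit of standardized
#'   severity (>= 0).
#' @param base_density expected fraction of present edges, in (0, 1].
#' @param base_weight_scale Poisson mean streamline count for present edges.
#' @param seed RNG seed for \code{\link{generateCohort}}.
#' @return A validated \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(n_nc = 48L, n_mci = 104L, n_ad = 39L,
                            n_rois = 120L, n_indices = 10L,
                            group_severity_means = c(NC = -1, MCI = 0.3,
                                                     AD = 1.3),
                            group_severity_sds = c(NC = 0.6, MCI = 0.7,
                                                   AD = 0.6),
                            index_loadings = NULL,
                            index_noise_sd = 0.7,
                            index_names = NULL,
                            planted_negative_rois = NULL,
                            planted_positive_rois = NULL,
                            effect_size = 0.4,
                            base_density = 0.3,
                            base_weight_scale = 20,
                            seed = 1L) {
  if (is.null(index_names)) {
    battery <- c("CDR-SOB", "ADAS-Cog-13", "MMSE", "MoCA", "FAQ",
                 "RAVLT-immediate", "RAVLT-learning", "RAVLT-percforgetting",
                 "ECog-PT-total", "ECog-SP-total")
    index_names <- if (n_indices <= length(battery)) battery[seq_len(n_indices)]
                   else sprintf("index%02d", seq_len(n_indices))
  }
  # default planted sets: 2 regions scaled down, 2 scaled up, spread over
  # the atlas (positions relative to n_rois so small test atlases work too)
  if (is.null(planted_negative_rois))
    planted_negative_rois <- unique(pmax(1L, round(n_rois * c(0.05, 0.20))))
  if (is.null(planted_positive_rois))
    planted_positive_rois <- setdiff(
      unique(pmax(1L, round(n_rois * c(0.50, 0.75)))), planted_negative_rois)
  if (is.null(index_loadings)) {
    # Heterogeneous magnitudes (some indices track severity more tightly than
    # others) with mixed signs: negative for MMSE, MoCA and the RAVLT
    # learning scores, where higher means better functioning.  Magnitudes are
    # kept moderate so that no pair of indices exceeds the usual 0.75
    # mutual-correlation screen at the default noise level.
    defaults <- c(0.9, 0.95, -0.9, -0.85, 0.7, -0.7, -0.85, 0.8, 0.7, 0.8)
    index_loadings <- rep_len(defaults, n_indices)
  }
  params <- list(n_nc = as.integer(n_nc), n_mci = as.integer(n_mci),
                 n_ad = as.integer(n_ad), n_rois = as.integer(n_rois),
                 n_indices = as.integer(n_indices),
                 group_severity_means = group_severity_means,
                 group_severity_sds = group_severity_sds,
                 index_loadings = as.numeric(index_loadings),
                 index_noise_sd = rep_len(as.numeric(index_noise_sd),
                                          n_indices),
                 index_names = as.character(index_names),
                 planted_negative_rois = as.integer(planted_negative_rois),
                 planted_positive_rois = as.integer(planted_positive_rois),
                 effect_size = as.numeric(effect_size),
                 base_density = as.numeric(base_density),
                 base_weight_scale = as.numeric(base_weight_scale),
                 seed = as.integer(seed))
  new("SyntheticConfig", params = params)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under the one-factor model described in
#' \code{\link{syntheticConfig}}.  Deterministic given the config seed.
#'
#' The ground-truth planted feature list contains the X2 strength features of
#' the planted regions (with the planted association sign): strength is the
#' metric the generator modulates directly, whereas centrality and efficiency
#' of those regions inherit only attenuated, collinear signal.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return A \linkS4class{SyntheticCohort}.
#' @examples
#' coh <- generateCohort(syntheticConfig(n_nc = 4, n_mci = 4, n_ad = 4,
#'                                       n_rois = 10, seed = 7))
#' coh
#' @export
generateCohort <- function(config) {
  validObject(config)
  p <- config@params
  withSeed(p$seed, {
    groups <- c(rep("NC", p$n_nc), rep("MCI", p$n_mci), rep("AD", p$n_ad))
    m <- length(groups)
    ids <- sprintf("sub%04d", seq_len(m))
    rois <- sprintf("ROI%03d", seq_len(p$n_rois))

    z <- rnorm(m, p$group_severity_means[groups], p$group_severity_sds[groups])
    zn <- as.numeric(scale(z))   # cohort-standardized severity for modulation

    y <- vapply(seq_len(p$n_indices), function(s)
      p$index_loadings[s] * z + rnorm(m, 0, p$index_noise_sd[s]),
      numeric(m))
    clinical <- clinicalTable(y, indexNames = p$index_names,
                              subjectIDs = ids, diagnosis = groups)

    # per-region multiplicative modulation factors, one column per subject
    fac <- matrix(1, p$n_rois, m)
    if (length(p$planted_negative_rois))
      fac[p$planted_negative_rois, ] <-
        rep(pmax(0, 1 - p$effect_size * zn),
            each = length(p$planted_negative_rois))
    if (length(p$planted_positive_rois))
      fac[p$planted_positive_rois, ] <-
        rep(pmax(0, 1 + p$effect_size * zn),
            each = length(p$planted_positive_rois))

    n <- p$n_rois
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
    ne <- nrow(ut)
    connectomes <- lapply(seq_len(m), function(sub) {
      mask <- rbinom(ne, 1L, p$base_density)
      mu <- p$base_weight_scale * fac[ut[, 1L], sub] * fac[ut[, 2L], sub]
      wvec <- mask * rpois(ne, mu)
      w <- matrix(0, n, n)
      w[ut] <- wvec
      w <- w + t(w)
      connectivityMatrix(w, rois, subjectID = ids[sub])
    })

    pasteLab <- function(idx) if (length(idx)) paste0("S-", rois[idx])
                              else character(0)
    planted <- data.frame(
      label = c(pasteLab(p$planted_negative_rois),
                pasteLab(p$planted_positive_rois)),
      sign = c(rep(-1, length(p$planted_negative_rois)),
               rep(1, length(p$planted_positive_rois))),
      stringsAsFactors = FALSE)

    new("SyntheticCohort",
        dataset = cohortDataset(connectomes, clinical),
        trueSeverity = z, plantedFeatures = planted, config = config)
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes one headerless connectivity CSV per subject
#' (\code{<subject_id>.csv}), a clinical CSV (subject_id, diagnosis, index
#' columns), a ground-truth CSV (severity and planted feature labels), a
#' manifest CSV mapping subject_id to matrix filename, and the config as YAML.
#'
#' @param cohort a \linkS4class{SyntheticCohort} or
#'   \linkS4class{CohortDataset}.
#' @param directory output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return Invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, directory, overwrite = FALSE) {
  truth <- NULL
  if (is(cohort, "SyntheticCohort")) {
    truth <- cohort
    dataset <- cohort@dataset
  } else dataset <- cohort
  if (dir.exists(directory) && length(dir(directory)) && !overwrite)
    stop("directory '", directory, "' is not empty; use overwrite = TRUE")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)

  cl <- dataset@clinical
  for (cm in dataset@connectomes)
    utils::write.table(cm@weights,
                       file.path(directory, paste0(cm@subjectID, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  clin <- data.frame(subject_id = cl@subjectIDs, diagnosis = cl@diagnosis,
                     cl@values, check.names = FALSE)
  names(clin) <- c("subject_id", "diagnosis", cl@indexNames)
  utils::write.csv(clin, file.path(directory, "clinical.csv"),
                   row.names = FALSE)
  manifest <- data.frame(subject_id = cl@subjectIDs,
                         file = paste0(cl@subjectIDs, ".csv"),
                         stringsAsFactors = FALSE)
  mpath <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  writeLines(c(paste("roi:", roiLabels(dataset), collapse = NULL)),
             file.path(directory, "roi_labels.txt"))
  if (!is.null(truth)) {
    gt <- data.frame(subject_id = cl@subjectIDs,
                     true_severity = truth@trueSeverity)
    utils::write.csv(gt, file.path(directory, "ground_truth_severity.csv"),
                     row.names = FALSE)
    utils::write.csv(truth@plantedFeatures,
                     file.path(directory, "ground_truth_planted.csv"),
                     row.names = FALSE)
    yaml::write_yaml(truth@config@params, file.path(directory, "config.yaml"))
  }
  invisible(mpath)
}

#' Read a cohort from a manifest directory
#'
#' Counterpart of \code{\link{writeCohort}}; round-trips integer edge weights
#' bit-exactly.
#'
#' @param directory directory containing manifest.csv, clinical.csv and the
#'   per-subject connectivity CSVs.
#' @return A \linkS4class{CohortDataset}.
#' @export
readCohort <- function(directory) {
  manifest <- utils::read.csv(file.path(directory, "manifest.csv"),
                              stringsAsFactors = FALSE)
  clin <- utils::read.csv(file.path(directory, "clinical.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  roiFile <- file.path(directory, "roi_labels.txt")
  rois <- if (file.exists(roiFile))
    sub("^roi: ", "", readLines(roiFile)) else NULL
  connectomes <- lapply(seq_len(nrow(manifest)), function(i) {
    w <- as.matrix(utils::read.csv(file.path(directory, manifest$file[i]),
                                   header = FALSE))
    connectivityMatrix(unname(w), rois, subjectID = manifest$subject_id[i])
  })
  clinical <- clinicalTable(as.matrix(clin[, -(1:2), drop = FALSE]),
                            indexNames = names(clin)[-(1:2)],
                            subjectIDs = clin$subject_id,
                            diagnosis = clin$diagnosis)
  cohortDataset(connectomes, clinical)
}

#' Model-implied moments of the synthetic generator
#'
#' Closed-form quantities of the one-factor generative model, derived from
#' the configuration alone (no data): the latent severity variance of the
#' group mixture, the model-implied correlation matrix of the clinical
#' indices, and the fraction of standardized variance carried by its leading
#' eigenvector — the value the fold-wise PCA should recover.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return List with \code{severityVariance}, \code{correlation} (S x S),
#'   and \code{explainedVariance} (leading eigenvalue / S).
#' @export
theoreticalMoments <- function(config) {
  p <- config@params
  wts <- c(p$n_nc, p$n_mci, p$n_ad) / (p$n_nc + p$n_mci + p$n_ad)
  mus <- p$group_severity_means[c("NC", "MCI", "AD")]
  sds <- p$group_severity_sds[c("NC", "MCI", "AD")]
  mz <- sum(wts * mus)
  vz <- sum(wts * (sds^2 + mus^2)) - mz^2
  a <- p$index_loadings
  s2 <- p$index_noise_sd^2
  cv <- outer(a, a) * vz
  diag(cv) <- a^2 * vz + s2
  cr <- stats::cov2cor(cv)
  ev <- eigen(cr, symmetric = TRUE, only.values = TRUE)$values[1L] /
    length(a)
  list(severityVariance = vz, correlation = cr, explainedVariance = ev)
}
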
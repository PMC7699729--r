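#' Per-feature selection frequency and mean weight
#'
#' Aggregates a T x P matrix of Lasso coefficient vectors (one row per
#' cross-validation round) into per-feature selection frequencies
#' \eqn{f_p = \#\{rounds: \beta_{tp} \ne 0\} / T}, mean weights (mean over
#' all T rounds, zeros included) and association signs.
#'
#' @param b T x P numeric weight matrix (exact zeros mark unselected
#'   features).
#' @param labels P feature labels.
#' @return A \linkS4class{StabilityReport} with no selection applied yet.
#' @export
computeStability <- function(b, labels) {
  b <- as.matrix(b)
  if (ncol(b) != length(labels))
    stop("label count (", length(labels), ") must match columns of B (",
         ncol(b), ")")
  if (nrow(b) < 1L) stop("need at least one round")
  freq <- colMeans(b != 0)
  mw <- colMeans(b)
  tab <- data.frame(label = labels, frequency = freq, meanWeight = mw,
                    sign = ifelse(mw > 0, "positive",
                                  ifelse(mw < 0, "negative", "none")),
                    selected = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  new("StabilityReport", table = tab, percentile = NA_real_,
      occurrenceCut = NA_real_, stableFeatures = character(0),
      nullModel = all(b == 0))
}

#' Threshold a stability report into a stable-feature list
#'
#' A feature is stable when its selection frequency strictly exceeds both the
#' given percentile of the frequency distribution (interpolated quantile over
#' the full feature vector, zeros included, unless
#' \code{everSelectedOnly = TRUE}) and the absolute occurrence cut.  Stable
#' features are ordered by |mean weight| descending and partitioned by the
#' sign of their mean weight.
#'
#' @param report a \linkS4class{StabilityReport} from
#'   \code{\link{computeStability}}.
#' @param percentile percentile of the frequency distribution, in [0, 100].
#' @param occurrenceCut absolute frequency cut in [0, 1].
#' @param everSelectedOnly compute the percentile over ever-selected features
#'   only.
#' @return The report with \code{selected} flags, thresholds and the ordered
#'   \code{stableFeatures} filled in.
#' @export
selectStable <- function(report, percentile = 99, occurrenceCut = 0.7,
                         everSelectedOnly = FALSE) {
  if (percentile < 0 || percentile > 100)
    stop("percentile must lie in [0, 100]")
  if (occurrenceCut < 0 || occurrenceCut > 1)
    stop("occurrenceCut must lie in [0, 1]")
  tab <- report@table
  pool <- if (everSelectedOnly) tab$frequency[tab$frequency > 0]
          else tab$frequency
  qthr <- if (length(pool)) quantile(pool, percentile / 100, names = FALSE)
          else Inf
  sel <- tab$frequency > qthr & tab$frequency > occurrenceCut
  tab$selected <- sel
  stable <- tab[sel, , drop = FALSE]
  stable <- stable[order(-abs(stable$meanWeight)), , drop = FALSE]
  report@table <- tab
  report@percentile <- percentile
  report@occurrenceCut <- occurrenceCut
  report@stableFeatures <- stable$label
  validObject(report)
  report
}

#' Parse X2 feature labels into metric and region
#'
#' Splits labels of the form "S-ROI001", "eig-ROI001" or "E-ROI001" into a
#' metric / ROI table, mirroring how stable-feature lists are reported per
#' region and metric.
#'
#' @param labels character vector of X2 feature labels.
#' @return data.frame with columns label, metric, roi.
#' @export
parseX2Labels <- function(labels) {
  metric <- sub("-.*$", "", labels)
  roi <- sub("^[^-]+-", "", labels)
  data.frame(label = labels, metric = metric, roi = roi,
             stringsAsFactors = FALSE)
}

#' Write a stability report to CSV
#'
#' Columns: feature label, frequency, mean weight, sign, selected; for X2
#' labels the metric and ROI are split out as extra columns.
#'
#' @param report a \linkS4class{StabilityReport}.
#' @param path output path.
#' @param x2Labels treat labels as X2 metric-ROI labels.
#' @return Invisibly, the path.
#' @export
writeStabilityReport <- function(report, path, x2Labels = FALSE) {
  tab <- report@table
  if (x2Labels) {
    parsed <- parseX2Labels(tab$label)
    tab$metric <- parsed$metric
    tab$roi <- parsed$roi
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Planted-feature recovery metrics for a synthetic cohort
#'
#' Compares a stability report's stable-feature list against the ground
#' truth of a \linkS4class{SyntheticCohort}.  Because all metric features of
#' a planted region are modulated by the same latent factor, the strength
#' and centrality features of one region are generator-collinear and an
#' embedded selector may stably retain either as the region's
#' representative; recovery is therefore assessed at the region level by
#' default (a selected feature counts as correct when its region is
#' planted, and a planted region counts as recovered when any of its metric
#' features is selected).  \code{level = "label"} scores exact feature-label
#' matches instead.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param report an X2 \linkS4class{StabilityReport} after
#'   \code{\link{selectStable}}.
#' @param level "roi" (default) or "label".
#' @return List with precision, recall, signAgreement (fraction of recovered
#'   planted regions/labels whose reported sign matches the planted sign),
#'   and the selected and planted label sets.
#' @export
recoveryMetrics <- function(cohort, report, level = c("roi", "label")) {
  level <- match.arg(level)
  planted <- plantedFeatures(cohort)
  tab <- stabilityTable(report)
  sel <- tab[tab$selected, , drop = FALSE]
  plantedSigns <- setNames(planted$sign, parseX2Labels(planted$label)$roi)
  if (level == "label") {
    tp <- intersect(sel$label, planted$label)
    precision <- if (nrow(sel)) length(tp) / nrow(sel) else NA_real_
    recall <- length(tp) / nrow(planted)
    signs <- vapply(tp, function(l)
      (sel$sign[sel$label == l] == "positive") ==
        (planted$sign[planted$label == l] > 0), logical(1))
  } else {
    selRois <- parseX2Labels(sel$label)$roi
    plantedRois <- names(plantedSigns)
    precision <- if (nrow(sel)) mean(selRois %in% plantedRois) else NA_real_
    recovered <- intersect(plantedRois, selRois)
    recall <- length(recovered) / length(plantedRois)
    signs <- vapply(recovered, function(roi) {
      s <- sel$sign[selRois == roi]
      all((s == "positive") == (plantedSigns[roi] > 0))
    }, logical(1))
  }
  list(precision = precision, recall = recall,
       signAgreement = if (length(signs)) mean(signs) else NA_real_,
       selected = sel$label, planted = planted$label)
}
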
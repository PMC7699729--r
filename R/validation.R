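#' Fit a univariate Gaussian mixture by EM
#'
#' Expectation-maximization with k-means++-style seeded initialization,
#' \code{nStarts} restarts (best final log-likelihood wins), a variance floor
#' of \code{1e-6 * var(z)} against component collapse, and convergence when
#' the relative log-likelihood change drops below \code{tol} or
#' \code{maxIter} iterations are reached.  The log-likelihood trace of the
#' winning restart is stored and is checked to be non-decreasing.
#'
#' @param z numeric score vector.
#' @param nComponents number of mixture components.
#' @param seed RNG seed; the fit is deterministic given the seed.
#' @param nStarts number of EM restarts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations per restart.
#' @return A \linkS4class{GmmFit}.
#' @examples
#' z <- c(rnorm(50, -3), rnorm(50, 3))
#' fitGmm1d(z, 2, seed = 1)
#' @export
fitGmm1d <- function(z, nComponents, seed = 1L, nStarts = 10L, tol = 1e-8,
                     maxIter = 500L) {
  k <- as.integer(nComponents)
  if (k < 1L) stop("nComponents must be >= 1")
  if (length(z) <= k) stop("need more observations than components")
  if (length(unique(z)) < k)
    stop("nComponents exceeds the number of distinct values")
  vz <- var(z)
  floorVar <- max(1e-6 * vz, 1e-12)

  emOnce <- function(mu0) {
    w <- rep(1 / k, k); mu <- mu0; v <- rep(max(vz, floorVar), k)
    ll <- -Inf; trace <- numeric(0)
    for (it in seq_len(maxIter)) {
      dens <- vapply(seq_len(k), function(j)
        w[j] * dnorm(z, mu[j], sqrt(v[j])), numeric(length(z)))
      rowsum <- rowSums(dens)
      rowsum[rowsum == 0] <- .Machine$double.xmin
      newll <- sum(log(rowsum))
      trace <- c(trace, newll)
      resp <- dens / rowsum
      nk <- colSums(resp)
      nk[nk == 0] <- .Machine$double.xmin
      w <- nk / length(z)
      mu <- colSums(resp * z) / nk
      v <- pmax(colSums(resp * (outer(z, mu, "-")^2)) / nk, floorVar)
      if (is.finite(ll) && abs(newll - ll) <= tol * abs(newll)) {
        ll <- newll
        break
      }
      ll <- newll
    }
    list(w = w, mu = mu, v = v, ll = ll, trace = trace)
  }

  best <- NULL
  withSeed(seed, {
    for (s in seq_len(nStarts)) {
      # k-means++-style spread-out initial means
      mu0 <- numeric(k)
      mu0[1L] <- z[sample.int(length(z), 1L)]
      if (k > 1L) for (j in 2:k) {
        d2 <- vapply(z, function(x) min((x - mu0[seq_len(j - 1L)])^2),
                     numeric(1))
        if (sum(d2) == 0) mu0[j] <- z[sample.int(length(z), 1L)]
        else mu0[j] <- z[sample.int(length(z), 1L, prob = d2)]
      }
      fit <- emOnce(mu0)
      if (is.null(best) || fit$ll > best$ll) best <- fit
    }
  })
  if (any(diff(best$trace) < -1e-6 * (1 + abs(best$ll))))
    stop("EM log-likelihood decreased; this indicates a numerical fault")
  dens <- vapply(seq_len(k), function(j)
    best$w[j] * dnorm(z, best$mu[j], sqrt(best$v[j])), numeric(length(z)))
  labels <- max.col(dens, ties.method = "first")
  ord <- order(best$mu)
  relabel <- match(seq_len(k), ord)
  new("GmmFit", weights = best$w[ord], means = best$mu[ord],
      variances = best$v[ord], labels = as.integer(relabel[labels]),
      logLik = best$ll, trace = best$trace)
}

#' Choose the number of mixture components by BIC
#'
#' Fits 1..\code{kMax} component mixtures and returns the component count
#' minimizing BIC = -2 logLik + (3k - 1) log n.
#'
#' @param z numeric score vector.
#' @param kMax largest component count to consider.
#' @param seed RNG seed.
#' @param ... passed to \code{\link{fitGmm1d}}.
#' @return Integer component count.
#' @export
selectNComponents <- function(z, kMax = 4L, seed = 1L, ...) {
  kMax <- as.integer(kMax)
  if (kMax < 1L) stop("kMax must be >= 1")
  seeds <- childSeeds(seed, kMax)
  bic <- vapply(seq_len(kMax), function(k) {
    fit <- tryCatch(fitGmm1d(z, k, seed = seeds[k], ...),
                    error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    -2 * fit@logLik + (3 * k - 1) * log(length(z))
  }, numeric(1))
  which.min(bic)
}

#' Normalized mutual information between two partitions
#'
#' \eqn{NMI = I(a; b) / g(H(a), H(b))} with natural logarithms, where g is
#' the arithmetic mean by default ("mean"), or min/geometric/max.  If either
#' partition has zero entropy the value is 1 when both are constant and 0
#' otherwise.
#'
#' @param a,b equal-length partition vectors (any label type).
#' @param normalization entropy normalization: "mean", "min", "geometric" or
#'   "max".
#' @return NMI in [0, 1].
#' @examples
#' nmiPartition(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' @export
nmiPartition <- function(a, b, normalization = c("mean", "min", "geometric",
                                                 "max")) {
  normalization <- match.arg(normalization)
  if (length(a) != length(b)) stop("partitions must have equal length")
  n <- length(a)
  tab <- table(a, b)
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  ha <- -sum(ifelse(pi > 0, pi * log(pi), 0))
  hb <- -sum(ifelse(pj > 0, pj * log(pj), 0))
  if (ha == 0 || hb == 0) return(if (ha == 0 && hb == 0) 1 else 0)
  mi <- sum(ifelse(pij > 0, pij * log(pij / outer(pi, pj)), 0))
  denom <- switch(normalization, mean = (ha + hb) / 2, min = min(ha, hb),
                  geometric = sqrt(ha * hb), max = max(ha, hb))
  min(max(mi / denom, 0), 1)
}

#' Permutation test for cluster-diagnosis overlap
#'
#' Builds a null NMI distribution by permuting the diagnostic labels
#' \code{nPerm} times and counts how often the permuted NMI reaches the
#' observed one; the p-value is \code{#(null >= observed) / nPerm}
#' (the >= counter is the conservative reading of "greater than"; ties have
#' measure zero for a continuous statistic).
#'
#' @param clusters cluster assignment (e.g. from \code{\link{fitGmm1d}}).
#' @param labels diagnostic labels.
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @param gmm optional \linkS4class{GmmFit} to attach to the report.
#' @param normalization passed to \code{\link{nmiPartition}}.
#' @return A \linkS4class{ClusterValidation}.
#' @export
permutationTestNmi <- function(clusters, labels, nPerm = 10000L, seed = 1L,
                               gmm = NULL, normalization = "mean") {
  if (nPerm < 1L) stop("nPerm must be >= 1")
  obs <- nmiPartition(clusters, labels, normalization)
  nullNmi <- withSeed(seed, vapply(seq_len(nPerm), function(i)
    nmiPartition(clusters, sample(labels), normalization), numeric(1)))
  if (is.null(gmm))
    gmm <- new("GmmFit", weights = 1, means = 0, variances = 1,
               labels = integer(0), logLik = NA_real_, trace = numeric(0))
  new("ClusterValidation", clusterLabels = as.integer(factor(clusters)),
      nComponents = length(unique(clusters)), nmi = obs, nullNmi = nullNmi,
      pValue = mean(nullNmi >= obs), gmm = gmm)
}

#' Validate a score vector against diagnostic labels
#'
#' Convenience wrapper: GMM clustering of the score, then the NMI
#' permutation test against the labels.
#'
#' @param z score vector.
#' @param labels diagnostic labels.
#' @param nComponents mixture components (default 3, one per clinical group);
#'   use \code{\link{selectNComponents}} for a BIC-driven choice.
#' @param nPerm permutations for the null.
#' @param seed RNG seed.
#' @param normalization NMI normalization.
#' @return A \linkS4class{ClusterValidation}.
#' @export
validateScore <- function(z, labels, nComponents = 3L, nPerm = 1000L,
                          seed = 1L, normalization = "mean") {
  seeds <- childSeeds(seed, 2L)
  gmm <- fitGmm1d(z, nComponents, seed = seeds[1L])
  out <- permutationTestNmi(gmm@labels, labels, nPerm = nPerm,
                            seed = seeds[2L], gmm = gmm,
                            normalization = normalization)
  out@nComponents <- as.integer(nComponents)
  out
}
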
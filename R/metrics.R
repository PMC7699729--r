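#' Node strength
#'
#' The weighted degree of every region: \eqn{s_i = \sum_j w_{ij}}.
#'
#' @param c a \linkS4class{ConnectivityMatrix}.
#' @return Named numeric vector of strengths, one per region.
#' @examples
#' w <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
#' nodeStrength(connectivityMatrix(w))
#' @export
nodeStrength <- function(c) {
  checkConnectivity(c)
  setNames(rowSums(c@weights), c@roiLabels)
}

#' Eigenvector centrality
#'
#' The Perron eigenpair of the weighted adjacency matrix: the non-negative,
#' unit-Euclidean-norm vector \eqn{eig} with \eqn{W \cdot eig = \Lambda \cdot
#' eig}, \eqn{\Lambda} the largest eigenvalue.  Computed by power iteration
#' and invariant to positive rescaling of the weights.
#'
#' If the graph is disconnected the eigenpair of the full matrix is still
#' returned (supported on the dominant component) with a warning.
#'
#' @param c a \linkS4class{ConnectivityMatrix}.
#' @param tol convergence tolerance on the residual
#'   \eqn{\max_i |(W eig)_i - \Lambda eig_i|}.
#' @param maxIter maximum number of power iterations.
#' @return List with components \code{vector} (named centralities) and
#'   \code{lambda} (the leading eigenvalue).
#' @examples
#' w <- matrix(c(0, 1, 1, 0), 2)
#' eigenvectorCentrality(connectivityMatrix(w))
#' @export
eigenvectorCentrality <- function(c, tol = 1e-10, maxIter = 1000L) {
  checkConnectivity(c)
  w <- c@weights
  if (all(w == 0))
    stop("eigenvector centrality is undefined for an empty graph")
  if (!isConnected(w))
    warning("graph is disconnected; centrality computed on the full matrix ",
            "is supported on the dominant component")
  n <- nrow(w)
  v <- rep(1 / sqrt(n), n)
  # Shifted iteration on W + sI: same Perron vector, but the dominant
  # eigenvalue is strictly largest in magnitude even for bipartite graphs
  # (where lambda and -lambda tie and plain power iteration oscillates).
  s <- max(rowSums(w))
  lambda <- 0
  for (it in seq_len(maxIter)) {
    wv <- drop(w %*% v) + s * v
    nrm <- sqrt(sum(wv^2))
    if (nrm == 0) stop("power iteration collapsed to the zero vector")
    v <- wv / nrm
    lambda <- drop(crossprod(v, w %*% v))
    if (max(abs(w %*% v - lambda * v)) <= tol) break
  }
  if (max(abs(w %*% v - lambda * v)) > tol)
    warning("power iteration did not reach tol = ", tol, " in ", maxIter,
            " iterations")
  if (sum(v) < 0) v <- -v
  v[abs(v) < 1e-14] <- 0
  list(vector = setNames(v, c@roiLabels), lambda = lambda)
}

# Connectivity of the nonzero pattern via breadth-first search.
isConnected <- function(w) {
  n <- nrow(w)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- which(w[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Weighted local efficiency
#'
#' For each region \eqn{i} with neighbour set \eqn{G_i} of size \eqn{n_i}:
#' \deqn{E(G_i) = \frac{1}{n_i (n_i - 1)} \sum_{j \ne k \in G_i} 1 / d(j, k)}
#' where \eqn{d} is the shortest-path length within the subgraph induced by
#' \eqn{G_i}.  By default (the Brain Connectivity Toolbox convention) link
#' lengths are inverse normalized weights \eqn{1 / (w / w_{max})}, which keeps
#' every efficiency in \eqn{[0, 1]}; \code{lengths = "raw"} instead treats the
#' weights themselves as lengths (the literal minimize-the-sum-of-weights
#' reading), in which case the \eqn{[0, 1]} bound no longer applies.
#' Disconnected neighbour pairs contribute 0 and regions with fewer than two
#' neighbours get efficiency 0.
#'
#' @param c a \linkS4class{ConnectivityMatrix}.
#' @param lengths "inverse" (default) or "raw" link-length convention.
#' @return Named numeric vector of local efficiencies.
#' @examples
#' w <- matrix(1, 3, 3); diag(w) <- 0
#' localEfficiency(connectivityMatrix(w))  # complete triangle: all 1
#' @export
localEfficiency <- function(c, lengths = c("inverse", "raw")) {
  checkConnectivity(c)
  lengths <- match.arg(lengths)
  e <- .localEfficiencyCpp(c@weights, lengths == "inverse")
  setNames(e, c@roiLabels)
}

#' Per-region metric table for one subject
#'
#' @param c a \linkS4class{ConnectivityMatrix}.
#' @param lengths link-length convention for \code{\link{localEfficiency}}.
#' @return data.frame with columns roi, strength, eigCentrality,
#'   localEfficiency, plus attribute \code{"lambda"} (leading eigenvalue).
#' @export
nodeMetricTable <- function(c, lengths = "inverse") {
  ec <- eigenvectorCentrality(c)
  out <- data.frame(roi = c@roiLabels,
                    strength = unname(nodeStrength(c)),
                    eigCentrality = unname(ec$vector),
                    localEfficiency = unname(localEfficiency(c, lengths)),
                    stringsAsFactors = FALSE)
  attr(out, "lambda") <- ec$lambda
  out
}
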
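# Independent brute-force oracles and small fixtures, kept deliberately
# separate from the package's implementations.

# random symmetric non-negative weighted graph; guarantees at least one edge
randomGraph <- function(n, density = 0.6, maxw = 5) {
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    vals <- ifelse(runif(sum(ut)) < density, sample(1:maxw, sum(ut),
                                                    replace = TRUE), 0)
    w[ut] <- vals
    w <- w + t(w)
    if (any(w > 0)) return(w)
  }
}

# graph with a guaranteed connected nonzero pattern (spanning path added)
randomConnectedGraph <- function(n, density = 0.5, maxw = 5) {
  w <- randomGraph(n, density, maxw)
  for (i in seq_len(n - 1)) if (w[i, i + 1] == 0) w[i, i + 1] <- w[i + 1, i] <- 1
  w
}

# strength by explicit double loop
oracleStrength <- function(w) {
  n <- nrow(w)
  s <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) s[i] <- s[i] + w[i, j]
  s
}

# Perron eigenpair from a dense eigendecomposition
oracleEig <- function(w) {
  e <- eigen(w, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  if (sum(v) < 0) v <- -v
  list(vector = v, lambda = max(e$values))
}

# local efficiency by explicit neighbour-pair enumeration with shortest
# paths from e1071::allShortestPaths (Floyd-Warshall, independent codebase)
oracleLocalEfficiency <- function(w) {
  n <- nrow(w)
  wmax <- max(w)
  out <- numeric(n)
  if (wmax == 0) return(out)
  for (i in seq_len(n)) {
    nb <- setdiff(which(w[i, ] > 0), i)
    k <- length(nb)
    if (k < 2) next
    len <- matrix(NA_real_, k, k)
    for (a in seq_len(k)) for (b in seq_len(k))
      if (a != b && w[nb[a], nb[b]] > 0) len[a, b] <- wmax / w[nb[a], nb[b]]
    d <- e1071::allShortestPaths(len)$length
    acc <- 0
    for (a in seq_len(k)) for (b in seq_len(k))
      if (a != b && is.finite(d[a, b]) && !is.na(d[a, b]))
        acc <- acc + 1 / d[a, b]
    out[i] <- acc / (k * (k - 1))
  }
  out
}

# a small default-structure cohort config for fast tests
smallConfig <- function(seed, ...) {
  args <- list(n_nc = 12L, n_mci = 20L, n_ad = 10L, n_rois = 24L,
               base_density = 0.6, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(syntheticConfig, args)
}

# shared full-size cohorts/features across acceptance blocks (built lazily)
.fixtureCache <- new.env(parent = emptyenv())
cachedCohort <- function(seed, config = syntheticConfig(seed = seed)) {
  key <- paste0("cohort", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateCohort(config)
  .fixtureCache[[key]]
}
cachedFeatures <- function(seed, variant) {
  key <- paste0(variant, seed)
  if (is.null(.fixtureCache[[key]])) {
    ds <- cachedCohort(seed)@dataset
    .fixtureCache[[key]] <- if (variant == "X1") buildX1(ds) else buildX2(ds)
  }
  .fixtureCache[[key]]
}
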
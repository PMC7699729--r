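# Internal helpers: seeded evaluation and input checks.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so package functions never perturb it.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive reproducible child seeds from a master seed; values stay < 2^31.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max, n))
}

checkConnectivity <- function(c) {
  validObject(c)
  invisible(c)
}

# Stratified assignment of fold ids 1..k within each level of `strata`;
# falls back to unstratified assignment (with a warning) when a stratum is
# smaller than k.
foldAssignment <- function(strata, k) {
  n <- length(strata)
  fold <- integer(n)
  if (any(table(strata) < k)) {
    warning("a diagnostic group is smaller than k; using unstratified folds")
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    for (g in unique(strata)) {
      idx <- which(strata == g)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  fold
}
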
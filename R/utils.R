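# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin, so fold class counts differ by at most one.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(vapply(split(y, fold), function(v) length(unique(v)), 1L) < 2L)) {
    stop("a fold contains a single class; too few cases per class for ", k,
         " folds")
  }
  fold
}

# Stratified subset of approximately `fraction` of the cases.
stratified_subset <- function(y, fraction) {
  keep <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n <- max(1L, round(fraction * length(idx)))
    keep <- c(keep, idx[sample.int(length(idx))][seq_len(n)])
  }
  sort(keep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
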
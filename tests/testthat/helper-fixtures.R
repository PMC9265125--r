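# Fixtures built in code: small quantized VOIs, planted feature tables and
# paper-sized synthetic splits.

# A quantized_voi constructed directly from a 3D level array (0 = outside).
qvoi_from_array <- function(lev, nbins, spacing = c(1, 1, 1)) {
  idx <- which(lev > 0)
  structure(
    list(levels = as.integer(lev[idx]), idx0 = idx - 1L, dims = dim(lev),
         n_bins = as.integer(nbins), spacing = spacing),
    class = "quantized_voi"
  )
}

# Random blob-shaped VOI with random levels inside a small grid.
random_level_array <- function(seed, side = 5, nbins = 8, fill = 0.7) {
  set.seed(seed)
  dims <- rep(side, 3)
  lev <- array(0L, dims)
  voi <- array(runif(prod(dims)) < fill, dims)
  if (!any(voi)) voi[sample(prod(dims), 3)] <- TRUE
  lev[voi] <- sample.int(nbins, sum(voi), replace = TRUE)
  lev
}

# Feature table with one informative column among noise, named with valid
# sequence tokens so selection can group by sequence.
planted_table <- function(seed, n = 50, p = 50, informative = min(7, p),
                          beta = 1, noise = 0.3, sequence = "GD") {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  for (j in informative) X[, j] <- beta * y + rnorm(n, sd = noise)
  colnames(X) <- sprintf("-_%s_original_INT_f%03d", sequence, seq_len(p))
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  list(X = X, y = y, informative = colnames(X)[informative])
}

# Clinical-scale split: 27/20 training cases and 5/5 validation cases.
study_split <- function(seed, effect_size = 2, n0 = 27, n1 = 20,
                        n_val_per_class = 5, ...) {
  tr_all <- generate_cohort(cohort_config(
    n_cases_per_class = max(n0, n1), effect_size = effect_size,
    seed = seed, ...))
  nmax <- max(n0, n1)
  tr <- tr_all[c(seq_len(n0), nmax + seq_len(n1))]
  va <- generate_cohort(cohort_config(
    n_cases_per_class = n_val_per_class, effect_size = effect_size,
    seed = seed + 50000L, ...))
  va <- lapply(va, function(cs) {
    cs$case_id <- paste0("val_", cs$case_id)
    cs
  })
  list(train = tr, validation = va)
}

ball_mask <- function(r, spacing = c(1, 1, 1), margin = 2) {
  half <- ceiling(r / spacing) + margin
  dims <- 2 * half + 1
  ctr <- half + 1
  x <- (seq_len(dims[1]) - ctr[1]) * spacing[1]
  y <- (seq_len(dims[2]) - ctr[2]) * spacing[2]
  z <- (seq_len(dims[3]) - ctr[3]) * spacing[3]
  arr <- outer(outer(x^2, y^2, `+`), z^2, `+`) <= r^2
  voi_mask(arr, spacing)
}

volume_from_array <- function(values, spacing = c(1, 1, 1)) {
  volume_image(values, spacing)
}
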
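# Per-case feature assembly and z-score normalization. One sequence yields
# 2438 features (8 morphology + 9 images x (18 intensity + 20 histogram) +
# 9 images x 4 bin settings x 58 texture); a case with both sequences
# carries 2438 x 2 = 4876.

extract_sequence <- function(volume, mask, sequence, morph = NULL) {
  check_same_grid(volume, mask)
  idx <- which(mask$values)
  if (length(idx) == 0L) stop("empty VOI")
  idx0 <- idx - 1L
  dims <- dim(volume$values)
  # same filter bank as wavelet_decompose(), but only the within-VOI values
  # of each subband are needed here
  flt <- coif1_filters()
  if (any(dims < length(flt$lo))) {
    stop("volume too small for the Coiflet-1 filter support (6 taps)")
  }
  wd <- cpp_wavelet8(volume$values, dims, flt$lo, flt$hi,
                     (length(flt$lo) %/% 2L) - 1L)
  voi_values <- list(original = volume$values[idx])
  wavelet_cols <- c(LLL = 1L, HLL = 2L, LHL = 3L, HHL = 4L,
                    LLH = 5L, HLH = 6L, LHH = 7L, HHH = 8L)
  for (lab in names(wavelet_cols)) {
    voi_values[[lab]] <- wd[idx, wavelet_cols[[lab]]]
  }

  out <- numeric(0)
  out <- c(out, unname(morph %||% morphology_features(mask)))
  for (sb in SUBBAND_LABELS) {
    out <- c(out, intensity_features_values(voi_values[[sb]]))
  }
  for (sb in SUBBAND_LABELS) {
    out <- c(out, histogram_features_levels(quantize_values(voi_values[[sb]], 64L), 64L))
  }
  for (sb in SUBBAND_LABELS) {
    out <- c(out, as.vector(
      cpp_texture_features_multi(voi_values[[sb]], idx0, dims, TEXTURE_BINS)))
  }
  names(out) <- feature_names(sequence)
  out
}

#' Extract the full radiomic feature vector of one case
#'
#' Runs the complete extraction for both sequences: wavelet decomposition,
#' morphology (once per sequence, from the shared mask), intensity and
#' 64-level histogram features per image, and all five texture families per
#' image and bin setting (16/32/64/128). Deterministic; column order is
#' fixed by the registry.
#'
#' @param case a list with `volumes` (named list of `GD`/`T2`
#'   [volume_image()]s) and `mask`, as produced by [generate_cohort()] or
#'   [load_case()].
#' @return Named numeric vector of 4876 features (2438 per sequence).
#' @export
extract_case <- function(case) {
  res <- tryCatch(
    {
      morph <- morphology_features(case$mask)  # shared mask: compute once
      c(extract_sequence(case$volumes$GD, case$mask, "GD", morph),
        extract_sequence(case$volumes$T2, case$mask, "T2", morph))
    },
    error = function(e) {
      stop("feature extraction failed for case '", case$case_id %||% "?",
           "': ", conditionMessage(e))
    }
  )
  if (!all(is.finite(res))) {
    stop("non-finite feature values for case '", case$case_id %||% "?", "'")
  }
  res
}

#' Extract a feature table for a whole cohort
#'
#' @param cases list of cases ([generate_cohort()] / [read_cohort()]).
#' @return A data frame: `case_id`, `label`, then 4876 feature columns in
#'   registry order.
#' @export
extract_cohort <- function(cases) {
  feats <- lapply(cases, extract_case)
  tab <- do.call(rbind, feats)
  out <- data.frame(
    case_id = vapply(cases, function(c) as.character(c$case_id), ""),
    label = vapply(cases, function(c) as.numeric(c$label), 0),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(tab, check.names = FALSE))
  rownames(out) <- NULL
  out
}

# Numeric feature matrix of a feature table (drops case_id/label).
feature_matrix <- function(table) {
  cols <- setdiff(colnames(table), c("case_id", "label"))
  as.matrix(table[, cols, drop = FALSE])
}

#' Fit a z-score normalization on a training feature matrix
#'
#' Column means and sample (N-1) standard deviations are computed on the
#' training rows only; constant columns are flagged and later mapped to 0.
#'
#' @param x numeric matrix (rows = cases).
#' @return list with `center`, `scale` and logical `constant`.
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("z-score normalization needs at least 2 training rows")
  n <- nrow(x)
  center <- colMeans(x)
  scale <- sqrt(pmax(colSums(x^2) - n * center^2, 0) / (n - 1))
  constant <- scale < 1e-12 * pmax(abs(center), 1)
  list(center = center, scale = scale, constant = constant)
}

#' Apply a fitted z-score normalization
#'
#' @param fit result of [zscore_fit()].
#' @param x matrix with the same columns as the training matrix.
#' @return The normalized matrix; constant training columns become 0.
#' @export
zscore_apply <- function(fit, x) {
  x <- as.matrix(x)
  s <- ifelse(fit$constant, 1, fit$scale)
  out <- sweep(sweep(x, 2, fit$center, "-"), 2, s, "/")
  if (any(fit$constant)) out[, fit$constant] <- 0
  out
}

#' Fit on a training table and normalize it together with other tables
#'
#' @param train training feature matrix.
#' @param ... further matrices (e.g. a validation table) normalized with the
#'   training statistics.
#' @return list with `train`, `others` (list), `center`, `scale`,
#'   `constant`.
#' @export
zscore_fit_apply <- function(train, ...) {
  fit <- zscore_fit(train)
  others <- lapply(list(...), function(x) zscore_apply(fit, x))
  c(list(train = zscore_apply(fit, train), others = others), fit)
}
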
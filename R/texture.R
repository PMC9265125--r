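# Texture-matrix features. Matrix construction and the feature formulas run
# in C++ (src/texture.cpp); this file provides the user-facing surface. All
# five families use the 26-neighborhood at Chebyshev distance 1 and merge
# counts over the 13 unique 3D directions before normalization (one matrix
# per family, not per-direction averaging). Features with a variance
# denominator return 0 on a constant VOI.

texture_feature_order <- function() {
  reg <- feature_registry()
  unlist(lapply(TEXTURE_FAMILIES, function(f) paste0(f, "_", reg$families[[f]])),
         use.names = FALSE)
}

#' All 58 texture features of a quantized VOI
#'
#' Computes 11 GLCM, 13 GLRLM, 13 GLSZM, 16 NGLDM and 5 NGTDM features from
#' one quantized VOI in a single pass.
#'
#' @param q a [quantize()]d VOI.
#' @return Named numeric vector of 58 features, names prefixed with the
#'   family (`GLCM_...`, `GLRLM_...`, ...).
#' @export
texture_features <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  out <- cpp_texture_features(q$levels, q$idx0, q$dims, q$n_bins)
  names(out) <- texture_feature_order()
  out
}

#' Raw texture matrices of a quantized VOI
#'
#' Mostly useful for inspection and testing: GLCM pair counts (symmetric,
#' unnormalized), GLRLM run counts (level x run length), GLSZM zone counts
#' (level x zone size, 26-connected zones), NGLDM dependence counts
#' (level x dependence+1, dependence threshold alpha = 0) and the NGTDM
#' occurrence counts `n_i` and absolute-difference sums `s_i`.
#'
#' @param q a [quantize()]d VOI.
#' @return list with `glcm_counts`, `glrlm`, `glszm`, `ngldm`, `ngtdm_n`,
#'   `ngtdm_s`.
#' @export
texture_matrices <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  cpp_texture_matrices(q$levels, q$idx0, q$dims, q$n_bins)
}

family_features <- function(q, family) {
  reg <- feature_registry()
  all <- texture_features(q)
  out <- all[paste0(family, "_", reg$families[[family]])]
  names(out) <- reg$families[[family]]
  out
}

#' Gray-level co-occurrence features
#'
#' Co-occurrence counts are summed over all 13 unique direction vectors at
#' Chebyshev distance 1 in both orientations (symmetric matrix), restricted
#' to voxel pairs inside the VOI, and normalized once. Correlation of a
#' constant VOI is defined as 0.
#'
#' @param q a [quantize()]d VOI with at least 2 voxels.
#' @return Named numeric vector of 11 GLCM features.
#' @export
glcm_features <- function(q) {
  if (length(q$levels) < 2L) stop("GLCM needs a VOI with at least 2 voxels")
  family_features(q, "GLCM")
}

#' Gray-level run-length features
#'
#' Maximal equal-level runs per direction, counts merged over the 13
#' directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 13 GLRLM features.
#' @export
glrlm_features <- function(q) family_features(q, "GLRLM")

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal level within the VOI; the
#' matrix is direction-free.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 13 GLSZM features.
#' @export
glszm_features <- function(q) family_features(q, "GLSZM")

#' Neighboring gray-level dependence features
#'
#' Dependence of a voxel = number of its 26-neighbors inside the VOI with
#' identical level (threshold alpha = 0); the matrix is indexed by
#' (level, dependence + 1).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 NGLDM features.
#' @export
ngldm_features <- function(q) family_features(q, "NGLDM")

#' Neighborhood gray-tone difference features
#'
#' `s_i` sums, over VOI voxels of level i, the absolute difference between i
#' and the mean level of the voxel's in-VOI 26-neighborhood; voxels with no
#' in-VOI neighbor are excluded. The coarseness denominator is guarded with
#' epsilon = 1e-6 when `sum(p_i * s_i)` is 0.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of the 5 NGTDM features (coarseness,
#'   contrast, busyness, complexity, strength).
#' @export
ngtdm_features <- function(q) family_features(q, "NGTDM")
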
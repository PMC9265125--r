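# Single-level undecimated 3D wavelet decomposition with the orthonormal
# Coiflet-1 analysis filter bank. The transform is stationary (no
# decimation) so every subband stays voxel-aligned with the VOI mask, which
# is what allows the same mask to be applied to all 9 images. Boundary
# handling is half-sample symmetric (mirror) padding.

# Orthonormal Coiflet-1 analysis filters (6 taps). The high-pass is the
# quadrature mirror of the low-pass: g[k] = (-1)^k h[L-1-k].
coif1_filters <- function() {
  lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
          0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
  hi <- rev(lo) * c(1, -1, 1, -1, 1, -1)
  list(lo = lo, hi = hi)
}

#' Undecimated single-level Coiflet-1 wavelet decomposition
#'
#' Applies the Coiflet-1 low-pass (L) and high-pass (H) analysis filters
#' separably along x, y and z in all 8 combinations. Outputs keep the input
#' grid (undecimated), so subbands remain aligned with the VOI mask. Subband
#' labels read in axis order (x, y, z): "HLL" is high-pass along x, low-pass
#' along y and z.
#'
#' @param volume a [volume_image()]; every dimension must be at least the
#'   filter length (6).
#' @return A named list of 9 [volume_image()]s: `original`, `LLL`, `HLL`,
#'   `LHL`, `LLH`, `HHL`, `HLH`, `LHH`, `HHH`.
#' @export
wavelet_decompose <- function(volume) {
  stopifnot(inherits(volume, "volume_image"))
  dims <- dim(volume$values)
  flt <- coif1_filters()
  if (any(dims < length(flt$lo))) {
    stop("volume too small for the Coiflet-1 filter support (6 taps)")
  }
  offset <- (length(flt$lo) %/% 2L) - 1L  # center the 6-tap filter
  wd <- cpp_wavelet8(volume$values, dims, flt$lo, flt$hi, offset)
  cols <- c(LLL = 1L, HLL = 2L, LHL = 3L, HHL = 4L,
            LLH = 5L, HLH = 6L, LHH = 7L, HHH = 8L)
  out <- list(original = volume)
  for (lab in c("LLL", "HLL", "LHL", "LLH", "HHL", "HLH", "LHH", "HHH")) {
    out[[lab]] <- volume_image(array(wd[, cols[[lab]]], dim = dims),
                               spacing = volume$spacing, origin = volume$origin)
  }
  out
}
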
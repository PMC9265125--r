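# Fixed-bin-number discretization of within-VOI intensities. The
# quantization range is the within-VOI min/max of the given image, computed
# independently per image (each wavelet subband has its own unrelated
# dynamic range). This makes every downstream texture and histogram feature
# invariant to affine rescaling of the source intensities.

quantize_values <- function(x, n_bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep.int(1L, length(x)))
  lev <- floor(n_bins * (x - rng[1]) / (rng[2] - rng[1])) + 1
  as.integer(pmin(lev, n_bins))  # the maximum maps to n_bins, not n_bins+1
}

#' Quantize within-VOI intensities to a fixed number of gray levels
#'
#' Level = `floor(n_bins * (x - min) / (max - min)) + 1`, with the maximum
#' clamped to level `n_bins`. A constant region maps every voxel to level 1.
#'
#' @param volume a [volume_image()] (typically one wavelet subband).
#' @param mask the [voi_mask()] aligned with it.
#' @param n_bins number of gray levels; texture features use 16/32/64/128,
#'   histogram features always 64.
#' @return A `quantized_voi`: integer `levels` per VOI voxel, the 0-based
#'   linear voxel indices `idx0`, grid `dims`, `n_bins` and `spacing`.
#' @export
quantize <- function(volume, mask, n_bins) {
  stopifnot(inherits(volume, "volume_image"), inherits(mask, "voi_mask"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  check_same_grid(volume, mask)
  idx <- which(mask$values)
  structure(
    list(levels = quantize_values(volume$values[idx], n_bins),
         idx0 = idx - 1L,
         dims = dim(volume$values),
         n_bins = n_bins,
         spacing = volume$spacing),
    class = "quantized_voi"
  )
}
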
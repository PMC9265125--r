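# The feature registry fixes the identity, order and count of every feature
# family. Counts are enforced at load time: 8 morphology, 18 intensity, 20
# histogram, 11 GLCM, 13 GLRLM, 13 GLSZM, 16 NGLDM, 5 NGTDM.

REGISTRY_COUNTS <- c(MORPH = 8L, INT = 18L, HIST = 20L, GLCM = 11L,
                     GLRLM = 13L, GLSZM = 13L, NGLDM = 16L, NGTDM = 5L)
TEXTURE_FAMILIES <- c("GLCM", "GLRLM", "GLSZM", "NGLDM", "NGTDM")
SUBBAND_LABELS <- c("original", "LLL", "HLL", "LHL", "LLH",
                    "HHL", "HLH", "LHH", "HHH")
TEXTURE_BINS <- c(16L, 32L, 64L, 128L)

.registry_cache <- new.env(parent = emptyenv())

#' The canonical feature registry
#'
#' Loads the versioned registry shipped with the package and validates the
#' per-family feature counts; extraction refuses to run on a registry whose
#' counts are not 8/18/20/11/13/13/16/5.
#'
#' @return list with `version` and `families` (named list of ordered
#'   feature-name vectors).
#' @export
feature_registry <- function() {
  if (!is.null(.registry_cache$registry)) return(.registry_cache$registry)
  path <- system.file("extdata", "feature_registry.yaml", package = "radvox")
  reg <- yaml::read_yaml(path)
  counts <- vapply(reg$families, length, 1L)
  if (!identical(counts[names(REGISTRY_COUNTS)], REGISTRY_COUNTS)) {
    stop("feature registry counts do not match the required ",
         paste(REGISTRY_COUNTS, collapse = "/"), " layout")
  }
  .registry_cache$registry <- reg
  reg
}

# "bit" token: log2 of the number of gray levels (16 -> "4bit").
bins_token <- function(n_bins) paste0(as.integer(log2(n_bins)), "bit")

#' Canonical feature names for one image sequence
#'
#' Names render as `{bins}_{sequence}_{subband}_{family}_{name}`, with the
#' bins token rendered `-` for intensity features (which need no
#' quantization) and `6bit` for histogram features (fixed 64 levels).
#' Morphology names are `MORPH_{sequence}_{name}`. One sequence carries
#' 8 + 9*(18 + 20) + 9*4*(11 + 13 + 13 + 16 + 5) = 2438 features.
#'
#' @param sequence `"GD"` or `"T2"`.
#' @return Character vector of 2438 feature names in extraction order.
#' @export
feature_names <- function(sequence) {
  key <- paste0("names_", sequence)
  if (!is.null(.registry_cache[[key]])) return(.registry_cache[[key]])
  reg <- feature_registry()
  nm <- character(0)
  nm <- c(nm, paste0("MORPH_", sequence, "_", reg$families$MORPH))
  for (sb in SUBBAND_LABELS) {
    nm <- c(nm, paste0("-_", sequence, "_", sb, "_INT_", reg$families$INT))
  }
  for (sb in SUBBAND_LABELS) {
    nm <- c(nm, paste0("6bit_", sequence, "_", sb, "_HIST_", reg$families$HIST))
  }
  for (sb in SUBBAND_LABELS) {
    for (nb in TEXTURE_BINS) {
      for (fam in TEXTURE_FAMILIES) {
        nm <- c(nm, paste0(bins_token(nb), "_", sequence, "_", sb, "_", fam,
                           "_", reg$families[[fam]]))
      }
    }
  }
  .registry_cache[[key]] <- nm
  nm
}

# Sequence token of a canonical feature name (second "_"-separated field).
feature_sequence <- function(names) {
  vapply(strsplit(names, "_", fixed = TRUE), `[`, "", 2L)
}
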
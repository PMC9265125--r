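# Seeded synthetic two-class cohorts of paired 3D volumes with ellipsoidal
# VOI masks. Classes differ in texture correlation length and mean intensity;
# a single effect-size knob interpolates both differences, so effect_size = 0
# makes the classes identically distributed.

#' Configuration for a synthetic two-class cohort
#'
#' Each case carries two sequence volumes ("GD", "T2") on the same grid and
#' one ellipsoidal VOI mask. Voxel intensities are a Gaussian-smoothed white
#' noise field (standardized to unit variance, correlation length
#' `texture_scale_by_class` in mm) plus a class mean shift plus independent
#' voxel noise. The class parameters actually used are interpolated towards
#' their midpoint by `effect_size`: `effect_size = 0` collapses both classes
#' onto the midpoint (identically distributed), `effect_size = 1` uses the
#' configured per-class values, larger values extrapolate.
#'
#' Defaults emulate a small skull base tumor cohort: 1 x 1 x 3 mm voxels
#' (slice thickness larger than in-plane resolution, as is typical for MRI),
#' and VOI radii of 8-14 mm giving ellipsoid volumes of roughly 2-11 cm^3.
#'
#' @param n_cases_per_class cases per class (label 0 = chordoma role,
#'   1 = chondrosarcoma role).
#' @param grid_shape 3 positive integers, voxels per axis.
#' @param voxel_spacing 3 positive reals, mm.
#' @param voi_radius_range positive pair, mm; per-axis ellipsoid radii are
#'   drawn uniformly from this range and must fit inside the grid.
#' @param effect_size non-negative interpolation factor described above.
#' @param texture_scale_by_class pair of Gaussian smoothing correlation
#'   lengths (mm), class 0 then class 1.
#' @param intensity_shift_by_class pair of mean shifts (arbitrary units).
#' @param noise_sd sd of the independent voxel noise.
#' @param seed integer RNG seed; cohorts are bit-reproducible per seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_cases_per_class = 20,
                          grid_shape = c(32, 32, 32),
                          voxel_spacing = c(1, 1, 3),
                          voi_radius_range = c(8, 14),
                          effect_size = 1,
                          texture_scale_by_class = c(4, 7),
                          intensity_shift_by_class = c(-0.5, 0.5),
                          noise_sd = 1,
                          seed = 1) {
  cfg <- list(n_cases_per_class = as.integer(n_cases_per_class),
              grid_shape = as.integer(grid_shape),
              voxel_spacing = as.numeric(voxel_spacing),
              voi_radius_range = as.numeric(voi_radius_range),
              effect_size = as.numeric(effect_size),
              texture_scale_by_class = as.numeric(texture_scale_by_class),
              intensity_shift_by_class = as.numeric(intensity_shift_by_class),
              noise_sd = as.numeric(noise_sd),
              seed = as.integer(seed))
  if (cfg$n_cases_per_class < 1L) stop("n_cases_per_class must be >= 1")
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 1L)) {
    stop("grid_shape must be 3 positive integers")
  }
  if (any(cfg$voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  if (length(cfg$voi_radius_range) != 2L || any(cfg$voi_radius_range <= 0) ||
      diff(cfg$voi_radius_range) < 0) {
    stop("voi_radius_range must be an increasing positive pair (mm)")
  }
  if (cfg$effect_size < 0) stop("effect_size must be non-negative")
  if (any(cfg$texture_scale_by_class <= 0)) stop("texture scales must be positive")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  extent <- cfg$grid_shape * cfg$voxel_spacing
  if (any(2 * cfg$voi_radius_range[2] > extent)) {
    stop("voi_radius_range maxima do not fit inside the grid extent (",
         paste(signif(extent, 4), collapse = " x "), " mm)")
  }
  class(cfg) <- "cohort_config"
  cfg
}

# Interpolate the two configured class values towards their midpoint.
effective_class_params <- function(cfg) {
  interp <- function(v) mean(v) + cfg$effect_size * (v - mean(v))
  list(texture_scale = interp(cfg$texture_scale_by_class),
       intensity_shift = interp(cfg$intensity_shift_by_class))
}

# Gaussian-smoothed standardized white noise field on the full grid.
smoothed_field <- function(grid_shape, spacing, sigma_mm) {
  field <- array(rnorm(prod(grid_shape)), dim = grid_shape)
  for (axis in 0:2) {
    sigma_vox <- sigma_mm / spacing[axis + 1]
    r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
    if (2L * r + 1L > grid_shape[axis + 1]) {
      r <- (grid_shape[axis + 1] - 1L) %/% 2L
    }
    taps <- dnorm(seq(-r, r), sd = sigma_vox)
    taps <- taps / sum(taps)
    field <- array(
      cpp_axis_convolve(field, dim(field), axis, taps, r),
      dim = grid_shape
    )
  }
  (field - mean(field)) / sd(as.vector(field))
}

ellipsoid_mask <- function(grid_shape, spacing, center_vox, radii_mm) {
  x <- ((seq_len(grid_shape[1]) - 1) - center_vox[1]) * spacing[1] / radii_mm[1]
  y <- ((seq_len(grid_shape[2]) - 1) - center_vox[2]) * spacing[2] / radii_mm[2]
  z <- ((seq_len(grid_shape[3]) - 1) - center_vox[3]) * spacing[3] / radii_mm[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

#' Generate a seeded synthetic two-class cohort
#'
#' @param config a [cohort_config()].
#' @return A list of cases; each case is a list with `case_id`, `label`
#'   (0/1), `volumes` (named list of `GD` and `T2` [volume_image()]s sharing
#'   the label but with independent noise draws) and `mask` ([voi_mask()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  pars <- effective_class_params(config)
  gs <- config$grid_shape
  sp <- config$voxel_spacing
  with_seed(config$seed, {
    cases <- list()
    for (cls in 0:1) {
      for (i in seq_len(config$n_cases_per_class)) {
        radii <- runif(3, config$voi_radius_range[1], config$voi_radius_range[2])
        margin <- ceiling(radii / sp)
        lo <- margin
        hi <- (gs - 1) - margin
        if (any(hi < lo)) {
          stop("VOI of radius ", paste(signif(radii, 3), collapse = "/"),
               " mm cannot fit inside the grid")
        }
        center <- lo + (hi - lo) * runif(3)
        mask_arr <- ellipsoid_mask(gs, sp, center, radii)
        if (sum(mask_arr) < 27L) {
          stop("VOI smaller than 27 voxels; enlarge voi_radius_range or the grid")
        }
        vols <- lapply(c(GD = "GD", T2 = "T2"), function(role) {
          vals <- smoothed_field(gs, sp, pars$texture_scale[cls + 1]) +
            pars$intensity_shift[cls + 1] +
            config$noise_sd * array(rnorm(prod(gs)), dim = gs)
          volume_image(vals, sp)
        })
        cases[[length(cases) + 1L]] <- list(
          case_id = sprintf("case_c%d_%03d", cls, i),
          label = cls,
          volumes = vols,
          mask = voi_mask(mask_arr, sp)
        )
      }
    }
    cases
  })
}
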
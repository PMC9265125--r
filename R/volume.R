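#' 3D volume image
#'
#' A scalar 3D grid with anisotropic voxel spacing — the unit every stage of
#' the pipeline operates on. Axes are stored in (x, y, z) order matching the
#' NIfTI header affine axes.
#'
#' @param values 3D numeric array of voxel values; must be finite everywhere.
#' @param spacing length-3 positive numeric, mm per voxel along (x, y, z).
#' @param origin length-3 numeric, mm position of the first voxel center.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (!all(is.finite(values))) stop("values must be finite everywhere")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive reals (mm)")
  }
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "volume_image"
  )
}

#' Binary volume-of-interest mask
#'
#' Same grid conventions as [volume_image()]. Any voxel value above 0.5
#' counts as foreground, tolerating fractional exports from planning
#' systems.
#'
#' @param values 3D array (logical or numeric); foreground where > 0.5.
#' @inheritParams volume_image
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  v <- if (is.logical(values)) values else values > 0.5
  dim(v) <- dim(values)
  if (!any(v)) stop("empty VOI: mask has no foreground voxel")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive reals (mm)")
  }
  structure(
    list(values = v, spacing = spacing, origin = as.numeric(origin)),
    class = "voi_mask"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$values), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("<voi_mask> ", paste(dim(x$values), collapse = "x"),
      " voxels, ", sum(x$values), " foreground, spacing ",
      paste(signif(x$spacing, 4), collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

# Same grid shape and spacing (spacing tolerance in mm)?
check_same_grid <- function(volume, mask, tol = 1e-4) {
  if (!identical(dim(volume$values), dim(mask$values))) {
    stop("grid mismatch: volume is ", paste(dim(volume$values), collapse = "x"),
         " but mask is ", paste(dim(mask$values), collapse = "x"))
  }
  if (any(abs(volume$spacing - mask$spacing) > tol)) {
    stop("grid mismatch: voxel spacing differs beyond ", tol, " mm")
  }
  invisible(TRUE)
}
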
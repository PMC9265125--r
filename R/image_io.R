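# NIfTI reading/writing and case loading. All physical quantities downstream
# use the header voxel spacing; volumes are consumed on their native grids
# (no resampling), and a volume/mask grid mismatch is an error rather than a
# silent interpolation.

write_nifti_volume <- function(values, spacing, path) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  values <- array(as.vector(img), dim = dim(img))  # plain array, no header attrs
  list(values = values, spacing = as.numeric(RNifti::pixdim(img))[1:3])
}

#' Load one case (two sequence volumes and a VOI mask) from NIfTI files
#'
#' Reads the GD (post-gadolinium T1) and T2 volumes plus the binary mask,
#' checks that all three share the grid (shape, and spacing within 1e-4 mm),
#' and refuses empty masks. No resampling is ever performed.
#'
#' @param gd_path,t2_path,mask_path paths to NIfTI (`.nii`/`.nii.gz`) files.
#' @param case_id optional case identifier carried through.
#' @param label optional binary class label (0/1).
#' @return A list with elements `case_id`, `label`, `volumes` (named list
#'   with `GD` and `T2` [volume_image()] objects) and `mask` ([voi_mask()]).
#' @export
load_case <- function(gd_path, t2_path, mask_path, case_id = NULL, label = NA) {
  gd <- read_nifti_volume(gd_path)
  t2 <- read_nifti_volume(t2_path)
  mk <- read_nifti_volume(mask_path)
  if (!any(mk$values > 0.5)) stop("empty VOI: ", mask_path)
  vol_gd <- volume_image(gd$values, gd$spacing)
  vol_t2 <- volume_image(t2$values, t2$spacing)
  mask <- voi_mask(mk$values, mk$spacing)
  check_same_grid(vol_gd, mask)
  check_same_grid(vol_t2, mask)
  list(case_id = case_id %||% basename(mask_path), label = label,
       volumes = list(GD = vol_gd, T2 = vol_t2), mask = mask)
}

#' Write a synthetic cohort to NIfTI files plus a manifest CSV
#'
#' @param cases list of cases from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data frame (case_id, label, file paths).
#' @export
write_cohort <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cases, function(cs) {
    gd <- file.path(dir, paste0(cs$case_id, "_GD.nii.gz"))
    t2 <- file.path(dir, paste0(cs$case_id, "_T2.nii.gz"))
    mk <- file.path(dir, paste0(cs$case_id, "_mask.nii.gz"))
    write_nifti_volume(cs$volumes$GD$values, cs$volumes$GD$spacing, gd)
    write_nifti_volume(cs$volumes$T2$values, cs$volumes$T2$spacing, t2)
    write_nifti_volume(cs$mask$values * 1, cs$mask$spacing, mk)
    data.frame(case_id = cs$case_id, label = cs$label,
               gd_path = gd, t2_path = t2, mask_path = mk,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort back from a manifest CSV written by [write_cohort()]
#'
#' @param manifest_path path to the manifest CSV.
#' @return list of cases as returned by [load_case()].
#' @export
read_cohort <- function(manifest_path) {
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    load_case(manifest$gd_path[i], manifest$t2_path[i], manifest$mask_path[i],
              case_id = manifest$case_id[i], label = manifest$label[i])
  })
}
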
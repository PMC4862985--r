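#' Volume of a voxel mask
#'
#' @param mask Logical 3-D array.
#' @param voxel_size_mm Three voxel edge lengths (mm).
#' @return Volume in cm^3 (`count * voxel volume / 1000`).
#' @examples
#' roi_volume(array(TRUE, c(10, 10, 10)), c(1, 1, 1)) # 1 cm^3
#' @export
roi_volume <- function(mask, voxel_size_mm) {
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    cvr_abort("`voxel_size_mm` must be three positive edge lengths.",
              "invalid_argument")
  }
  sum(mask & TRUE) * prod(voxel_size_mm) / 1000
}

#' Tissue-wise CVR indexes and volumes
#'
#' Reduces a CVR map to the subject-level imaging measures: mean CVR slope
#' over valid voxels of GM, WM and brain (= GM + WM; CSF and ventricles are
#' excluded because ventricular reactivity is artifactually negative), plus
#' GM/WM tissue volumes. ROI means are unweighted over valid voxels; an ROI
#' with no valid voxels yields `NA` with a warning.
#'
#' @param map A `cvr_map` from [compute_cvr_map()].
#' @param masks A [tissue_masks()] on the same grid.
#' @return A one-row tibble: `gm_cvr`, `wm_cvr`, `brain_cvr` (% / mmHg),
#'   `gm_volume_cm3`, `wm_volume_cm3`, `n_valid_gm`, `n_valid_wm`,
#'   `n_valid_brain`.
#' @export
summarize_rois <- function(map, masks) {
  stopifnot(inherits(map, "cvr_map"), inherits(masks, "tissue_masks"))
  check_same_grid(map$grid_id, masks$grid_id, "CVR map and masks")
  roi_mean <- function(roi, name) {
    sel <- roi & map$valid
    n <- sum(sel)
    if (n == 0L) {
      rlang::warn(sprintf("ROI `%s` has no valid voxels; CVR reported as NA.", name))
      return(list(mean = NA_real_, n = 0L))
    }
    list(mean = mean(map$slope[sel]), n = n)
  }
  gm <- roi_mean(masks$gm, "gm")
  wm <- roi_mean(masks$wm, "wm")
  br <- roi_mean(masks$gm | masks$wm, "brain")
  tibble::tibble(
    gm_cvr = gm$mean, wm_cvr = wm$mean, brain_cvr = br$mean,
    gm_volume_cm3 = roi_volume(masks$gm, masks$voxel_size_mm),
    wm_volume_cm3 = roi_volume(masks$wm, masks$voxel_size_mm),
    n_valid_gm = gm$n, n_valid_wm = wm$n, n_valid_brain = br$n
  )
}
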
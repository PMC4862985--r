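#' 4D BOLD image container
#'
#' A light container for a BOLD time series: a 4-D array `(x, y, z, t)` of
#' signal intensity, voxel edge lengths, TR, and a grid token used to refuse
#' cross-grid operations.
#'
#' @param data 4-D numeric array `(x, y, z, t)` with `t >= 10`.
#' @param voxel_size_mm Three voxel edge lengths (mm).
#' @param tr_s Repetition time (s).
#' @return A `bold_image` object.
#' @export
bold_image <- function(data, voxel_size_mm, tr_s) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    cvr_abort("`data` must be a 4-D array (x, y, z, t).", "invalid_argument")
  }
  if (dim(data)[4] < 10L) {
    cvr_abort("BOLD series needs at least 10 volumes.", "invalid_argument")
  }
  if (any(!is.finite(data))) {
    cvr_abort("BOLD data must be finite.", "invalid_argument")
  }
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    cvr_abort("`voxel_size_mm` must be three positive edge lengths.",
              "invalid_argument")
  }
  check_number(tr_s, "tr_s", positive = TRUE)
  structure(
    list(data = data,
         voxel_size_mm = as.numeric(voxel_size_mm),
         tr_s = tr_s,
         grid_id = grid_token(dim(data)[1:3], voxel_size_mm)),
    class = "bold_image"
  )
}

#' @export
print.bold_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_image> %dx%dx%d voxels x %d volumes, voxel %s mm, TR %.3g s\n",
              d[1], d[2], d[3], d[4],
              paste(x$voxel_size_mm, collapse = "x"), x$tr_s))
  invisible(x)
}

#' @export
dim.bold_image <- function(x) dim(x$data)

#' Tissue mask container
#'
#' Boolean per-voxel membership for gray matter, white matter, and CSF on the
#' BOLD grid. GM/WM/CSF must be mutually exclusive; the ventricle mask is a
#' subset of CSF (ventricular CSF shows an apparent negative reactivity and
#' is tracked separately so it can be inspected or excluded).
#'
#' @param gm,wm,csf,ventricle Logical 3-D arrays on the same grid;
#'   `ventricle` defaults to empty.
#' @param voxel_size_mm Three voxel edge lengths (mm).
#' @return A `tissue_masks` object.
#' @export
tissue_masks <- function(gm, wm, csf, ventricle = NULL, voxel_size_mm) {
  dims <- dim(gm)
  if (length(dims) != 3L) cvr_abort("Masks must be 3-D arrays.", "invalid_argument")
  ventricle <- ventricle %||% array(FALSE, dims)
  for (m in list(wm, csf, ventricle)) {
    if (!identical(dim(m), dims)) {
      cvr_abort("All masks must share one grid.", "grid_mismatch")
    }
  }
  gm <- gm & TRUE; wm <- wm & TRUE; csf <- csf & TRUE; ventricle <- ventricle & TRUE
  if (any(gm & wm) || any(gm & csf) || any(wm & csf)) {
    cvr_abort("GM, WM and CSF masks must be mutually exclusive.", "invalid_argument")
  }
  if (any(ventricle & !csf)) {
    cvr_abort("Ventricle mask must be a subset of CSF.", "invalid_argument")
  }
  if (!any(gm | wm | csf)) {
    cvr_abort("At least one tissue class must be nonempty.", "invalid_argument")
  }
  structure(
    list(gm = gm, wm = wm, csf = csf, ventricle = ventricle,
         voxel_size_mm = as.numeric(voxel_size_mm),
         grid_id = grid_token(dims, voxel_size_mm)),
    class = "tissue_masks"
  )
}

#' @export
print.tissue_masks <- function(x, ...) {
  cat(sprintf("<tissue_masks> %s: GM %d, WM %d, CSF %d (ventricle %d) voxels\n",
              x$grid_id, sum(x$gm), sum(x$wm), sum(x$csf), sum(x$ventricle)))
  invisible(x)
}

#' Whole-brain analysis mask (GM + WM + CSF)
#'
#' @param masks A [tissue_masks()] object.
#' @return Logical 3-D array.
#' @export
brain_mask <- function(masks) {
  stopifnot(inherits(masks, "tissue_masks"))
  masks$gm | masks$wm | masks$csf
}

## ---- NIfTI I/O -------------------------------------------------------------

#' Read and write BOLD images and tissue masks as NIfTI-1
#'
#' Masks use an integer label convention: 0 background, 1 GM, 2 WM, 3 CSF,
#' 4 ventricle (ventricular voxels count as CSF).
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param bold,masks Objects to write.
#' @param tr_s TR override when the NIfTI header lacks timing (s).
#' @return Readers return a `bold_image` / `tissue_masks`; writers return the
#'   path invisibly.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
read_bold_nifti <- function(path, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) {
    cvr_abort("Expected a 4-D NIfTI BOLD series.", "invalid_argument")
  }
  tr <- tr_s %||% (if (length(pix) >= 4 && pix[4] > 0) pix[4] else
    cvr_abort("NIfTI header has no TR; pass `tr_s`.", "invalid_argument"))
  bold_image(arr, voxel_size_mm = pix[1:3], tr_s = tr)
}

#' @rdname nifti_io
#' @export
write_bold_nifti <- function(bold, path) {
  stopifnot(inherits(bold, "bold_image"))
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(bold$voxel_size_mm, bold$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_tissue_masks_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  lab <- as.array(img)
  if (length(dim(lab)) == 4L && dim(lab)[4] == 1L) lab <- lab[, , , 1]
  pix <- RNifti::pixdim(img)
  tissue_masks(gm = lab == 1, wm = lab == 2,
               csf = lab == 3 | lab == 4, ventricle = lab == 4,
               voxel_size_mm = pix[1:3])
}

#' @rdname nifti_io
#' @export
write_tissue_masks_nifti <- function(masks, path) {
  stopifnot(inherits(masks, "tissue_masks"))
  lab <- array(0L, dim(masks$gm))
  lab[masks$gm] <- 1L
  lab[masks$wm] <- 2L
  lab[masks$csf] <- 3L
  lab[masks$ventricle] <- 4L
  img <- RNifti::asNifti(lab)
  RNifti::pixdim(img) <- masks$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
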
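#' Tidy a CVR map into a per-voxel tibble
#'
#' @param x A `cvr_map`.
#' @param valid_only Keep only valid voxels (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with voxel indexes `x`, `y`, `z` and columns `slope`,
#'   `rvalue`, `valid`, `degenerate`, `baseline_signal`.
#' @export
tidy.cvr_map <- function(x, valid_only = TRUE, ...) {
  map <- x
  sel <- if (valid_only) which(map$valid) else seq_along(map$valid)
  idx <- arrayInd(sel, dim(map$valid))
  tibble::tibble(
    x = idx[, 1], y = idx[, 2], z = idx[, 3],
    slope = map$slope[sel], rvalue = map$rvalue[sel],
    valid = map$valid[sel], degenerate = map$degenerate[sel],
    baseline_signal = map$baseline_signal[sel]
  )
}

#' One-row summary of a CVR map
#'
#' @param x A `cvr_map`.
#' @param ... Unused.
#' @return A one-row tibble: voxel counts, % valid, median slope and r over
#'   valid voxels, volumes retained after QC, and the lag applied.
#' @export
glance.cvr_map <- function(x, ...) {
  v <- x$valid
  tibble::tibble(
    n_voxels = length(v), n_valid = sum(v),
    pct_valid = x$qc_report$pct_valid,
    median_slope = if (any(v)) median(x$slope[v]) else NA_real_,
    median_rvalue = if (any(v)) median(x$rvalue[v]) else NA_real_,
    n_retained = x$qc_report$n_retained,
    lag_volumes = x$qc_report$lag_volumes
  )
}
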
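## internal helpers shared across modules

cvr_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("cvrkit_error_", class), "cvrkit_error"), ...)
}

check_number <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    cvr_abort(sprintf("`%s` must be a single finite number.", name), "invalid_argument")
  }
  if (positive && x <= 0) {
    cvr_abort(sprintf("`%s` must be > 0.", name), "invalid_argument")
  }
  if (non_negative && x < 0) {
    cvr_abort(sprintf("`%s` must be >= 0.", name), "invalid_argument")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    cvr_abort(sprintf("`%s` must be an integer >= %d.", name, min), "invalid_argument")
  }
  invisible(as.integer(x))
}

#' Token identifying a voxel grid
#'
#' Two images live on the same grid iff their tokens match (dimensions and
#' voxel edge lengths). Used to refuse silent cross-grid operations.
#'
#' @param dims Integer vector of grid dimensions (x, y, z).
#' @param voxel_size_mm Numeric vector of the three voxel edge lengths in mm.
#' @return A single string.
#' @export
grid_token <- function(dims, voxel_size_mm) {
  ## voxel sizes round-trip through float32 NIfTI headers; 6 significant
  ## digits keeps the token stable across that conversion
  paste0(paste(dims, collapse = "x"), "@",
         paste(format(signif(voxel_size_mm, 6), trim = TRUE), collapse = "x"))
}

check_same_grid <- function(grid_a, grid_b, what = "inputs") {
  if (!identical(grid_a, grid_b)) {
    cvr_abort(
      sprintf("Grid mismatch between %s (%s vs %s); resample upstream, cvrkit never resamples implicitly.",
              what, grid_a, grid_b),
      "grid_mismatch"
    )
  }
  invisible(TRUE)
}
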
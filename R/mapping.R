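#' Fit one voxel's CVR by ordinary least squares
#'
#' The BOLD series is regressed on the PetCO2 regressor:
#' `slope = 100 * b / S0` where `b` is the OLS slope of signal on PetCO2 and
#' `S0` is the mean signal over the baseline volumes, giving CVR in % BOLD
#' signal change per mmHg. Fit confidence is the Pearson product-moment
#' correlation between signal and PetCO2.
#'
#' @param ts Numeric signal series for one voxel.
#' @param regressor A `cvr_regressor` (or numeric vector) of the same length.
#' @param baseline_volumes Integer indexes of baseline-epoch volumes used for
#'   `S0`; `NULL` means all volumes.
#' @param signal_floor Voxels with `S0 <=` this are flagged invalid (air).
#' @return A one-row tibble: `slope_pct_per_mmHg`, `rvalue`,
#'   `baseline_signal`, `valid`, `degenerate` (constant series: slope and r
#'   reported as 0).
#' @examples
#' reg <- build_protocol_waveform(hypercapnia_protocol(), 2, 255)
#' x <- regressor_values(reg)
#' ts <- 800 * (1 + 0.28 / 100 * (x - 35))
#' fit_voxel(ts, reg, baseline_volumes = which(x == 35))
#' @export
fit_voxel <- function(ts, regressor, baseline_volumes = NULL, signal_floor = 0) {
  x <- if (inherits(regressor, "cvr_regressor")) regressor$petco2_mmHg else as.numeric(regressor)
  if (length(ts) != length(x) || length(ts) < 3L) {
    cvr_abort("Series and regressor must have equal length >= 3.",
              "invalid_argument")
  }
  if (any(!is.finite(ts)) || any(!is.finite(x))) {
    cvr_abort("Series and regressor must be finite.", "invalid_argument")
  }
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) {
    cvr_abort("Regressor has zero variance: CVR is unidentifiable.",
              "invalid_argument")
  }
  s0 <- if (is.null(baseline_volumes)) mean(ts) else mean(ts[baseline_volumes])
  if (!is.finite(s0) || s0 <= signal_floor) {
    return(tibble::tibble(slope_pct_per_mmHg = NA_real_, rvalue = NA_real_,
                          baseline_signal = s0, valid = FALSE, degenerate = FALSE))
  }
  syy <- sum((ts - mean(ts))^2)
  if (syy <= 0) {
    return(tibble::tibble(slope_pct_per_mmHg = 0, rvalue = 0,
                          baseline_signal = s0, valid = TRUE, degenerate = TRUE))
  }
  sxy <- sum((x - mean(x)) * (ts - mean(ts)))
  b <- sxy / sxx
  r <- max(-1, min(1, sxy / sqrt(sxx * syy)))
  tibble::tibble(slope_pct_per_mmHg = 100 * b / s0, rvalue = r,
                 baseline_signal = s0, valid = TRUE, degenerate = FALSE)
}

## vectorised OLS over a T x V matrix; returns list of per-voxel vectors
fit_matrix <- function(Y, x, baseline_idx, signal_floor) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  s0 <- if (length(baseline_idx)) colMeans(Y[baseline_idx, , drop = FALSE]) else colMeans(Y)
  ym <- colMeans(Y)
  sxy <- as.vector(crossprod(Y, xc))               # sum((x-xbar) y) == sum((x-xbar)(y-ybar))
  syy <- colSums(Y^2) - n * ym^2
  syy <- pmax(syy, 0)
  b <- sxy / sxx
  valid <- is.finite(s0) & s0 > signal_floor
  degenerate <- valid & syy <= 1e-12 * pmax(1, ym^2)
  slope <- 100 * b / s0
  r <- ifelse(syy > 0, sxy / sqrt(sxx * syy), 0)
  r <- pmax(-1, pmin(1, r))
  slope[degenerate] <- 0
  r[degenerate] <- 0
  slope[!valid] <- NA_real_
  r[!valid] <- NA_real_
  list(slope = slope, rvalue = r, baseline_signal = s0,
       valid = valid, degenerate = degenerate)
}

#' Compute a voxelwise CVR map
#'
#' Applies QC (initial-volume discard, motion censoring), then fits every
#' in-mask voxel by OLS of the BOLD signal on the PetCO2 regressor, producing
#' a slope map (% BOLD per mmHg), a Pearson r fit-confidence map, and
#' validity flags. Optionally searches a global integer-volume lag between
#' regressor and BOLD by maximising the mean in-mask r.
#'
#' Percent normalisation uses the mean signal over volumes whose PetCO2 lies
#' within `baseline_tol_mmHg` of `baseline_mmHg` (default: the regressor
#' minimum, i.e. the baseline plateau); if no such epoch exists the mean over
#' all retained volumes is used.
#'
#' @param bold A [bold_image()].
#' @param regressor A `cvr_regressor`, one value per original volume.
#' @param qc A [qc_spec()].
#' @param mask Logical 3-D analysis mask (e.g. [brain_mask()]); `NULL` fits
#'   every voxel. Out-of-mask voxels are marked invalid.
#' @param baseline_mmHg Protocol baseline PetCO2; `NULL` uses the post-QC
#'   regressor minimum.
#' @param baseline_tol_mmHg Half-width of the baseline epoch window (mmHg).
#' @param signal_floor Absolute signal floor below which voxels are invalid;
#'   `NULL` uses `1e-6 *` the grand-mean signal.
#' @param lag_search If `TRUE`, search integer-volume lags in
#'   `[-max_lag, max_lag]` (regressor shifted with constant edge extension)
#'   and keep the lag maximising mean in-mask r.
#' @param max_lag Lag search half-window (volumes).
#' @return A `cvr_map`: arrays `slope`, `rvalue`, `valid`, `degenerate`,
#'   `baseline_signal`, plus grid metadata and a `qc_report` list.
#' @export
compute_cvr_map <- function(bold, regressor, qc = qc_spec(), mask = NULL,
                            baseline_mmHg = NULL, baseline_tol_mmHg = 1,
                            signal_floor = NULL,
                            lag_search = FALSE, max_lag = 5) {
  stopifnot(inherits(bold, "bold_image"))
  dims <- dim(bold$data)[1:3]
  if (is.null(mask)) {
    mask <- array(TRUE, dims)
  } else if (inherits(mask, "tissue_masks")) {
    check_same_grid(bold$grid_id, mask$grid_id, "BOLD and masks")
    mask <- brain_mask(mask)
  } else if (!identical(dim(mask), dims)) {
    cvr_abort("Analysis mask grid does not match the BOLD grid.", "grid_mismatch")
  }
  mask <- mask & TRUE

  qcd <- apply_qc(bold, regressor, qc)
  x <- qcd$regressor$petco2_mmHg
  if (sum((x - mean(x))^2) <= 0 && any(mask)) {
    cvr_abort("Regressor has zero variance after QC.", "invalid_argument")
  }
  n_t <- length(x)
  v_mask <- which(mask)

  out <- list(
    slope = array(NA_real_, dims), rvalue = array(NA_real_, dims),
    valid = array(FALSE, dims), degenerate = array(FALSE, dims),
    baseline_signal = array(NA_real_, dims),
    voxel_size_mm = bold$voxel_size_mm, grid_id = bold$grid_id,
    qc_report = list(n_volumes_in = dim(bold$data)[4],
                     n_discard = qc$n_discard,
                     censor_volumes = qc$censor_volumes,
                     n_retained = n_t, lag_volumes = 0L,
                     pct_valid = 0)
  )
  class(out) <- "cvr_map"
  if (!length(v_mask)) return(out)

  Y <- matrix(aperm(qcd$bold$data, c(4, 1, 2, 3)), nrow = n_t)[, v_mask, drop = FALSE]
  signal_floor <- signal_floor %||% (1e-6 * mean(Y))

  shift_x <- function(x, lag) {
    ## positive lag: BOLD response trails the regressor by `lag` volumes
    n <- length(x)
    idx <- pmin(pmax(seq_len(n) - lag, 1L), n)
    x[idx]
  }
  baseline_idx_for <- function(xx) {
    b0 <- baseline_mmHg %||% min(xx)
    idx <- which(abs(xx - b0) <= baseline_tol_mmHg)
    if (!length(idx)) idx <- seq_along(xx)
    idx
  }

  lag <- 0L
  if (isTRUE(lag_search)) {
    lags <- seq.int(-max_lag, max_lag)
    score <- vapply(lags, function(l) {
      xs <- shift_x(x, l)
      if (sum((xs - mean(xs))^2) <= 0) return(-Inf)
      f <- fit_matrix(Y, xs, baseline_idx_for(xs), signal_floor)
      mean(f$rvalue[f$valid], na.rm = TRUE)
    }, numeric(1))
    lag <- lags[which.max(score)]
  }
  xs <- shift_x(x, lag)
  fit <- fit_matrix(Y, xs, baseline_idx_for(xs), signal_floor)

  out$slope[v_mask] <- fit$slope
  out$rvalue[v_mask] <- fit$rvalue
  out$valid[v_mask] <- fit$valid
  out$degenerate[v_mask] <- fit$degenerate
  out$baseline_signal[v_mask] <- fit$baseline_signal
  out$qc_report$lag_volumes <- as.integer(lag)
  out$qc_report$pct_valid <- 100 * sum(fit$valid) / length(mask)
  out
}

#' @export
print.cvr_map <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("<cvr_map> %s, %d valid voxels (%.1f%%)\n",
              x$grid_id, nv, x$qc_report$pct_valid))
  if (nv) {
    cat(sprintf("  slope %% / mmHg: median %.3f [%.3f, %.3f]\n",
                median(x$slope[x$valid]),
                quantile(x$slope[x$valid], 0.05),
                quantile(x$slope[x$valid], 0.95)))
  }
  invisible(x)
}

#' Write a CVR map as NIfTI volumes plus a QC report
#'
#' Writes `<prefix>_cvr.nii.gz` (slope, NA outside valid voxels),
#' `<prefix>_r.nii.gz`, and `<prefix>_qc.json` (volumes discarded/censored,
#' lag, % valid voxels).
#'
#' @param map A `cvr_map`.
#' @param prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_cvr_map <- function(map, prefix) {
  stopifnot(inherits(map, "cvr_map"))
  files <- c(paste0(prefix, "_cvr.nii.gz"), paste0(prefix, "_r.nii.gz"),
             paste0(prefix, "_qc.json"))
  for (i in 1:2) {
    arr <- if (i == 1) map$slope else map$rvalue
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- map$voxel_size_mm
    RNifti::writeNifti(img, files[i])
  }
  jsonlite::write_json(map$qc_report, files[3], auto_unbox = TRUE, digits = NA)
  invisible(files)
}
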
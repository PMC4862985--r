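#' Quality-control specification for a BOLD run
#'
#' Defaults follow common step-hypercapnia practice: discard the first three
#' volumes for magnetisation equilibration, and allow up to nine
#' motion-censored volumes per run.
#'
#' @param n_discard Number of initial volumes dropped.
#' @param censor_volumes Integer indexes (into the original volume numbering)
#'   excluded for motion. Must lie beyond the discarded block.
#' @param max_censor Maximum allowed number of censored volumes.
#' @return A `qc_spec` object.
#' @export
qc_spec <- function(n_discard = 3, censor_volumes = integer(), max_censor = 9) {
  n_discard <- check_count(n_discard, "n_discard", min = 0L)
  max_censor <- check_count(max_censor, "max_censor", min = 0L)
  if (length(censor_volumes)) {
    if (any(censor_volumes != round(censor_volumes)) || any(censor_volumes < 1)) {
      cvr_abort("`censor_volumes` must be positive integer indexes.",
                "invalid_argument")
    }
    censor_volumes <- sort(unique(as.integer(censor_volumes)))
  } else {
    censor_volumes <- integer()
  }
  structure(list(n_discard = n_discard,
                 censor_volumes = censor_volumes,
                 max_censor = max_censor),
            class = "qc_spec")
}

#' Discard and censor volumes, keeping BOLD and regressor in lockstep
#'
#' Discarded initial volumes and motion-censored volumes are *removed* from
#' both the BOLD series and the regressor (row deletion, never
#' interpolation), preserving the pairing used by the voxelwise fit.
#'
#' @param bold A [bold_image()].
#' @param regressor A `cvr_regressor` with one value per original volume.
#' @param qc A [qc_spec()].
#' @param min_remaining Minimum volumes that must survive QC (default 10).
#' @return A list with elements `bold`, `regressor` (trimmed), and
#'   `kept_volumes` (original indexes retained).
#' @export
apply_qc <- function(bold, regressor, qc = qc_spec(), min_remaining = 10L) {
  stopifnot(inherits(bold, "bold_image"), inherits(qc, "qc_spec"))
  n_t <- dim(bold$data)[4]
  if (!inherits(regressor, "cvr_regressor") || nrow(regressor) != n_t) {
    cvr_abort("Regressor length must equal the number of BOLD volumes.",
              "invalid_argument")
  }
  cen <- qc$censor_volumes
  if (length(cen) > qc$max_censor) {
    cvr_abort(sprintf("%d volumes censored but max_censor is %d.",
                      length(cen), qc$max_censor), "qc_failure")
  }
  if (length(cen) && (max(cen) > n_t || min(cen) <= qc$n_discard)) {
    cvr_abort("Censor indexes must lie within the run and beyond the discarded block.",
              "invalid_argument")
  }
  if (qc$n_discard >= n_t) {
    cvr_abort("n_discard leaves no volumes.", "qc_failure")
  }
  keep <- setdiff(seq_len(n_t), c(seq_len(qc$n_discard), cen))
  if (length(keep) < min_remaining) {
    cvr_abort(sprintf("Only %d volumes remain after QC (need >= %d).",
                      length(keep), min_remaining), "qc_failure")
  }
  bold2 <- bold
  bold2$data <- bold$data[, , , keep, drop = FALSE]
  reg2 <- new_regressor(regressor$petco2_mmHg[keep],
                        tr_s = attr(regressor, "tr_s"),
                        t0_s = attr(regressor, "t0_s"))
  reg2$volume <- keep
  reg2$time_s <- regressor$time_s[keep]
  list(bold = bold2, regressor = reg2, kept_volumes = keep)
}

#' Derive a censor list from motion parameters
#'
#' Computes framewise displacement (FD) from six rigid-body motion parameters
#' (three translations in mm, three rotations in radians converted to arc
#' length on a 50 mm sphere) as the sum of absolute backward differences, and
#' censors volumes whose FD exceeds the threshold.
#'
#' @param motion Data frame with columns `trans_x, trans_y, trans_z` (mm) and
#'   `rot_x, rot_y, rot_z` (radians), one row per volume.
#' @param fd_threshold_mm Censoring threshold (mm), default 0.9.
#' @param head_radius_mm Sphere radius for rotation conversion (mm).
#' @return Integer vector of volume indexes to censor (FD of volume 1 is 0).
#' @export
censor_from_fd <- function(motion, fd_threshold_mm = 0.9, head_radius_mm = 50) {
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (!all(need %in% names(motion))) {
    cvr_abort(sprintf("`motion` needs columns %s.", paste(need, collapse = ", ")),
              "invalid_argument")
  }
  m <- as.matrix(motion[need])
  m[, 4:6] <- m[, 4:6] * head_radius_mm
  fd <- c(0, rowSums(abs(diff(m))))
  which(fd > fd_threshold_mm)
}
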
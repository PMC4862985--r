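#' Compartment presets for the digital phantom
#'
#' True CVR gains follow the healthy-control and mTBI visit-1 tissue means
#' (GM 0.28 vs 0.26, WM 0.160 vs 0.1472 % BOLD / mmHg). The ventricular
#' compartment has a *negative* gain: ventricular BOLD varies inversely with
#' PetCO2 (vessel dilatation displaces CSF), and the phantom reproduces that
#' sign so the mapping stage can be shown to recover it. Baseline signal
#' levels are typical EPI tissue intensities; noise SDs default to 1% of the
#' baseline signal (temporal SNR ~100).
#'
#' @param preset `"healthy-control"` or `"mtbi"`.
#' @return A tibble with one row per compartment: `tissue`,
#'   `true_cvr_pct_per_mmHg`, `baseline_signal`, `noise_sd`,
#'   `drift_slope_per_volume`.
#' @export
tissue_presets <- function(preset = c("healthy-control", "mtbi")) {
  preset <- match.arg(preset)
  gm_cvr <- if (preset == "healthy-control") 0.28 else 0.26
  wm_cvr <- if (preset == "healthy-control") 0.160 else 0.1472
  tibble::tibble(
    tissue = c("gm", "wm", "csf", "ventricle"),
    true_cvr_pct_per_mmHg = c(gm_cvr, wm_cvr, 0, -0.10),
    baseline_signal = c(1000, 800, 600, 600),
    noise_sd = c(10, 8, 6, 6),
    drift_slope_per_volume = c(0, 0, 0, 0)
  )
}

#' Specify a digital 4D BOLD phantom
#'
#' The phantom is a nested-box head: an air border, a one-voxel CSF rim, a
#' two-voxel GM shell, a WM core, and a small ventricle pocket (ventricular
#' CSF) at the centre. Every voxel's generating CVR gain is known, so map
#' recovery can be checked exactly.
#'
#' @param grid_dims Three grid dimensions; default `c(24, 24, 16)`.
#' @param voxel_size_mm Voxel edges (mm); default `c(3.6, 3.6, 3)` (typical
#'   GRE-EPI resolution).
#' @param compartments A compartment tibble as from [tissue_presets()].
#' @param tr_s Repetition time (s).
#' @param n_volumes Number of volumes; default 255.
#' @param baseline_mmHg PetCO2 baseline of the signal model (mmHg).
#' @param noise_scale Multiplier on compartment noise SDs (0 = noiseless).
#' @param ar_coef AR(1) coefficient of the temporal noise (0 = white).
#' @param seed Integer seed used by [generate_phantom()].
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_dims = c(24, 24, 16),
                         voxel_size_mm = c(3.6, 3.6, 3),
                         compartments = tissue_presets("healthy-control"),
                         tr_s = 2, n_volumes = 255,
                         baseline_mmHg = 35,
                         noise_scale = 1, ar_coef = 0, seed = 1L) {
  if (length(grid_dims) != 3L || any(grid_dims < 8)) {
    cvr_abort("`grid_dims` must be three dimensions >= 8.", "invalid_argument")
  }
  need <- c("tissue", "true_cvr_pct_per_mmHg", "baseline_signal", "noise_sd",
            "drift_slope_per_volume")
  if (!all(need %in% names(compartments)) ||
      !all(c("gm", "wm", "csf", "ventricle") %in% compartments$tissue)) {
    cvr_abort("`compartments` must cover gm, wm, csf and ventricle.",
              "spec_error")
  }
  check_number(noise_scale, "noise_scale", non_negative = TRUE)
  if (abs(ar_coef) >= 1) cvr_abort("`ar_coef` must be in (-1, 1).", "invalid_argument")
  n_volumes <- check_count(n_volumes, "n_volumes", min = 10L)
  structure(
    list(grid_dims = as.integer(grid_dims),
         voxel_size_mm = as.numeric(voxel_size_mm),
         compartments = compartments,
         tr_s = tr_s, n_volumes = n_volumes,
         baseline_mmHg = baseline_mmHg,
         noise_scale = noise_scale, ar_coef = ar_coef,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

## label array for the nested-box geometry: 0 air, 1 gm, 2 wm, 3 csf rim,
## 4 ventricle (ventricle voxels are CSF-class). The head box leaves a
## one-voxel air margin; shell thickness and ventricle size adapt to the
## grid so small test phantoms still contain every compartment.
phantom_labels <- function(grid_dims) {
  d <- grid_dims
  ## per-axis depth inside the head box (-1 = air margin)
  ax <- function(n) {
    v <- rep(-1L, n)
    idx <- 2:(n - 1)
    v[idx] <- pmin(idx - 2L, (n - 1L) - idx)
    v
  }
  A1 <- array(ax(d[1]), d)
  A2 <- array(rep(ax(d[2]), each = d[1]), d)
  A3 <- array(rep(ax(d[3]), each = d[1] * d[2]), d)
  depth <- pmin(A1, A2, A3)
  gm_thick <- if (min(d) >= 14) 2L else 1L
  lab <- array(0L, d)
  lab[depth == 0L] <- 3L                       # CSF rim
  lab[depth >= 1L & depth <= gm_thick] <- 1L   # GM shell
  lab[depth > gm_thick] <- 2L                  # WM core
  if (!any(lab == 2L)) {
    cvr_abort("Grid too small to contain a WM core.", "spec_error")
  }
  ## ventricle pocket: a small box at the head centre, kept inside WM
  cx <- round(d / 2)
  h <- if (min(d) >= 14) c(1L, 1L, 1L) else c(0L, 0L, 0L)
  vent <- array(FALSE, d)
  vent[max(cx[1] - h[1], 1):min(cx[1] + h[1], d[1]),
       max(cx[2] - h[2], 1):min(cx[2] + h[2], d[2]),
       max(cx[3], 1):min(cx[3] + h[3], d[3])] <- TRUE
  vent <- vent & (lab == 2L)
  if (!any(vent) || sum(lab == 2L) - sum(vent) < 1L) {
    cvr_abort("Grid too small to carve a ventricle inside the WM core.",
              "spec_error")
  }
  lab[vent] <- 4L
  lab
}

#' Generate a 4D BOLD phantom with known voxelwise CVR
#'
#' Each voxel follows the linear reactivity signal model
#' `S(t) = S0 * (1 + (c/100) * (PetCO2(t) - baseline)) + drift * t + e(t)`
#' with `c` the compartment's true CVR gain (% / mmHg) and `e` seeded
#' Gaussian noise (optionally AR(1)). Air voxels are low-level noise around
#' zero signal.
#'
#' @param spec A [phantom_spec()].
#' @param regressor A `cvr_regressor` of length `spec$n_volumes`.
#' @return A list: `bold` ([bold_image()]), `masks` ([tissue_masks()]),
#'   `truth` (3-D array of generating CVR gains, `NA` in air), and `labels`.
#' @examples
#' spec <- phantom_spec(grid_dims = c(10, 10, 8), n_volumes = 60, noise_scale = 0)
#' reg <- build_protocol_waveform(hypercapnia_protocol(), 2, 60)
#' ph <- generate_phantom(spec, reg)
#' @export
generate_phantom <- function(spec, regressor) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(regressor, "cvr_regressor"))
  if (nrow(regressor) != spec$n_volumes) {
    cvr_abort("Regressor length must equal spec n_volumes.", "invalid_argument")
  }
  set.seed(spec$seed)
  lab <- phantom_labels(spec$grid_dims)
  v <- as.integer(lab)
  comp <- spec$compartments
  row_of <- match(c("gm", "wm", "csf", "ventricle"), comp$tissue)
  lut <- function(col) {
    vals <- c(0, comp[[col]][row_of])  # air = 0
    vals[v + 1L]
  }
  s0 <- lut("baseline_signal")
  cvr <- lut("true_cvr_pct_per_mmHg")
  noise <- lut("noise_sd") * spec$noise_scale
  noise[v == 0L] <- 0.5 * spec$noise_scale   # faint air noise
  drift <- lut("drift_slope_per_volume")

  x <- regressor$petco2_mmHg - spec$baseline_mmHg
  n_t <- spec$n_volumes
  n_v <- length(v)
  ## T x V deterministic signal
  Y <- outer(x, s0 * cvr / 100) +
    matrix(s0, n_t, n_v, byrow = TRUE) +
    outer(seq_len(n_t) - 1, drift)
  if (spec$noise_scale > 0) {
    E <- matrix(rnorm(n_t * n_v), n_t, n_v)
    if (spec$ar_coef != 0) {
      a <- spec$ar_coef
      E <- apply(E * sqrt(1 - a^2), 2, function(e) as.numeric(stats::filter(e, a, method = "recursive")))
    }
    Y <- Y + E * matrix(noise, n_t, n_v, byrow = TRUE)
  }
  arr <- aperm(array(Y, c(n_t, spec$grid_dims)), c(2, 3, 4, 1))

  masks <- tissue_masks(gm = lab == 1L, wm = lab == 2L,
                        csf = lab == 3L | lab == 4L, ventricle = lab == 4L,
                        voxel_size_mm = spec$voxel_size_mm)
  truth <- array(cvr, spec$grid_dims)
  truth[lab == 0L] <- NA_real_
  list(bold = bold_image(arr, spec$voxel_size_mm, spec$tr_s),
       masks = masks, truth = truth, labels = lab)
}
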
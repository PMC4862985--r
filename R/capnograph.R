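#' Simulate a capnograph trace for a hypercapnia protocol
#'
#' Generates an instantaneous airway pCO2 waveform as a sequence of idealised
#' respiratory cycles: each breath starts with an inspiratory trough (a few
#' mmHg, inspired gas), rises through expiration, and holds an end-expiratory
#' plateau whose level is the protocol's target PetCO2 at that breath (plus
#' optional per-breath Gaussian noise). The plateau occupies the final 20% of
#' each cycle so the per-breath maximum equals the plateau level exactly.
#'
#' This stands in for a prospective end-tidal targeting recording; it makes no
#' attempt to model gas exchange or rebreathing-circuit physics.
#'
#' @param x A [hypercapnia_protocol()] or a `cvr_regressor` giving the target
#'   schedule; a regressor is read as a step function over its volumes.
#' @param breath_rate_per_min Respiratory rate (breaths/min), default 15.
#' @param noise_sd_mmHg SD of per-breath plateau noise (mmHg).
#' @param sample_rate_hz Trace sampling rate (Hz).
#' @param trough_mmHg Inspiratory trough level (mmHg), default 3.
#' @param duration_s Trace length (s); defaults to the protocol duration or
#'   the regressor's covered time span.
#' @param seed Optional integer seed; same seed, same trace.
#' @return A `capno_trace` tibble with columns `time_s`, `pco2_mmHg`;
#'   attributes record the sampling rate, breath period, and the generating
#'   per-breath plateau levels (ground truth for validation).
#' @export
simulate_capnograph <- function(x,
                                breath_rate_per_min = 15,
                                noise_sd_mmHg = 0,
                                sample_rate_hz = 25,
                                trough_mmHg = 3,
                                duration_s = NULL,
                                seed = NULL) {
  check_number(breath_rate_per_min, "breath_rate_per_min", positive = TRUE)
  check_number(noise_sd_mmHg, "noise_sd_mmHg", non_negative = TRUE)
  check_number(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  check_number(trough_mmHg, "trough_mmHg", non_negative = TRUE)

  if (inherits(x, "cvr_protocol")) {
    target <- function(t) protocol_target(x, t)
    duration_s <- duration_s %||% protocol_duration(x)
  } else if (inherits(x, "cvr_regressor")) {
    tr <- attr(x, "tr_s")
    target <- function(t) {
      approx(x$time_s, x$petco2_mmHg, xout = t, method = "constant",
             rule = 2, f = 0)$y
    }
    duration_s <- duration_s %||% (attr(x, "t0_s") + nrow(x) * tr)
  } else {
    cvr_abort("`x` must be a hypercapnia protocol or a PetCO2 regressor.",
              "invalid_argument")
  }
  check_number(duration_s, "duration_s", positive = TRUE)

  if (!is.null(seed)) set.seed(seed)
  breath_period <- 60 / breath_rate_per_min
  n_breaths <- max(1L, floor(duration_s / breath_period))
  breath_start <- (seq_len(n_breaths) - 1L) * breath_period
  ## plateau level sampled inside the plateau window of each breath
  plateau <- target(breath_start + 0.9 * breath_period) +
    rnorm(n_breaths, 0, noise_sd_mmHg)

  t <- seq(0, n_breaths * breath_period - 1 / sample_rate_hz, by = 1 / sample_rate_hz)
  breath_of <- pmin(floor(t / breath_period) + 1L, n_breaths)
  phase <- t / breath_period - (breath_of - 1L)
  plat <- plateau[breath_of]
  pco2 <- ifelse(
    phase < 0.35, trough_mmHg,
    ifelse(phase < 0.8,
           trough_mmHg + (plat - trough_mmHg) * (phase - 0.35) / 0.45,
           plat)
  )
  pco2 <- pmax(pco2, 0)

  out <- tibble::tibble(time_s = t, pco2_mmHg = pco2)
  structure(out,
            sample_rate_hz = sample_rate_hz,
            breath_period_s = breath_period,
            plateau_mmHg = plateau,
            breath_start_s = breath_start,
            class = c("capno_trace", class(out)))
}

#' Detect end-tidal points on a capnograph trace
#'
#' Automates end-tidal selection: the trace is thresholded at the midpoint of
#' its range, each supra-threshold run is treated as one expiratory excursion,
#' and the end-tidal point of a breath is the maximum of its excursion (the
#' last sample attaining it, i.e. end of expiration). Excursions whose peaks
#' fall closer together than `min_breath_interval_s` are merged, keeping the
#' higher peak.
#'
#' @param trace A `capno_trace` (or any data frame with `time_s`,
#'   `pco2_mmHg`).
#' @param min_breath_interval_s Minimum separation between end-tidal points
#'   (s); the default 2 s admits respiratory rates up to 30 breaths/min.
#' @return An `end_tidal` tibble with columns `breath_time_s`,
#'   `petco2_mmHg`, one row per detected breath.
#' @export
detect_end_tidal <- function(trace, min_breath_interval_s = 2) {
  check_number(min_breath_interval_s, "min_breath_interval_s", positive = TRUE)
  if (!all(c("time_s", "pco2_mmHg") %in% names(trace))) {
    cvr_abort("`trace` needs columns `time_s` and `pco2_mmHg`.", "invalid_argument")
  }
  tt <- trace$time_s
  p <- trace$pco2_mmHg
  if (length(tt) < 4L || any(diff(tt) <= 0)) {
    cvr_abort("`trace` must have >= 4 samples with strictly increasing times.",
              "invalid_argument")
  }
  rng <- range(p)
  if (diff(rng) < 1e-6) {
    cvr_abort("No respiratory oscillation in trace: cannot segment breaths.",
              "detection_failure")
  }
  thr <- rng[1] + 0.5 * diff(rng)
  above <- p >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) < 2L) {
    cvr_abort("Trace spans fewer than two breaths: cannot build an end-tidal series.",
              "detection_failure")
  }
  peak_t <- peak_v <- numeric(length(runs))
  for (j in seq_along(runs)) {
    idx <- starts[runs[j]]:ends[runs[j]]
    vmax <- max(p[idx])
    i_at <- idx[p[idx] >= vmax - 1e-12]
    i_at <- i_at[length(i_at)]   # end of expiration on ties / plateaus
    peak_t[j] <- tt[i_at]
    peak_v[j] <- p[i_at]
  }
  ## merge peaks violating the minimum breath interval, keeping the higher
  keep_t <- peak_t[1]
  keep_v <- peak_v[1]
  for (j in seq_along(peak_t)[-1]) {
    last <- length(keep_t)
    if (peak_t[j] - keep_t[last] < min_breath_interval_s) {
      if (peak_v[j] >= keep_v[last]) {
        keep_t[last] <- peak_t[j]
        keep_v[last] <- peak_v[j]
      }
    } else {
      keep_t <- c(keep_t, peak_t[j])
      keep_v <- c(keep_v, peak_v[j])
    }
  }
  if (length(keep_t) < 2L) {
    cvr_abort("Fewer than two end-tidal points detected.", "detection_failure")
  }
  out <- tibble::tibble(breath_time_s = keep_t, petco2_mmHg = keep_v)
  structure(out, class = c("end_tidal", class(out)))
}

#' Resample an end-tidal series onto the scanner TR grid
#'
#' Linear interpolation of breath-wise PetCO2 evaluated at volume midpoints
#' `t0 + (i - 0.5) * TR`, with constant extrapolation before the first and
#' after the last breath.
#'
#' @param etseries An `end_tidal` tibble (or data frame with
#'   `breath_time_s`, `petco2_mmHg`); needs at least two points.
#' @param tr_s Repetition time (s).
#' @param n_volumes Number of BOLD volumes.
#' @param t0_s Time of the first volume's start relative to the trace (s).
#' @return A `cvr_regressor` of length `n_volumes`.
#' @export
resample_to_tr <- function(etseries, tr_s = 2, n_volumes = 255, t0_s = 0) {
  check_number(tr_s, "tr_s", positive = TRUE)
  n_volumes <- check_count(n_volumes, "n_volumes", min = 1L)
  check_number(t0_s, "t0_s")
  if (!all(c("breath_time_s", "petco2_mmHg") %in% names(etseries)) ||
      nrow(etseries) < 2L) {
    cvr_abort("`etseries` needs >= 2 end-tidal points.", "invalid_argument")
  }
  mid <- t0_s + (seq_len(n_volumes) - 0.5) * tr_s
  vals <- approx(etseries$breath_time_s, etseries$petco2_mmHg,
                 xout = mid, method = "linear", rule = 2)$y
  new_regressor(vals, tr_s = tr_s, t0_s = t0_s)
}

#' Read / write capnograph traces and regressors as CSV
#'
#' A trace is a two-column CSV `time_s,pco2_mmHg`; a regressor is written as
#' `volume,time_s,petco2_mmHg` with TR and t0 in a JSON sidecar
#' (`<path>.json`) so it round-trips exactly.
#'
#' @param path File path.
#' @param trace,regressor Objects to write.
#' @param sample_rate_hz Sampling rate to attach on read (optional).
#' @return `read_capno_csv()` a `capno_trace`; `read_regressor_csv()` a
#'   `cvr_regressor`; writers return the path invisibly.
#' @name capno_io
NULL

#' @rdname capno_io
#' @export
read_capno_csv <- function(path, sample_rate_hz = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "pco2_mmHg") %in% names(df))) {
    cvr_abort("Capnograph CSV must have columns `time_s,pco2_mmHg`.",
              "invalid_argument")
  }
  sr <- sample_rate_hz %||% (1 / stats::median(diff(df$time_s)))
  structure(tibble::as_tibble(df[c("time_s", "pco2_mmHg")]),
            sample_rate_hz = sr,
            class = c("capno_trace", class(tibble::tibble())))
}

#' @rdname capno_io
#' @export
write_capno_csv <- function(trace, path) {
  readr::write_csv(tibble::as_tibble(trace)[c("time_s", "pco2_mmHg")], path)
  invisible(path)
}

#' @rdname capno_io
#' @export
write_regressor_csv <- function(regressor, path) {
  stopifnot(inherits(regressor, "cvr_regressor"))
  readr::write_csv(tibble::as_tibble(regressor), path)
  jsonlite::write_json(
    list(tr_s = attr(regressor, "tr_s"), t0_s = attr(regressor, "t0_s"),
         n_volumes = nrow(regressor)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname capno_io
#' @export
read_regressor_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    tr <- meta$tr_s
    t0 <- meta$t0_s %||% 0
  } else {
    tr <- stats::median(diff(df$time_s))
    t0 <- df$time_s[1] - 0.5 * tr
  }
  new_regressor(df$petco2_mmHg, tr_s = tr, t0_s = t0)
}
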
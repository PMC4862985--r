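#' Define a step hypercapnia protocol
#'
#' A hypercapnia challenge is described as a baseline end-tidal CO2 target
#' with one or more square-wave hypercapnic blocks. The default reproduces a
#' two-block design: PetCO2 raised 10 mmHg above a ~35 mmHg baseline, held for
#' 45 s, returned to baseline for 90 s, then held again for 130 s, with a 60 s
#' lead-in; the tail pads the schedule to a 255-volume, TR 2 s acquisition.
#'
#' @param baseline_mmHg Baseline PetCO2 target (mmHg).
#' @param step_mmHg Hypercapnic step amplitude above baseline (mmHg). May be 0
#'   (degenerate flat protocol, useful for null simulations).
#' @param block_durations_s Ordered hypercapnic block durations (s).
#' @param inter_block_s Baseline interval between consecutive blocks (s).
#' @param lead_in_s Baseline period before the first block (s).
#' @param tail_s Baseline period after the last block (s).
#' @return An object of class `cvr_protocol`.
#' @examples
#' p <- hypercapnia_protocol()
#' protocol_duration(p) # 510 s = 255 volumes at TR 2 s
#' @export
hypercapnia_protocol <- function(baseline_mmHg = 35,
                                 step_mmHg = 10,
                                 block_durations_s = c(45, 130),
                                 inter_block_s = 90,
                                 lead_in_s = 60,
                                 tail_s = 185) {
  check_number(baseline_mmHg, "baseline_mmHg", positive = TRUE)
  check_number(step_mmHg, "step_mmHg", non_negative = TRUE)
  if (length(block_durations_s) < 1L || any(!is.finite(block_durations_s)) ||
      any(block_durations_s <= 0)) {
    cvr_abort("`block_durations_s` must be one or more positive durations.",
              "invalid_argument")
  }
  check_number(inter_block_s, "inter_block_s", positive = TRUE)
  check_number(lead_in_s, "lead_in_s", positive = TRUE)
  check_number(tail_s, "tail_s", positive = TRUE)
  structure(
    list(baseline_mmHg = baseline_mmHg,
         step_mmHg = step_mmHg,
         block_durations_s = as.numeric(block_durations_s),
         inter_block_s = inter_block_s,
         lead_in_s = lead_in_s,
         tail_s = tail_s),
    class = "cvr_protocol"
  )
}

#' @export
print.cvr_protocol <- function(x, ...) {
  cat("<cvr_protocol>\n")
  cat(sprintf("  baseline %.2f mmHg, step +%.2f mmHg\n", x$baseline_mmHg, x$step_mmHg))
  cat(sprintf("  blocks: %s s (inter-block %.0f s, lead-in %.0f s, tail %.0f s)\n",
              paste(x$block_durations_s, collapse = ", "),
              x$inter_block_s, x$lead_in_s, x$tail_s))
  cat(sprintf("  total duration %.0f s\n", protocol_duration(x)))
  invisible(x)
}

#' Total protocol duration
#'
#' @param protocol A [hypercapnia_protocol()].
#' @return Duration in seconds: lead-in + blocks + inter-block gaps + tail.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "cvr_protocol"))
  nb <- length(protocol$block_durations_s)
  protocol$lead_in_s + sum(protocol$block_durations_s) +
    protocol$inter_block_s * (nb - 1L) + protocol$tail_s
}

## block start times (s) relative to protocol start
protocol_block_starts <- function(protocol) {
  nb <- length(protocol$block_durations_s)
  protocol$lead_in_s +
    c(0, cumsum(protocol$block_durations_s[-nb] + protocol$inter_block_s))
}

#' Evaluate the target PetCO2 schedule
#'
#' Piecewise-constant target: `baseline + step` inside hypercapnic blocks,
#' `baseline` elsewhere (including beyond the protocol end).
#'
#' @param protocol A [hypercapnia_protocol()].
#' @param time_s Numeric vector of times (s) from protocol start.
#' @return Target PetCO2 (mmHg) at each time.
#' @export
protocol_target <- function(protocol, time_s) {
  stopifnot(inherits(protocol, "cvr_protocol"))
  starts <- protocol_block_starts(protocol)
  ends <- starts + protocol$block_durations_s
  elevated <- rep(FALSE, length(time_s))
  for (k in seq_along(starts)) {
    elevated <- elevated | (time_s >= starts[k] & time_s < ends[k])
  }
  protocol$baseline_mmHg + protocol$step_mmHg * as.numeric(elevated)
}

new_regressor <- function(values_mmHg, tr_s, t0_s = 0) {
  n <- length(values_mmHg)
  out <- tibble::tibble(
    volume = seq_len(n),
    time_s = t0_s + (seq_len(n) - 0.5) * tr_s,
    petco2_mmHg = as.numeric(values_mmHg)
  )
  structure(out, tr_s = tr_s, t0_s = t0_s,
            class = c("cvr_regressor", class(out)))
}

#' PetCO2 values of a regressor
#'
#' @param regressor A `cvr_regressor`.
#' @return Numeric vector, one PetCO2 value (mmHg) per BOLD volume.
#' @export
regressor_values <- function(regressor) {
  stopifnot(inherits(regressor, "cvr_regressor"))
  regressor$petco2_mmHg
}

#' Sample the protocol schedule on the scanner TR grid
#'
#' Volume `i` is assigned the target at its temporal midpoint
#' `t0 + (i - 0.5) * TR`; midpoints past the protocol end take the baseline
#' value (baseline padding), so the regressor always has `n_volumes` rows.
#'
#' @param protocol A [hypercapnia_protocol()].
#' @param tr_s Repetition time (s).
#' @param n_volumes Number of BOLD volumes.
#' @param t0_s Acquisition start time relative to protocol start (s).
#' @return A `cvr_regressor` tibble with columns `volume`, `time_s`,
#'   `petco2_mmHg` and attributes `tr_s`, `t0_s`.
#' @examples
#' reg <- build_protocol_waveform(hypercapnia_protocol(), tr_s = 2, n_volumes = 255)
#' range(reg$petco2_mmHg) # 35 and 45 mmHg
#' @export
build_protocol_waveform <- function(protocol, tr_s = 2, n_volumes = 255, t0_s = 0) {
  stopifnot(inherits(protocol, "cvr_protocol"))
  check_number(tr_s, "tr_s", positive = TRUE)
  n_volumes <- check_count(n_volumes, "n_volumes", min = 1L)
  check_number(t0_s, "t0_s")
  mid <- t0_s + (seq_len(n_volumes) - 0.5) * tr_s
  new_regressor(protocol_target(protocol, mid), tr_s = tr_s, t0_s = t0_s)
}
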
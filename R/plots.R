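#' Plot a capnograph trace
#'
#' @param object A `capno_trace`.
#' @param end_tidal Optional `end_tidal` tibble to overlay as points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.capno_trace <- function(object, end_tidal = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time_s, y = .data$pco2_mmHg)) +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "airway pCO2 (mmHg)") +
    ggplot2::theme_minimal()
  if (!is.null(end_tidal)) {
    p <- p + ggplot2::geom_point(
      data = tibble::as_tibble(end_tidal),
      ggplot2::aes(x = .data$breath_time_s, y = .data$petco2_mmHg),
      colour = "firebrick", size = 1)
  }
  p
}

#' Plot a PetCO2 regressor on the TR grid
#'
#' @param object A `cvr_regressor`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cvr_regressor <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$petco2_mmHg)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "PetCO2 (mmHg)") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a CVR map
#'
#' @param object A `cvr_map`.
#' @param slice Axial (z) slice index; default the middle slice.
#' @param what `"slope"` or `"rvalue"`.
#' @param ... Unused.
#' @return A ggplot raster of the slice (invalid voxels blank).
#' @export
autoplot.cvr_map <- function(object, slice = NULL,
                             what = c("slope", "rvalue"), ...) {
  what <- match.arg(what)
  dims <- dim(object$valid)
  slice <- slice %||% ceiling(dims[3] / 2)
  arr <- object[[what]][, , slice]
  arr[!object$valid[, , slice]] <- NA
  df <- tidyr::expand_grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
  df$value <- arr[cbind(df$x, df$y)]
  lab <- if (what == "slope") "CVR (% BOLD / mmHg)" else "fit r"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey90", high = "red",
                                  midpoint = 0, na.value = "black", name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("axial slice z = %d", slice)) +
    ggplot2::theme_void()
}

#' Scatter of symptom score against a CVR index, by group
#'
#' @param cohort Cohort tibble.
#' @param cvr_var CVR column to plot (default `"brain_cvr"`).
#' @param visit Visit filter (default 1).
#' @return A ggplot with per-group least-squares lines.
#' @export
plot_cvr_symptoms <- function(cohort, cvr_var = "brain_cvr", visit = 1) {
  df <- cohort[cohort$visit == visit, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[cvr_var]], y = .data$scat2,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = sprintf("%s (%% BOLD / mmHg)", cvr_var), y = "SCAT2") +
    ggplot2::theme_minimal()
}
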
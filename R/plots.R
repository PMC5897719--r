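# ggplot2 displays for the main result types

#' Raster plot of network activity
#'
#' @param object A `network_activity` object.
#' @param ... Unused.
#'
#' @return A ggplot: one tick per detected event, ROIs on the vertical axis.
#' @method autoplot network_activity
#' @export
autoplot.network_activity <- function(object, ...) {
  raster <- build_raster(object)
  ggplot2::ggplot(
    raster,
    ggplot2::aes(x = .data$onset_time_s, y = factor(.data$roi_id))
  ) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::labs(
      x = "time (s)", y = "ROI",
      title = sprintf(
        "%d events in %d ROIs (mean MFR %.3g Hz)",
        nrow(raster), nrow(object$mfr), mean(object$mfr$mfr_hz)
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a dF/F0 trace with its smoothed copy and detected onsets
#'
#' Mirrors the conventional single-neuron activity display: the raw dF/F0
#' trace in grey, the de-noised trace on top, and detected event onsets as
#' points.
#'
#' @param traces A `ca_traces` tibble (see [normalize_traces()]).
#' @param roi ROI id to display.
#' @param activity Optional `network_activity` with detected events to mark.
#'
#' @return A ggplot.
#' @export
plot_trace <- function(traces, roi, activity = NULL) {
  df <- dplyr::filter(traces, .data$roi_id == roi)
  if (!nrow(df)) stop("ROI ", roi, " not found in `traces`", call. = FALSE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$dff), colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$dff_smooth), colour = "black") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F[0])) +
    ggplot2::theme_minimal()
  if (!is.null(activity)) {
    ev <- dplyr::filter(activity$events, .data$roi_id == roi)
    if (nrow(ev)) {
      ev <- dplyr::left_join(
        ev,
        df[, c("frame", "dff_smooth")],
        by = c(onset_frame = "frame")
      )
      p <- p + ggplot2::geom_point(
        data = ev,
        ggplot2::aes(x = .data$onset_time_s, y = .data$dff_smooth),
        colour = "red", size = 1.8
      )
    }
  }
  p
}

#' Plot a pressure-clamp recording with the detected activation threshold
#'
#' @param rec Recording tibble (`time_s`, `pressure_mmhg`, `current_pa`).
#' @param threshold Optional result of [detect_activation_threshold()].
#' @param downsample Keep every n-th sample for display (default 25).
#'
#' @return A ggplot with current and pressure panels.
#' @export
plot_recording <- function(rec, threshold = NULL, downsample = 25) {
  idx <- seq(1, nrow(rec), by = max(1, downsample))
  long <- rec[idx, ] |>
    tidyr::pivot_longer(
      c("current_pa", "pressure_mmhg"),
      names_to = "channel", values_to = "value"
    )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(threshold) && isTRUE(threshold$detected)) {
    p <- p + ggplot2::geom_vline(
      xintercept = threshold$crossing_time_s,
      linetype = "dashed", colour = "red"
    )
  }
  p
}
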
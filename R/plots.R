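#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a hypnogram
#'
#' Step plot of the epoch labels over time, WAKE on top, REM at the bottom,
#' with DOUBT epochs marked.
#'
#' @param object a `hypnogram` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.hypnogram <- function(object, ...) {
  lv <- c("REM", "NREM", "DOUBT", "WAKE")
  df <- tibble::tibble(
    time_min = object$start_s / 60,
    label = factor(object$label, levels = lv)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min,
                                   y = as.integer(.data$label))) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = seq_along(lv), labels = lv,
                                limits = c(1, length(lv))) +
    ggplot2::labs(x = "time (min)", y = NULL, title = "Hypnogram") +
    ggplot2::theme_minimal()
}

#' Plot a ventilation series with detected events
#'
#' Per-breath minute ventilation over time; detected apnoeas/hypopnoeas are
#' shaded when supplied.
#'
#' @param object a [minute_ventilation()] series.
#' @param events optional [detect_events()] tibble.
#' @param baseline optional per-breath baseline to overlay.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.vent_series <- function(object, events = NULL, baseline = NULL,
                                 ...) {
  df <- tibble::tibble(time_min = object$t_peak_s / 60,
                       ve = object$ve_ml_per_kg_min)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$ve)) +
    ggplot2::geom_line(linewidth = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = "time (min)",
                  y = expression(V[E] ~ "(mL" %.% kg^-1 %.% min^-1 * ")")) +
    ggplot2::theme_minimal()
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(time_min = object$t_peak_s / 60, ve = baseline),
      colour = "steelblue", linewidth = 0.3, na.rm = TRUE)
  }
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = tibble::tibble(xmin = events$start_s / 60,
                            xmax = events$end_s / 60,
                            kind = events$kind),
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf,
                   ymax = Inf, fill = .data$kind),
      alpha = 0.3, inherit.aes = FALSE)
  }
  p
}

#' Plot an occupancy heat map
#'
#' @param heatmap an [occupancy_heatmap()] tibble.
#' @return A ggplot tile map of dwell time.
#' @export
plot_occupancy <- function(heatmap) {
  ggplot2::ggplot(heatmap, ggplot2::aes(.data$x_cm, .data$y_cm,
                                        fill = .data$dwell_s)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "dwell (s)") +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' Plot per-state AHI and dyspnoea time from a recording summary
#'
#' @param summary a [compute_summary()] row (or several, row-bound).
#' @return A ggplot with events/h and s/h by state.
#' @export
plot_state_breakdown <- function(summary) {
  df <- tidyr::pivot_longer(
    summary[, c("ahi_nrem", "ahi_rem", "dyspnoea_s_nrem", "dyspnoea_s_rem")],
    dplyr::everything(), names_to = "key", values_to = "value")
  df$metric <- ifelse(grepl("^ahi", df$key), "events / h sleep",
                      "dyspnoeic s / h sleep")
  df$state <- ifelse(grepl("nrem", df$key), "NREM", "REM")
  ggplot2::ggplot(df, ggplot2::aes(.data$state, .data$value)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
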
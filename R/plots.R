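#' Plot a ranked scan
#'
#' Bar chart of the variance explained by the top results of a scan
#' (individual muscles or muscle combinations).
#'
#' @param object A `sv_rank_report`.
#' @param top Number of top rows to display (default 15).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sv_rank_report <- function(object, top = 15, ...) {
  df <- tibble::as_tibble(utils::head(object, top))
  label_cols <- intersect(c("muscle", "muscle_1", "muscle_2", "muscle_3",
                            "muscle_4"), names(df))
  df$label <- apply(df[label_cols], 1, paste, collapse = " + ")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$r2, y = stats::reorder(.data$label, .data$r2))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = expression(R^2 ~ "with peak sprint speed"),
      y = NULL,
      title = sprintf("Top %d results (%s scan)", nrow(df),
                      attr(object, "mode"))) +
    ggplot2::theme_minimal()
}

#' Plot combination improvement over individual muscles
#'
#' Scatter of combination R^2 against the lead muscle's individual R^2, one
#' point per lead muscle, with the no-improvement identity line dashed; the
#' vertical distance of each point above the line is the additional variance
#' explained by combining muscles.
#'
#' @param object A `sv_improvement` from [improvement_summary()].
#' @param label_top Number of leading points to label (default 5).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sv_improvement <- function(object, label_top = 5, ...) {
  df <- tibble::as_tibble(object)
  lab <- utils::head(dplyr::arrange(df, .data$lead_rank), label_top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$individual_r2,
                                   y = .data$combination_r2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$lead_muscle),
                       vjust = -0.7, size = 3) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = expression("individual muscle" ~ R^2),
      y = expression("combination" ~ R^2),
      title = sprintf("Gain from %s combinations", attr(object, "mode"))) +
    ggplot2::theme_minimal()
}

#' Plot the speed-extraction chain for one trial
#'
#' Distance, filtered distance, and the derived speed series with the
#' detected peak marked; a diagnostic for the trace-to-speed processing.
#'
#' @param trace A sprint trace (see [validate_trace()]).
#' @param cutoff_hz,order Filter settings as in [peak_speed()].
#' @return A ggplot object.
#' @export
plot_speed_chain <- function(trace, cutoff_hz = 1, order = 4) {
  validate_trace(trace)
  fs <- trace_sample_rate(trace)
  d <- distance_from_start(trace)
  f <- lowpass_1hz(d, fs, cutoff_hz = cutoff_hz, order = order)
  v <- differentiate(f, fs)
  k <- which.max(v)
  df <- tibble::tibble(
    t_s = rep(trace$t_s, 2),
    value = c(f, v),
    series = rep(c("filtered distance [m]", "speed [m/s]"),
                 each = nrow(trace))
  )
  peak <- tibble::tibble(t_s = trace$t_s[k], value = v[k],
                         series = "speed [m/s]")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(data = peak, color = "firebrick", size = 2) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL,
                  title = sprintf("Peak speed %.2f m/s at %.1f m",
                                  v[k], f[k])) +
    ggplot2::theme_minimal()
}
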
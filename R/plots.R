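#' Plot a peri-stimulus time histogram
#'
#' @param psth output of [compute_psth()].
#' @return a ggplot.
#' @export
plot_psth <- function(psth) {
  ggplot2::ggplot(psth, ggplot2::aes(x = .data$bin_mid, y = .data$rate)) +
    ggplot2::geom_col(width = psth$bin_end[1] - psth$bin_start[1],
      fill = "grey30"
    ) +
    ggplot2::labs(x = "time (s)", y = "firing rate (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a simulated firing-rate trace with its stimulus epochs
#'
#' @param trace output of [simulate_rate_trace()].
#' @param events optional stimulus-event table to shade light epochs.
#' @return a ggplot.
#' @export
plot_rate_trace <- function(trace, events = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_s, y = .data$rate_hz))
  if (!is.null(events)) {
    light <- events[events$kind == "light", ]
    if (nrow(light) > 0) {
      p <- p + ggplot2::annotate("rect",
        xmin = light$onset_s, xmax = light$offset_s,
        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "skyblue"
      )
    }
  }
  p + ggplot2::geom_line(color = "grey20") +
    ggplot2::labs(x = "time (s)", y = "rate (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot recovery timecourses by subtype or age
#'
#' Median percent recovery against recovery time, one line per group,
#' for a tidy recovery table (e.g. from [run_experiment()] or
#' [one_hour_timecourse()]`$recovery`).
#'
#' @param recovery tidy table with `time` (or `time_min`), `percent` and
#'   a grouping column.
#' @param group column (tidy-eval) to facet lines by, e.g. `label`.
#' @param metric which metric to plot.
#' @return a ggplot.
#' @export
plot_recovery <- function(recovery, group, metric = "total_spikes") {
  time_col <- if ("time" %in% names(recovery)) "time" else "time_min"
  df <- recovery %>%
    filter(.data$metric == !!metric, !is.na(.data$percent)) %>%
    group_by({{ group }}, time = .data[[time_col]]) %>%
    summarise(median_percent = median(.data$percent), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data$median_percent, color = {{ group }}
  )) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed", color = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "recovery time (min)", y = "median recovery (% of baseline)",
      title = metric
    ) +
    ggplot2::theme_minimal()
}

#' Plot mean cell densities by age and marker class
#'
#' @param summary output of [density_summary()].
#' @param classes marker classes to show.
#' @return a ggplot.
#' @export
plot_density_summary <- function(summary,
                                 classes = c(
                                   "mel_total", "mel_smi_neg", "mel_smi_pos"
                                 )) {
  df <- summary %>% filter(.data$class %in% classes)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$age_group, y = .data$mean_density, fill = .data$class
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_density - .data$sem,
        ymax = .data$mean_density + .data$sem
      ),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = expression(cells ~ mm^-2)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_recovery
#' @param object an `iprgc_timecourse` from [one_hour_timecourse()].
#' @param ... passed on.
#' @exportS3Method ggplot2::autoplot
autoplot.iprgc_timecourse <- function(object, ...) {
  plot_recovery(
    object$recovery %>% rename(time = "time_min"),
    group = .data$retina_id, ...
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
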
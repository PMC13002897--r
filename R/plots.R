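#' @importFrom ggplot2 ggplot aes geom_tile geom_point geom_line geom_errorbar
#'   geom_boxplot geom_rect labs scale_fill_gradient2 autoplot theme_minimal
NULL

#' Heatmap of an SR matrix
#'
#' Electrode-by-emitter tile plot of suppression ratios; positive (suppressed)
#' cells in blue, negative (promoted) cells in red.
#'
#' @param object an [sr_matrix()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sr_matrix
#' @export
autoplot.sr_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df, aes(x = factor(.data$emitter_id), y = factor(.data$electrode_id),
                 fill = .data$sr_percent)) +
    geom_tile() +
    scale_fill_gradient2(low = "firebrick", mid = "white", high = "navy",
                         midpoint = 0, name = "SR (%)") +
    labs(x = "emitter", y = "electrode",
         title = sprintf("Suppression ratios, pattern %s",
                         attr(object, "pattern_id"))) +
    theme_minimal()
}

#' Firing rates per emitter
#'
#' Stimulated versus baseline mean rates with SEM error bars, one panel-less
#' plot per unit x emitter combination.
#'
#' @param object a [firing_rates()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot firing_rate_result
#' @export
autoplot.firing_rate_result <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("stim_rate_hz", "baseline_rate_hz"),
                        names_to = "condition", values_to = "rate_hz") |>
    dplyr::mutate(sem = ifelse(.data$condition == "stim_rate_hz",
                               .data$stim_sem_hz, .data$baseline_sem_hz),
                  condition = ifelse(.data$condition == "stim_rate_hz",
                                     "stimulated", "baseline"))
  ggplot(df, aes(x = factor(.data$emitter_id), y = .data$rate_hz,
                 colour = .data$condition)) +
    geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    geom_errorbar(aes(ymin = .data$rate_hz - .data$sem,
                      ymax = .data$rate_hz + .data$sem),
                  width = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~unit_id, labeller = ggplot2::label_both) +
    labs(x = "emitter", y = "firing rate (Hz)") +
    theme_minimal()
}

#' Firing rate versus optical power
#'
#' @param object a [power_dependence()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot power_dependence_result
#' @export
autoplot.power_dependence_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df, aes(x = .data$power_uw, y = .data$stim_rate_hz,
                 group = factor(.data$unit_id), colour = factor(.data$unit_id))) +
    geom_line() + geom_point() +
    geom_errorbar(aes(ymin = .data$stim_rate_hz - .data$stim_sem_hz,
                      ymax = .data$stim_rate_hz + .data$stim_sem_hz), width = 0) +
    labs(x = "emission power (µW)", y = "mean in-pulse rate (Hz)",
         colour = "unit") +
    theme_minimal()
}

#' Pulse-locked spike raster
#'
#' One row per pulse; each dot a spike at its latency from the acquisition
#' window start; the pulse interval is shaded.
#'
#' @param spike_trains a spike-train tibble.
#' @param schedule a [stim_schedule()].
#' @param unit unit id to plot.
#' @param emitter emitter id whose pulses to lock to (default: all).
#' @param window_s,pulse_offset_s acquisition window as in
#'   [fraction_in_pulse()].
#' @return a ggplot.
#' @export
plot_raster <- function(spike_trains, schedule, unit, emitter = NULL,
                        window_s = 0.230, pulse_offset_s = 0.1) {
  t <- spike_trains$spike_times[[match(unit, spike_trains$unit_id)]]
  pulses <- schedule$pulses
  if (!is.null(emitter)) pulses <- pulses[pulses$emitter_id %in% emitter, ]
  events <- purrr::map_dfr(seq_len(nrow(pulses)), function(p) {
    w0 <- pulses$onset_s[p] - pulse_offset_s
    sel <- t >= w0 & t < w0 + window_s
    tibble::tibble(pulse_index = p, latency_s = t[sel] - w0)
  })
  pulse_dur <- if (nrow(pulses)) pulses$duration_s[1] else 0
  ggplot(events, aes(x = .data$latency_s, y = .data$pulse_index)) +
    geom_rect(xmin = pulse_offset_s, xmax = pulse_offset_s + pulse_dur,
              ymin = -Inf, ymax = Inf, fill = "lightskyblue", alpha = 0.4,
              inherit.aes = FALSE,
              data = tibble::tibble(x = 1)) +
    geom_point(shape = "|", size = 2) +
    labs(x = "time in window (s)", y = "pulse",
         title = sprintf("Unit %s raster", unit)) +
    theme_minimal()
}

#' Pre/during/post power comparison plot
#'
#' Boxplot of per-(electrode, pulse) activity power by phase, on a log scale.
#'
#' @param powers output of [pre_dur_post_powers()].
#' @return a ggplot.
#' @export
plot_power_comparison <- function(powers) {
  df <- dplyr::mutate(powers, phase = factor(.data$phase,
                                             levels = c("pre", "during", "post")))
  ggplot(df, aes(x = .data$phase, y = .data$p_uv2)) +
    geom_boxplot() +
    ggplot2::scale_y_log10() +
    labs(x = NULL, y = expression("neural activity power (" * mu * V^2 * ")")) +
    theme_minimal()
}

#' Stacked channel traces of a recording snippet
#'
#' @param recording a [new_recording()].
#' @param channels channel ids (default: all).
#' @param from_s,to_s window to display.
#' @param spacing_uv vertical offset between channels.
#' @return a ggplot.
#' @export
plot_traces <- function(recording, channels = NULL, from_s = 0,
                        to_s = min(duration_s(recording), from_s + 5),
                        spacing_uv = NULL) {
  df <- recording_tibble(recording, channels, from_s, to_s)
  spacing_uv <- spacing_uv %||% (4 * stats::sd(df$uv))
  df <- dplyr::mutate(df, offset = spacing_uv * match(.data$channel_id,
                                                      unique(.data$channel_id)))
  ggplot(df, aes(x = .data$time_s, y = .data$uv + .data$offset,
                 group = .data$channel_id)) +
    geom_line(linewidth = 0.2) +
    labs(x = "time (s)", y = "channel (offset traces)") +
    theme_minimal()
}
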
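#' Threshold spike detection
#'
#' Deterministic per-channel threshold detector, the stand-in for full spike
#' sorting when working with synthetic data (one putative unit per channel).
#' The robust noise level of each channel is estimated as the median absolute
#' deviation scaled by 1/0.6745 (the Gaussian-consistent robust SD); samples
#' whose absolute value exceeds `threshold_mads` times that level are grouped
#' into events, events closer than `refractory_ms` are collapsed onto the
#' largest absolute peak, and events whose waveform window touches a blanked
#' sample or the recording edge are discarded.
#'
#' @param recording a spike-band filtered [new_recording()].
#' @param threshold_mads detection threshold in robust SDs (default 5).
#' @param refractory_ms minimum event separation (default 1).
#' @param waveform_ms extracted waveform length (default 1.6).
#' @return tibble of class `spike_trains`: `unit_id`, `home_electrode`,
#'   `n_spikes`, `spike_times` (list of sorted times, s), `waveforms` (list
#'   of samples x events matrices, microvolts), `peak_amplitude_uv` (median
#'   over events of the absolute per-event peak).
#' @export
detect_spikes <- function(recording, threshold_mads = 5, refractory_ms = 1,
                          waveform_ms = 1.6) {
  if (!is.null(recording$band) && recording$band != "spike") {
    warn("detect_spikes expects a spike-band filtered recording")
  }
  rate <- recording$rate_hz
  n <- n_samples(recording)
  refr <- as.integer(round(refractory_ms / 1000 * rate))
  wf_len <- as.integer(round(waveform_ms / 1000 * rate)) + 1L
  pre_pk <- as.integer(round(wf_len * 0.3))
  rows <- purrr::map(seq_len(n_channels(recording)), function(j) {
    ch <- recording$channel_ids[j]
    v <- valid_mask(recording, ch)
    x <- recording$data[, j]
    if (!any(v)) {
      warn(sprintf("channel %d is fully masked; empty spike train", ch))
      return(list(ch = ch, times = numeric(0),
                  wf = matrix(numeric(0), nrow = wf_len, ncol = 0)))
    }
    sigma <- stats::mad(x[v])            # = MAD / 0.6745
    thr <- threshold_mads * sigma
    cand <- which(abs(x) > thr & v)
    if (!length(cand)) {
      return(list(ch = ch, times = numeric(0),
                  wf = matrix(numeric(0), nrow = wf_len, ncol = 0)))
    }
    grp <- cumsum(c(1L, diff(cand) > refr))
    peaks <- vapply(split(cand, grp), function(ii) ii[which.max(abs(x[ii]))],
                    integer(1))
    i1 <- peaks - pre_pk
    i2 <- i1 + wf_len - 1L
    keep <- i1 >= 1L & i2 <= n
    if (any(keep) && !is.null(recording$blank_mask)) {
      bad_touch <- vapply(which(keep), function(k) {
        any(recording$blank_mask[i1[k]:i2[k]])
      }, logical(1))
      keep[which(keep)[bad_touch]] <- FALSE
    }
    peaks <- peaks[keep]
    if (!length(peaks)) {
      return(list(ch = ch, times = numeric(0),
                  wf = matrix(numeric(0), nrow = wf_len, ncol = 0)))
    }
    wf <- vapply(peaks, function(p) x[(p - pre_pk):(p - pre_pk + wf_len - 1L)],
                 numeric(wf_len))
    list(ch = ch, times = (peaks - 1) / rate, wf = wf)
  })
  tibble::tibble(
    unit_id = purrr::map_int(rows, "ch"),
    home_electrode = purrr::map_int(rows, "ch"),
    n_spikes = purrr::map_int(rows, function(r) length(r$times)),
    spike_times = purrr::map(rows, "times"),
    waveforms = purrr::map(rows, "wf"),
    peak_amplitude_uv = purrr::map_dbl(rows, function(r) {
      if (!ncol(r$wf)) return(NA_real_)
      median(apply(abs(r$wf), 2, max))
    })
  )
}

#' Unit quality metrics and gating
#'
#' Computes, per unit, the peak amplitude (median over events of the absolute
#' per-event peak), the spike count, and the inter-spike-interval violation
#' ratio (fraction of ISIs shorter than `refractory_ms`; 0 by convention for
#' fewer than two spikes), then gates on the curation thresholds: amplitude
#' >= 30 microvolts, count >= 200, ISI ratio <= 0.5 at a 2-ms refractory
#' period.
#'
#' @param spike_trains a spike-train tibble ([detect_spikes()] or
#'   [spike_trains_from_ground_truth()]).
#' @param refractory_ms refractory period for the ISI ratio (default 2).
#' @param min_amplitude_uv,min_count,max_isi_ratio gating thresholds.
#' @return tibble: `unit_id`, `peak_amplitude_uv`, `spike_count`,
#'   `isi_violation_ratio`, `passes`.
#' @export
unit_quality <- function(spike_trains, refractory_ms = 2,
                         min_amplitude_uv = 30, min_count = 200,
                         max_isi_ratio = 0.5) {
  refr <- refractory_ms / 1000
  tibble::tibble(
    unit_id = spike_trains$unit_id,
    peak_amplitude_uv = spike_trains$peak_amplitude_uv,
    spike_count = purrr::map_int(spike_trains$spike_times, length),
    isi_violation_ratio = purrr::map_dbl(spike_trains$spike_times, function(t) {
      if (length(t) < 2) return(0)
      isi <- diff(t)
      mean(isi < refr)
    })
  ) |>
    dplyr::mutate(passes = .data$peak_amplitude_uv >= min_amplitude_uv &
                    .data$spike_count >= min_count &
                    .data$isi_violation_ratio <= max_isi_ratio)
}

#' Fraction of spikes falling inside the optical pulse
#'
#' Over all pulses of one emitter, places a fixed acquisition window of
#' `window_s` starting `pulse_offset_s` before each pulse onset, pools the
#' spikes across pulses, and returns the fraction of window spikes that fall
#' inside the pulse interval. With a 230-ms window around a 30-ms pulse this
#' is the raster-plot in-pulse fraction.
#'
#' @param spike_trains a spike-train tibble.
#' @param schedule a [stim_schedule()].
#' @param emitter emitter id whose pulses to use (default: all pulses).
#' @param window_s acquisition window length (default 0.230); must be at
#'   least the pulse duration.
#' @param pulse_offset_s window start relative to pulse onset (default 0.1,
#'   i.e. the window opens 100 ms before the pulse).
#' @return tibble: `unit_id`, `n_window`, `n_in_pulse`, `fraction` (`NA` when
#'   no spikes fall in any window).
#' @export
fraction_in_pulse <- function(spike_trains, schedule, emitter = NULL,
                              window_s = 0.230, pulse_offset_s = 0.1) {
  pulses <- schedule$pulses
  if (!is.null(emitter)) pulses <- pulses[pulses$emitter_id %in% emitter, ]
  if (nrow(pulses) && any(window_s < pulses$duration_s)) {
    abort("window_s must be at least the pulse duration",
          class = "probeseize_invalid_argument")
  }
  w0 <- pulses$onset_s - pulse_offset_s
  w1 <- w0 + window_s
  p0 <- pulses$onset_s
  p1 <- pulses$onset_s + pulses$duration_s
  res <- purrr::map(spike_trains$spike_times, function(t) {
    if (!nrow(pulses)) return(c(0L, 0L))
    in_win <- 0L
    in_pulse <- 0L
    for (p in seq_len(nrow(pulses))) {
      sel <- t >= w0[p] & t < w1[p]
      in_win <- in_win + sum(sel)
      in_pulse <- in_pulse + sum(sel & t >= p0[p] & t < p1[p])
    }
    c(in_win, in_pulse)
  })
  tibble::tibble(
    unit_id = spike_trains$unit_id,
    n_window = purrr::map_int(res, function(v) as.integer(v[1])),
    n_in_pulse = purrr::map_int(res, function(v) as.integer(v[2]))
  ) |>
    dplyr::mutate(fraction = ifelse(.data$n_window > 0,
                                    .data$n_in_pulse / .data$n_window, NA_real_))
}

# Baseline intervals before a train start: [start - baseline_s, start),
# minus every pulse interval; returns matrix of (a, b) rows.
baseline_intervals <- function(train_start, baseline_s, pulses) {
  a <- max(0, train_start - baseline_s)
  b <- train_start
  if (b <= a) return(matrix(numeric(0), ncol = 2))
  ivs <- matrix(c(a, b), ncol = 2)
  for (p in seq_len(nrow(pulses))) {
    pa <- pulses$onset_s[p]
    pb <- pa + pulses$duration_s[p]
    out <- matrix(numeric(0), ncol = 2)
    for (r in seq_len(nrow(ivs))) {
      x <- ivs[r, 1]; y <- ivs[r, 2]
      if (pb <= x || pa >= y) {
        out <- rbind(out, c(x, y))
      } else {
        if (pa > x) out <- rbind(out, c(x, pa))
        if (pb < y) out <- rbind(out, c(pb, y))
      }
    }
    ivs <- out
    if (!nrow(ivs)) break
  }
  ivs
}

#' Pulse-locked and baseline firing rates
#'
#' For every unit and emitter: the stimulated rate is the mean over that
#' emitter's pulses of (spike count in pulse / pulse duration), with SEM over
#' pulses. The baseline rate is computed per train from the `baseline_s`
#' seconds preceding the train start (truncated to exclude any pulse
#' intervals), then averaged over trains with SEM over trains; it is shared
#' across emitters for a unit.
#'
#' @param spike_trains a spike-train tibble.
#' @param schedule a [stim_schedule()] whose pulses carry `train_id`.
#' @param baseline_s baseline window per train (default 10).
#' @return tibble of class `firing_rate_result`: `unit_id`, `home_electrode`,
#'   `emitter_id`, `n_pulses`, `stim_rate_hz`, `stim_sem_hz`,
#'   `baseline_rate_hz`, `baseline_sem_hz`, `n_trains`.
#' @export
firing_rates <- function(spike_trains, schedule, baseline_s = 10) {
  pulses <- schedule$pulses
  if (!nrow(pulses)) {
    abort("schedule has no pulses", class = "probeseize_invalid_schedule")
  }
  trains <- pulses |>
    dplyr::group_by(.data$train_id) |>
    dplyr::summarise(start_s = min(.data$onset_s), .groups = "drop")
  base_ivs <- purrr::map(trains$start_s, baseline_intervals,
                         baseline_s = baseline_s, pulses = pulses)
  out <- purrr::map_dfr(seq_len(nrow(spike_trains)), function(u) {
    t <- spike_trains$spike_times[[u]]
    base_rates <- purrr::map_dbl(base_ivs, function(iv) {
      len <- sum(iv[, 2] - iv[, 1])
      if (len <= 0) return(NA_real_)
      cnt <- 0L
      for (r in seq_len(nrow(iv))) cnt <- cnt + sum(t >= iv[r, 1] & t < iv[r, 2])
      cnt / len
    })
    base_rates <- base_rates[is.finite(base_rates)]
    per_pulse <- purrr::map_dbl(seq_len(nrow(pulses)), function(p) {
      sum(t >= pulses$onset_s[p] & t < pulses$onset_s[p] + pulses$duration_s[p]) /
        pulses$duration_s[p]
    })
    tibble::tibble(emitter_id = pulses$emitter_id, rate = per_pulse) |>
      dplyr::group_by(.data$emitter_id) |>
      dplyr::summarise(n_pulses = dplyr::n(),
                       stim_rate_hz = mean(.data$rate),
                       stim_sem_hz = sem(.data$rate), .groups = "drop") |>
      dplyr::mutate(unit_id = spike_trains$unit_id[u],
                    home_electrode = spike_trains$home_electrode[u],
                    baseline_rate_hz = if (length(base_rates)) mean(base_rates) else 0,
                    baseline_sem_hz = sem(base_rates),
                    n_trains = length(base_rates))
  })
  out <- dplyr::select(out, "unit_id", "home_electrode", "emitter_id",
                       "n_pulses", "stim_rate_hz", "stim_sem_hz",
                       "baseline_rate_hz", "baseline_sem_hz", "n_trains")
  class(out) <- c("firing_rate_result", class(out))
  out
}

#' Firing rate versus optical power
#'
#' Groups pulses by emission power level and returns, per unit, the mean
#' in-pulse rate and SEM at each level, sorted by ascending power.
#'
#' @param spike_trains a spike-train tibble.
#' @param schedule a [stim_schedule()] with a `power_uw` column.
#' @return tibble of class `power_dependence_result`: `unit_id`, `power_uw`,
#'   `n_pulses`, `stim_rate_hz`, `stim_sem_hz`.
#' @export
power_dependence <- function(spike_trains, schedule) {
  pulses <- schedule$pulses
  if (!nrow(pulses)) {
    abort("schedule has no pulses", class = "probeseize_invalid_schedule")
  }
  out <- purrr::map_dfr(seq_len(nrow(spike_trains)), function(u) {
    t <- spike_trains$spike_times[[u]]
    per_pulse <- purrr::map_dbl(seq_len(nrow(pulses)), function(p) {
      sum(t >= pulses$onset_s[p] & t < pulses$onset_s[p] + pulses$duration_s[p]) /
        pulses$duration_s[p]
    })
    tibble::tibble(unit_id = spike_trains$unit_id[u],
                   power_uw = pulses$power_uw, rate = per_pulse) |>
      dplyr::group_by(.data$unit_id, .data$power_uw) |>
      dplyr::summarise(n_pulses = dplyr::n(),
                       stim_rate_hz = mean(.data$rate),
                       stim_sem_hz = sem(.data$rate), .groups = "drop") |>
      dplyr::arrange(.data$power_uw)
  })
  class(out) <- c("power_dependence_result", class(out))
  out
}

#' Spatial selectivity of photostimulation
#'
#' Joins a firing-rate table with the probe geometry: for every unit and
#' tested emitter, the distance from the unit's home electrode to the emitter
#' and the rate change (stimulated minus baseline), sorted by distance.
#'
#' @param rates a [firing_rates()] result.
#' @param layout a [probe_layout()].
#' @return tibble: `unit_id`, `emitter_id`, `distance_um`,
#'   `rate_change_hz`, plus the input rate columns.
#' @export
spatial_selectivity <- function(rates, layout) {
  d <- electrode_emitter_distance(layout, rates$home_electrode, rates$emitter_id)
  rates |>
    dplyr::mutate(distance_um = d,
                  rate_change_hz = .data$stim_rate_hz - .data$baseline_rate_hz) |>
    dplyr::arrange(.data$unit_id, .data$distance_um)
}
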
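#' Simulate a multichannel probe recording with ground truth
#'
#' Generates a seeded synthetic extracellular recording on a probe layout:
#'
#' * baseline noise: a mixture of 1/f-weighted ("pink") and white Gaussian
#'   noise at `noise_sd_uv`;
#' * an epileptiform component after `seizure$onset_s`: a periodic
#'   spike-and-wave train whose amplitude decays exponentially with electrode
#'   distance from the microfluidic outlet, optionally sign-inverted across
#'   the outlet, and multiplied by `suppression_factor` during each scheduled
#'   pulse;
#' * Poisson single-unit spiking (rate = baseline plus a power- and
#'   distance-dependent term during pulses) rendered as biphasic templates
#'   whose amplitude decays across neighbouring electrodes;
#' * rectangular stimulus artifacts inside both edges of every pulse;
#' * slow 1-Hz drift on the four electrodes nearest the outlet during
#'   injection epochs.
#'
#' Identical `(config, schedule, layout)` give bit-identical output.
#'
#' @param config a [sim_config()].
#' @param schedule a [stim_schedule()] (default: empty).
#' @param layout a [probe_layout()] (default: [default_layout()]).
#' @return list with elements `recording` (a [new_recording()]) and
#'   `ground_truth` (list: `spikes` tibble with list-column `spike_times`,
#'   `seizure_base` suppressed base trace, `seizure_gain` per channel,
#'   `suppression_factor`, `artifact_intervals` tibble of sample indices,
#'   `seizure_onset_s`).
#' @export
simulate_recording <- function(config, schedule = stim_schedule(),
                               layout = default_layout()) {
  stopifnot(inherits(config, "sim_config"), inherits(schedule, "stim_schedule"),
            inherits(layout, "probe_layout"))
  rate <- config$sampling_rate_hz
  n <- as.integer(round(config$duration_s * rate))
  if (config$duration_s < schedule_end(schedule) - 1e-9) {
    abort("recording duration is shorter than the schedule",
          class = "probeseize_invalid_config")
  }
  electrodes <- layout$electrodes
  n_ch <- nrow(electrodes)
  ss <- derive_subseeds(config$seed, 3)

  # --- seizure base trace (seeded substream) -----------------------------
  z <- with_seed(ss[3], seizure_base_trace(config, n, rate))
  s <- config$suppression_factor
  uniform_suppression <- is.infinite(config$suppression_space_constant_um)
  pulses <- schedule$pulses
  if (uniform_suppression && nrow(pulses) && !is.null(z)) {
    for (p in seq_len(nrow(pulses))) {
      idx <- samples_in(pulses$onset_s[p], pulses$onset_s[p] + pulses$duration_s[p],
                        rate, n)
      z[idx] <- z[idx] * s
    }
  }
  gains <- seizure_channel_gains(config, layout)

  # --- noise + seizure assembly ------------------------------------------
  data <- with_seed(ss[1], {
    mat <- matrix(0, nrow = n, ncol = n_ch)
    for (ch in seq_len(n_ch)) {
      col <- sim_noise(n, rate, config$noise_sd_uv, config$pink_fraction)
      if (!is.null(z)) {
        if (uniform_suppression) {
          col <- col + gains[ch] * z
        } else {
          zc <- z
          for (p in seq_len(nrow(pulses))) {
            d <- electrode_emitter_distance(layout,
                                            electrodes$electrode_id[ch],
                                            pulses$emitter_id[p])
            f <- 1 - (1 - s) * exp(-d / config$suppression_space_constant_um)
            idx <- samples_in(pulses$onset_s[p],
                              pulses$onset_s[p] + pulses$duration_s[p], rate, n)
            zc[idx] <- zc[idx] * f
          }
          col <- col + gains[ch] * zc
        }
      }
      mat[, ch] <- col
    }
    mat
  })

  # --- unit spikes --------------------------------------------------------
  gt_spikes <- with_seed(ss[2], sim_spike_times(config, schedule, layout))
  if (nrow(gt_spikes)) {
    data <- render_spikes(data, gt_spikes, config, layout, rate)
  }

  # --- stimulus edge artifacts -------------------------------------------
  artifact_intervals <- tibble::tibble(start_sample = integer(),
                                       end_sample = integer())
  w <- config$artifact$edge_width_ms / 1000
  amp <- config$artifact$edge_amplitude_uv
  if (nrow(pulses) && amp > 0 && w > 0) {
    rows <- vector("list", 2L * nrow(pulses))
    for (p in seq_len(nrow(pulses))) {
      on <- pulses$onset_s[p]
      off <- on + pulses$duration_s[p]
      idx_on <- samples_in(on, min(on + w, off), rate, n)
      idx_off <- samples_in(max(off - w, on), off, rate, n)
      if (length(idx_on)) data[idx_on, ] <- data[idx_on, ] + amp
      if (length(idx_off)) data[idx_off, ] <- data[idx_off, ] - amp
      rows[[2L * p - 1L]] <- c(idx_on[1] %||% NA_integer_, idx_on[length(idx_on)] %||% NA_integer_)
      rows[[2L * p]] <- c(idx_off[1] %||% NA_integer_, idx_off[length(idx_off)] %||% NA_integer_)
    }
    iv <- do.call(rbind, rows)
    keep <- !is.na(iv[, 1])
    artifact_intervals <- tibble::tibble(start_sample = as.integer(iv[keep, 1]),
                                         end_sample = as.integer(iv[keep, 2]))
  }

  # --- injection drift on the 4 outlet-proximal electrodes ---------------
  inj <- schedule$injections
  if (nrow(inj) && config$injection_drift_uv > 0) {
    d_out <- electrode_outlet_distance(layout, electrodes$electrode_id)
    near <- order(d_out)[seq_len(min(4L, n_ch))]
    for (k in seq_len(nrow(inj))) {
      idx <- samples_in(inj$onset_s[k], inj$onset_s[k] + inj$duration_s[k], rate, n)
      if (!length(idx)) next
      drift <- config$injection_drift_uv * sin(2 * pi * 1.0 * (idx - 1) / rate)
      for (ch in near) data[idx, ch] <- data[idx, ch] + drift
    }
  }

  rec <- new_recording(data, rate, channel_ids = electrodes$electrode_id,
                       layout = layout, steps = "simulate")
  gt <- list(
    spikes = gt_spikes,
    seizure_base = z,
    seizure_gain = stats::setNames(gains, electrodes$electrode_id),
    suppression_factor = s,
    artifact_intervals = artifact_intervals,
    seizure_onset_s = config$seizure$onset_s
  )
  list(recording = rec, ground_truth = gt)
}

# 1/f-weighted + white Gaussian noise mixture, unit-variance components
# scaled to `sd_uv`. FFT-shaped over a fast length, truncated to n.
sim_noise <- function(n, rate, sd_uv, pink_fraction) {
  if (sd_uv <= 0) return(numeric(n))
  white <- rnorm(n)
  if (pink_fraction <= 0) return(sd_uv * white)
  m <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(m)
  f <- seq(0, m - 1) / m * rate
  f <- pmin(f, rate - f)                 # two-sided frequency axis
  h <- 1 / sqrt(pmax(f, 1))              # 1/f power below is flattened at 1 Hz
  h[1] <- 0                              # no DC
  pink <- Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / m
  pink <- pink[seq_len(n)]
  pink <- pink / stats::sd(pink)
  sd_uv * (sqrt(pink_fraction) * pink + sqrt(1 - pink_fraction) * white)
}

# Spike-and-wave template: sharp biphasic transient + slower opposing wave,
# ~250 ms support, dominant energy in the 5-300 Hz LFP band.
spike_wave_template <- function(rate) {
  tt <- seq(-0.125, 0.125, by = 1 / rate)
  sharp <- (tt / 0.008) * exp(0.5 - 0.5 * (tt / 0.008)^2)
  wave <- -0.45 * exp(-0.5 * ((tt - 0.07) / 0.035)^2)
  tmpl <- sharp + wave
  tmpl / max(abs(tmpl))
}

# Periodic spike-and-wave train starting at seizure onset; event centers at
# onset + (k + 1/2) / burst_rate (plus bounded jitter) so analysis windows
# that are multiples of the period hold matched seizure power.
# Returns NULL when disabled.
seizure_base_trace <- function(config, n, rate) {
  sz <- config$seizure
  if (!is.finite(sz$onset_s) || sz$onset_s >= n / rate || sz$burst_amplitude_uv <= 0 ||
      sz$burst_rate_hz <= 0) {
    return(NULL)
  }
  z <- numeric(n)
  tmpl <- spike_wave_template(rate)
  half <- (length(tmpl) - 1) %/% 2
  period <- 1 / sz$burst_rate_hz
  centers <- seq(sz$onset_s + period / 2, n / rate, by = period)
  tj <- sz$time_jitter_frac %||% 0
  if (tj > 0) {
    centers <- centers + runif(length(centers), -tj * period, tj * period)
  }
  env <- if (is.infinite(sz$afterdischarge_decay_s)) rep(1, length(centers)) else
    exp(-(centers - sz$onset_s) / sz$afterdischarge_decay_s)
  aj <- sz$amplitude_jitter %||% 0
  if (aj > 0) {
    env <- env * pmax(0, 1 + aj * rnorm(length(centers)))
  }
  for (k in seq_along(centers)) {
    c_idx <- as.integer(round(centers[k] * rate)) + 1L
    i1 <- c_idx - half
    i2 <- c_idx + half
    j1 <- max(1L, i1); j2 <- min(n, i2)
    if (j2 < j1) next
    z[j1:j2] <- z[j1:j2] + sz$burst_amplitude_uv * env[k] * tmpl[(j1 - i1 + 1L):(j2 - i1 + 1L)]
  }
  z
}

seizure_channel_gains <- function(config, layout) {
  ids <- layout$electrodes$electrode_id
  d <- electrode_outlet_distance(layout, ids)
  g <- exp(-d / config$outlet_space_constant_um)
  if (isTRUE(config$polarity_inversion)) {
    sign <- ifelse(layout$electrodes$axial_um >= layout$outlet[["axial_um"]], 1, -1)
    g <- g * sign
  }
  g
}

#' Draw ground-truth spike times for the configured units
#'
#' Poisson superposition: a homogeneous baseline process over the whole
#' recording plus, within each pulse, an extra process at
#' `gain_per_uw * power_uw * exp(-d_emitter / distance_constant_um)`.
#' Exposed for fast rate-law tests that do not need a rendered voltage trace;
#' note it consumes the current RNG stream (seed it yourself), whereas
#' [simulate_recording()] seeds it from `config$seed`.
#'
#' @inheritParams simulate_recording
#' @return tibble: `unit_id`, `home_electrode`, `spike_times` (list-column of
#'   sorted times in seconds).
#' @export
sim_spike_times <- function(config, schedule, layout) {
  units <- config$units
  if (nrow(units) == 0) {
    return(tibble::tibble(unit_id = integer(), home_electrode = integer(),
                          spike_times = list()))
  }
  dur <- config$duration_s
  pulses <- schedule$pulses
  out <- purrr::pmap(units, function(unit_id, home_electrode, baseline_rate_hz,
                                     gain_per_uw, distance_constant_um,
                                     amplitude_uv) {
    times <- if (baseline_rate_hz > 0) {
      sort(runif(rpois(1, baseline_rate_hz * dur), 0, dur))
    } else numeric(0)
    if (nrow(pulses)) {
      d <- electrode_emitter_distance(layout, home_electrode, pulses$emitter_id)
      lambda_extra <- gain_per_uw * pulses$power_uw * exp(-d / distance_constant_um)
      for (p in seq_len(nrow(pulses))) {
        k <- rpois(1, lambda_extra[p] * pulses$duration_s[p])
        if (k > 0) {
          times <- c(times, runif(k, pulses$onset_s[p],
                                  pulses$onset_s[p] + pulses$duration_s[p]))
        }
      }
      times <- sort(times)
    }
    times[times >= 0 & times < dur]
  })
  tibble::tibble(unit_id = units$unit_id,
                 home_electrode = units$home_electrode,
                 spike_times = out)
}

# Biphasic extracellular spike template, 1.6 ms, negative peak normalized
# to -1; returns list(shape, peak_index).
spike_template <- function(rate) {
  l <- as.integer(round(0.0016 * rate)) + 1L
  tt <- (seq_len(l) - 1) / rate
  shape <- -exp(-0.5 * ((tt - 4e-4) / 1.2e-4)^2) +
    0.4 * exp(-0.5 * ((tt - 9e-4) / 2.5e-4)^2)
  peak <- which.min(shape)
  list(shape = shape / abs(min(shape)), peak = peak)
}

render_spikes <- function(data, gt_spikes, config, layout, rate) {
  tmpl <- spike_template(rate)
  l <- length(tmpl$shape)
  n <- nrow(data)
  electrodes <- layout$electrodes
  for (u in seq_len(nrow(gt_spikes))) {
    times <- gt_spikes$spike_times[[u]]
    if (!length(times)) next
    home <- gt_spikes$home_electrode[u]
    amp0 <- config$units$amplitude_uv[config$units$unit_id == gt_spikes$unit_id[u]][1]
    d <- electrode_pair_distance(layout, rep(home, nrow(electrodes)),
                                 electrodes$electrode_id)
    reach <- which(d <= 5 * config$spike_space_constant_um)
    amps <- amp0 * exp(-d[reach] / config$spike_space_constant_um)
    starts <- as.integer(round(times * rate)) + 1L - (tmpl$peak - 1L)
    for (e in seq_along(times)) {
      i1 <- starts[e]; i2 <- i1 + l - 1L
      if (i1 < 1L || i2 > n) next
      for (k in seq_along(reach)) {
        data[i1:i2, reach[k]] <- data[i1:i2, reach[k]] + amps[k] * tmpl$shape
      }
    }
  }
  data
}

#' Spike trains from simulator ground truth
#'
#' Bypasses detection: converts the ground-truth spike table of
#' [simulate_recording()] into the spike-train format used by the analysis
#' functions (no waveforms; amplitudes taken from the generating unit table
#' when supplied).
#'
#' @param ground_truth the `ground_truth` element returned by
#'   [simulate_recording()].
#' @param units optional [unit_table()] supplying amplitudes.
#' @return a spike-train tibble as returned by [detect_spikes()].
#' @export
spike_trains_from_ground_truth <- function(ground_truth, units = NULL) {
  gs <- ground_truth$spikes
  amp <- rep(NA_real_, nrow(gs))
  if (!is.null(units)) {
    amp <- units$amplitude_uv[match(gs$unit_id, units$unit_id)]
  }
  tibble::tibble(
    unit_id = gs$unit_id,
    home_electrode = gs$home_electrode,
    n_spikes = purrr::map_int(gs$spike_times, length),
    spike_times = gs$spike_times,
    waveforms = vector("list", nrow(gs)),
    peak_amplitude_uv = amp
  )
}
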
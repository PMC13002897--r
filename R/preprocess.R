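#' Bandpass filter specification
#'
#' Zero-phase Butterworth bandpass. `order` is the order of the underlying
#' lowpass prototype (the bandpass has twice as many poles); the filter is
#' applied forward and backward so the net magnitude response is the square
#' of the single-pass response and the group delay is zero.
#'
#' @param low_hz,high_hz corner frequencies; `0 < low_hz < high_hz < rate/2`.
#' @param order Butterworth prototype order (default 4).
#' @param zero_phase apply forward-backward (default `TRUE`).
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(low_hz, high_hz, order = 4, zero_phase = TRUE) {
  if (!(low_hz > 0 && high_hz > low_hz)) {
    abort("need 0 < low_hz < high_hz", class = "probeseize_invalid_filter")
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 zero_phase = zero_phase), class = "filter_spec")
}

#' Canonical band presets
#'
#' The spike band (300-6000 Hz) for unit activity; the LFP band (5-300 Hz)
#' for field-potential / seizure-power analysis.
#'
#' @param band `"spike"` or `"lfp"`.
#' @return a [filter_spec()].
#' @export
band_spec <- function(band = c("spike", "lfp")) {
  band <- match.arg(band)
  if (band == "spike") filter_spec(300, 6000) else filter_spec(5, 300)
}

#' Common average referencing
#'
#' Subtracts, at every sample, the mean across the in-brain recording
#' channels from each of those channels, removing shared noise. Channels
#' outside the set (outside the brain, or listed as bad) are passed through
#' unreferenced and recorded in `unreferenced_channels`. Bad channels never
#' contribute to the mean.
#'
#' @param recording a [new_recording()].
#' @param in_brain_channels channel ids to reference over; defaults to the
#'   layout's in-brain electrodes minus `bad_channels`.
#' @return the referenced recording; the per-sample mean over the referenced
#'   set is 0 to numerical precision.
#' @export
common_average_reference <- function(recording, in_brain_channels = NULL) {
  if (is.null(in_brain_channels)) {
    in_brain_channels <- if (!is.null(recording$layout)) {
      setdiff(in_brain_electrodes(recording$layout), recording$bad_channels)
    } else {
      good_channels(recording)
    }
  }
  in_brain_channels <- setdiff(in_brain_channels, recording$bad_channels)
  if (length(in_brain_channels) == 0) {
    abort("in-brain channel set is empty", class = "probeseize_invalid_argument")
  }
  cols <- channel_index(recording, in_brain_channels)
  n <- n_samples(recording)
  cm <- numeric(n)
  for (j in cols) cm <- cm + recording$data[, j]
  cm <- cm / length(cols)
  for (j in cols) recording$data[, j] <- recording$data[, j] - cm
  recording$unreferenced_channels <- setdiff(recording$channel_ids, in_brain_channels)
  recording$steps <- c(recording$steps, "car")
  recording
}

#' Zero-phase bandpass filtering
#'
#' The Butterworth bandpass is designed and applied as a cascade of
#' second-order sections (stable even for the 5-Hz LFP corner at a 30-kHz
#' rate, where the expanded transfer-function form is not); the zero-phase
#' pass is a forward-backward application with odd-reflect padding sized to
#' the low corner (3 cycles), which keeps edge transients out of the data.
#'
#' @param recording a [new_recording()].
#' @param spec a [filter_spec()], or a band name (`"spike"`/`"lfp"`).
#' @return the filtered recording with `band` set when a preset was used.
#' @export
bandpass <- function(recording, spec = c("spike", "lfp")) {
  band <- NULL
  if (is.character(spec)) {
    band <- match.arg(spec)
    spec <- band_spec(band)
  }
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- recording$rate_hz / 2
  if (spec$high_hz >= nyq) {
    abort(sprintf("high corner %g Hz >= Nyquist %g Hz", spec$high_hz, nyq),
          class = "probeseize_invalid_filter")
  }
  sos <- butter_bandpass_sos(spec$order, spec$low_hz, spec$high_hz,
                             recording$rate_hz)
  pad <- as.integer(min(n_samples(recording) - 1,
                        max(9 * (2 * spec$order + 1),
                            ceiling(3 * recording$rate_hz / spec$low_hz))))
  for (j in seq_len(n_channels(recording))) {
    recording$data[, j] <- zero_phase_filter(sos, recording$data[, j],
                                             pad, spec$zero_phase)
  }
  recording$band <- band %||% recording$band
  recording$steps <- c(recording$steps,
                       sprintf("bandpass(%g-%g Hz)", spec$low_hz, spec$high_hz))
  recording
}

# Forward(-backward) second-order-section filtering with odd-reflect padding.
zero_phase_filter <- function(sos, x, pad, zero_phase = TRUE) {
  n <- length(x)
  pad <- min(pad, n - 1)
  xp <- c(2 * x[1] - x[seq(pad + 1, 2)], x, 2 * x[n] - x[seq(n - 1, n - pad)])
  y <- apply_sos(xp, sos)
  if (zero_phase) {
    y <- rev(apply_sos(rev(y), sos))
  }
  y[(pad + 1):(pad + n)]
}

#' Blank photostimulation artifacts
#'
#' Marks as invalid the first and last `blank_ms` milliseconds of every
#' scheduled pulse, on all channels. Sample values are untouched: blanking is
#' masking, not zeroing, and masked samples are excluded from the sample
#' count of every downstream power estimate and from spike windows. If
#' `2 * blank_ms` meets or exceeds a pulse duration the whole pulse is
#' masked, with a warning.
#'
#' @param recording a [new_recording()].
#' @param schedule a [stim_schedule()] whose pulses lie within the recording.
#' @param blank_ms milliseconds blanked at each pulse edge (default 5).
#' @return the recording with an updated blanking mask.
#' @export
blank_stim_artifacts <- function(recording, schedule, blank_ms = 5) {
  pulses <- schedule$pulses
  n <- n_samples(recording)
  rate <- recording$rate_hz
  if (nrow(pulses) && max(pulses$onset_s + pulses$duration_s) > duration_s(recording) + 1e-9) {
    abort("schedule pulses extend beyond the recording",
          class = "probeseize_invalid_schedule")
  }
  mask <- recording$blank_mask %||% rep(FALSE, n)
  b <- blank_ms / 1000
  for (p in seq_len(nrow(pulses))) {
    on <- pulses$onset_s[p]
    off <- on + pulses$duration_s[p]
    if (2 * b >= pulses$duration_s[p]) {
      warn(sprintf("blank_ms covers pulse %d entirely; masking whole pulse", p))
      mask[samples_in(on, off, rate, n)] <- TRUE
    } else {
      mask[samples_in(on, on + b, rate, n)] <- TRUE
      mask[samples_in(off - b, off, rate, n)] <- TRUE
    }
  }
  recording$blank_mask <- mask
  recording$steps <- c(recording$steps, sprintf("blank(%g ms)", blank_ms))
  recording
}

#' Mark channels as non-functional
#'
#' @param recording a [new_recording()].
#' @param channels channel ids to exclude from referencing and all statistics.
#' @return the updated recording.
#' @export
set_bad_channels <- function(recording, channels) {
  channel_index(recording, channels)  # validates
  recording$bad_channels <- as.integer(union(recording$bad_channels, channels))
  recording
}

#' Standard preprocessing chain
#'
#' Applies, in the canonical order, common average referencing, zero-phase
#' bandpass filtering, and stimulus-artifact blanking.
#'
#' @param recording a [new_recording()].
#' @param schedule a [stim_schedule()] for blanking.
#' @param band `"spike"` or `"lfp"`.
#' @param bad_channels channel ids to exclude first.
#' @param blank_ms blanking width per pulse edge.
#' @param in_brain_channels passed to [common_average_reference()].
#' @return the preprocessed recording.
#' @export
preprocess <- function(recording, schedule, band = c("spike", "lfp"),
                       bad_channels = integer(), blank_ms = 5,
                       in_brain_channels = NULL) {
  band <- match.arg(band)
  if (length(bad_channels)) recording <- set_bad_channels(recording, bad_channels)
  recording <- common_average_reference(recording, in_brain_channels)
  recording <- bandpass(recording, band)
  blank_stim_artifacts(recording, schedule, blank_ms)
}

#' Segment a recording around pulses
#'
#' For every pulse builds the pre window `[onset - pre_s, onset)`, the during
#' window `[onset, offset]`, and the post window `(offset, offset + post_s]`.
#' Pre/post windows are clipped against neighbouring pulses and the recording
#' edges; clipped or empty windows are flagged `truncated`.
#'
#' @param recording a [new_recording()].
#' @param schedule a [stim_schedule()].
#' @param pre_s,post_s window lengths in seconds (> 0).
#' @return tibble of class `segment_set`: `pulse_index`, `emitter_id`,
#'   `pattern_id`, `phase` (`pre`/`during`/`post`), `start_s`, `end_s`,
#'   `start_sample`, `end_sample`, `truncated`.
#' @export
segment_around_pulses <- function(recording, schedule, pre_s, post_s = pre_s) {
  assert_scalar_num(pre_s, "pre_s", min = 1e-12)
  assert_scalar_num(post_s, "post_s", min = 1e-12)
  pulses <- schedule$pulses
  n <- n_samples(recording)
  rate <- recording$rate_hz
  dur <- duration_s(recording)
  rows <- purrr::map_dfr(seq_len(nrow(pulses)), function(p) {
    on <- pulses$onset_s[p]
    off <- on + pulses$duration_s[p]
    others <- pulses[-p, ]
    prev_end <- suppressWarnings(max(others$onset_s[others$onset_s < on] +
                                       others$duration_s[others$onset_s < on], 0))
    next_start <- suppressWarnings(min(others$onset_s[others$onset_s >= off], dur))
    pre_a <- max(on - pre_s, prev_end, 0)
    post_b <- min(off + post_s, next_start, dur)
    tibble::tibble(
      pulse_index = p,
      emitter_id = pulses$emitter_id[p],
      pattern_id = pulses$pattern_id[p],
      phase = c("pre", "during", "post"),
      start_s = c(pre_a, on, off),
      end_s = c(on, off, post_b),
      truncated = c(pre_a > on - pre_s + 1e-12 || pre_a >= on,
                    FALSE,
                    post_b < off + post_s - 1e-12 || post_b <= off)
    )
  })
  idx <- purrr::map2(rows$start_s, rows$end_s, function(a, b) {
    r <- samples_in(a, b, rate, n)
    c(r[1] %||% NA_integer_, r[length(r)] %||% NA_integer_)
  })
  rows$start_sample <- purrr::map_int(idx, function(v) as.integer(v[1]))
  rows$end_sample <- purrr::map_int(idx, function(v) as.integer(v[2]))
  class(rows) <- c("segment_set", class(rows))
  rows
}
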
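#' Multichannel recording container
#'
#' A `recording` holds a time-by-channel voltage matrix in microvolts together
#' with the sampling rate, channel ids, a per-sample blanking mask, a set of
#' non-functional (bad) channels, and the probe layout the channels map onto.
#' The matrix representation (rather than a long table) keeps a 5-minute
#' 18-channel 30-kHz recording at a workable memory footprint; analysis
#' results, by contrast, are returned as tibbles throughout.
#'
#' Sample `i` is taken at time `(i - 1) / rate_hz`. A sample is *valid* on a
#' channel when it is not blanked and the channel is not marked bad; every
#' downstream sum (power, spike counting) is taken over valid samples only.
#'
#' @param data numeric matrix, `n_samples x n_channels`, microvolts.
#' @param rate_hz sampling rate (> 0).
#' @param channel_ids integer ids, one per column (defaults to `1:ncol`).
#' @param blank_mask logical vector of length `n_samples`; `TRUE` marks
#'   blanked samples (shared across channels). `NULL` means none.
#' @param bad_channels integer ids of non-functional channels.
#' @param layout optional [probe_layout()].
#' @param band `NULL`, `"spike"` or `"lfp"` after filtering.
#' @param steps character record of processing steps applied, in order.
#' @return An object of class `recording`.
#' @export
new_recording <- function(data, rate_hz, channel_ids = NULL, blank_mask = NULL,
                          bad_channels = integer(), layout = NULL,
                          band = NULL, steps = character()) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric matrix (time x channels)",
          class = "probeseize_invalid_recording")
  }
  assert_scalar_num(rate_hz, "rate_hz", min = 1e-9)
  channel_ids <- as.integer(channel_ids %||% seq_len(ncol(data)))
  if (length(channel_ids) != ncol(data)) {
    abort("`channel_ids` length must match ncol(data)",
          class = "probeseize_invalid_recording")
  }
  if (!is.null(blank_mask) && length(blank_mask) != nrow(data)) {
    abort("`blank_mask` length must match nrow(data)",
          class = "probeseize_invalid_recording")
  }
  structure(
    list(data = data, rate_hz = rate_hz, channel_ids = channel_ids,
         blank_mask = blank_mask, bad_channels = as.integer(bad_channels),
         layout = layout, band = band, steps = steps),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channels x %d samples @ %g Hz (%.1f s)%s%s\n",
    ncol(x$data), nrow(x$data), x$rate_hz, n_samples(x) / x$rate_hz,
    if (!is.null(x$band)) paste0(", band=", x$band) else "",
    if (length(x$steps)) paste0(" [", paste(x$steps, collapse = " > "), "]") else ""
  ))
  invisible(x)
}

#' Recording dimensions
#' @param recording a [new_recording()] object.
#' @return number of samples / channels / duration in seconds.
#' @export
n_samples <- function(recording) nrow(recording$data)

#' @rdname n_samples
#' @export
n_channels <- function(recording) ncol(recording$data)

#' @rdname n_samples
#' @export
duration_s <- function(recording) nrow(recording$data) / recording$rate_hz

channel_index <- function(recording, channel_id) {
  i <- match(channel_id, recording$channel_ids)
  if (anyNA(i)) {
    abort(sprintf("unknown channel id(s): %s",
                  paste(channel_id[is.na(i)], collapse = ", ")),
          class = "probeseize_unknown_channel")
  }
  i
}

#' Good (functional) channels of a recording
#' @param recording a [new_recording()] object.
#' @return integer channel ids excluding `bad_channels`.
#' @export
good_channels <- function(recording) {
  setdiff(recording$channel_ids, recording$bad_channels)
}

#' Per-sample validity mask for one channel
#'
#' @param recording a [new_recording()] object.
#' @param channel_id channel to query.
#' @return logical vector, `TRUE` where the sample is usable.
#' @export
valid_mask <- function(recording, channel_id) {
  ok <- !(channel_id %in% recording$bad_channels)
  base <- if (is.null(recording$blank_mask)) rep(TRUE, n_samples(recording)) else !recording$blank_mask
  if (!ok) base & FALSE else base
}

#' Extract a snippet of a recording as a long tibble
#'
#' Intended for inspection and plotting; do not use on full-length
#' high-rate recordings.
#'
#' @param recording a [new_recording()] object.
#' @param channels channel ids (default: all).
#' @param from_s,to_s time window in seconds.
#' @return tibble with `time_s`, `channel_id`, `uv`, `valid`.
#' @export
recording_tibble <- function(recording, channels = NULL,
                             from_s = 0, to_s = duration_s(recording)) {
  channels <- channels %||% recording$channel_ids
  idx <- samples_in(from_s, to_s, recording$rate_hz, n_samples(recording))
  cols <- channel_index(recording, channels)
  purrr::map_dfr(seq_along(cols), function(k) {
    tibble::tibble(
      time_s = (idx - 1) / recording$rate_hz,
      channel_id = channels[k],
      uv = recording$data[idx, cols[k]],
      valid = valid_mask(recording, channels[k])[idx]
    )
  })
}
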
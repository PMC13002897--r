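#' Write / read a recording as flat binary + JSON sidecar
#'
#' The on-disk format is a channel-interleaved little-endian signed 16-bit
#' binary (`<base>.bin`: for each time point, one count per channel in
#' channel-map order) plus a JSON sidecar (`<base>.json`) holding
#' `rate_hz`, `n_channels`, `n_samples`, `uv_per_count`, `channel_map`,
#' `bad_channels`, `band` and the processing steps. Voltages are quantized to
#' `uv_per_count`; a recording read from disk round-trips bit-exactly.
#'
#' @param recording a [new_recording()].
#' @param base path without extension; `.bin` and `.json` are appended.
#' @param uv_per_count microvolts per integer count (default 0.195, a typical
#'   acquisition-system LSB).
#' @param chunk_samples frames per write chunk (memory control).
#' @return `write_recording` returns `base` invisibly; `read_recording`
#'   returns a [new_recording()].
#' @export
write_recording <- function(recording, base, uv_per_count = 0.195,
                            chunk_samples = 1e6) {
  bin_path <- paste0(base, ".bin")
  json_path <- paste0(base, ".json")
  n <- n_samples(recording)
  con <- file(bin_path, "wb")
  on.exit(close(con), add = TRUE)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + as.integer(chunk_samples) - 1L)
    counts <- round(t(recording$data[i:j, , drop = FALSE]) / uv_per_count)
    counts <- pmin(pmax(counts, -32768), 32767)
    writeBin(as.integer(counts), con, size = 2L, endian = "little")
    i <- j + 1L
  }
  sidecar <- list(
    rate_hz = recording$rate_hz,
    n_channels = n_channels(recording),
    n_samples = n,
    uv_per_count = uv_per_count,
    channel_map = recording$channel_ids,
    bad_channels = recording$bad_channels,
    band = recording$band,
    steps = recording$steps
  )
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(base)
}

#' @rdname write_recording
#' @param layout optional [probe_layout()] to attach on read.
#' @export
read_recording <- function(base, layout = NULL, chunk_samples = 1e6) {
  bin_path <- paste0(base, ".bin")
  json_path <- paste0(base, ".json")
  if (!file.exists(json_path)) {
    abort(sprintf("missing sidecar: %s", json_path),
          class = "probeseize_missing_sidecar")
  }
  if (!file.exists(bin_path)) {
    abort(sprintf("missing binary: %s", bin_path),
          class = "probeseize_missing_file")
  }
  sc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  req <- c("rate_hz", "n_channels", "n_samples", "uv_per_count", "channel_map")
  if (!all(req %in% names(sc))) {
    abort("sidecar is missing required fields",
          class = "probeseize_invalid_sidecar")
  }
  nch <- as.integer(sc$n_channels)
  n <- as.integer(sc$n_samples)
  expected_bytes <- 2 * as.numeric(n) * nch
  actual_bytes <- file.info(bin_path)$size
  if (!isTRUE(all.equal(expected_bytes, actual_bytes))) {
    abort(sprintf("binary holds %g frames but sidecar declares %d (truncated or channel-count mismatch)",
                  actual_bytes / (2 * nch), n),
          class = "probeseize_truncated_binary")
  }
  con <- file(bin_path, "rb")
  on.exit(close(con), add = TRUE)
  data <- matrix(0, nrow = n, ncol = nch)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + as.integer(chunk_samples) - 1L)
    counts <- readBin(con, "integer", n = (j - i + 1L) * nch, size = 2L,
                      signed = TRUE, endian = "little")
    data[i:j, ] <- matrix(counts * sc$uv_per_count, ncol = nch, byrow = TRUE)
    i <- j + 1L
  }
  new_recording(data, sc$rate_hz, channel_ids = as.integer(sc$channel_map),
                bad_channels = as.integer(sc$bad_channels %||% integer()),
                layout = layout, band = sc$band,
                steps = as.character(sc$steps %||% character()))
}

#' Write simulator ground truth
#'
#' JSON summary (onset, suppression factor, per-channel seizure gains,
#' artifact intervals) plus one CSV per unit with its spike times.
#'
#' @param ground_truth the `ground_truth` element of [simulate_recording()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_ground_truth <- function(ground_truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    seizure_onset_s = ground_truth$seizure_onset_s,
    suppression_factor = ground_truth$suppression_factor,
    seizure_gain = as.list(ground_truth$seizure_gain),
    artifact_intervals = ground_truth$artifact_intervals,
    units = ground_truth$spikes$unit_id
  )
  jsonlite::write_json(summary, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  for (u in seq_len(nrow(ground_truth$spikes))) {
    readr::write_csv(
      tibble::tibble(spike_time_s = ground_truth$spikes$spike_times[[u]]),
      file.path(dir, sprintf("unit_%03d_spikes.csv",
                             ground_truth$spikes$unit_id[u]))
    )
  }
  invisible(dir)
}

#' Write an SR matrix as CSV (electrodes x emitters)
#'
#' @param x an [sr_matrix()] result.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_sr_matrix <- function(x, path) {
  m <- as.matrix(x)
  df <- tibble::as_tibble(m, .name_repair = ~ paste0("emitter_", .x))
  df <- dplyr::bind_cols(tibble::tibble(electrode_id = rownames(m)), df)
  readr::write_csv(df, path)
  invisible(path)
}
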
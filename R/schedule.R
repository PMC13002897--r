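#' Stimulation schedules
#'
#' A `stim_schedule` bundles a pulse table (one row per optical pulse) with an
#' injection table (one row per microfluidic injection epoch). Pulses carry
#' the emitter that fires, onset and duration in seconds, emission power in
#' microwatts, the photostimulation pattern they belong to, and (for pulse
#' trains) the train they belong to.
#'
#' @param pulses tibble with columns `emitter_id`, `onset_s`, `duration_s`,
#'   `power_uw`, `pattern_id` and optionally `train_id`.
#' @param injections tibble with columns `onset_s`, `duration_s`,
#'   `flow_rate_ul_min` (may be empty).
#' @return An object of class `stim_schedule`.
#' @export
stim_schedule <- function(pulses = NULL, injections = NULL) {
  empty_pulses <- tibble::tibble(
    emitter_id = integer(), onset_s = numeric(), duration_s = numeric(),
    power_uw = numeric(), pattern_id = integer(), train_id = integer()
  )
  empty_inj <- tibble::tibble(
    onset_s = numeric(), duration_s = numeric(), flow_rate_ul_min = numeric()
  )
  pulses <- if (is.null(pulses) || nrow(pulses) == 0) empty_pulses else tibble::as_tibble(pulses)
  injections <- if (is.null(injections) || nrow(injections) == 0) empty_inj else tibble::as_tibble(injections)
  if (!"train_id" %in% names(pulses)) pulses$train_id <- seq_len(nrow(pulses))
  if (!"pattern_id" %in% names(pulses)) pulses$pattern_id <- 1L
  req <- c("emitter_id", "onset_s", "duration_s", "power_uw", "pattern_id", "train_id")
  missing_cols <- setdiff(req, names(pulses))
  if (length(missing_cols)) {
    abort(paste0("pulse table is missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "probeseize_invalid_schedule")
  }
  pulses <- dplyr::arrange(pulses[req], .data$onset_s)
  if (nrow(pulses)) {
    if (any(pulses$duration_s <= 0) || any(pulses$onset_s < 0)) {
      abort("pulses need onset_s >= 0 and duration_s > 0",
            class = "probeseize_invalid_schedule")
    }
    ends <- pulses$onset_s + pulses$duration_s
    if (nrow(pulses) > 1 && any(pulses$onset_s[-1] < ends[-nrow(pulses)] - 1e-9)) {
      abort("pulses overlap in time", class = "probeseize_invalid_schedule")
    }
    bad <- pulses |>
      dplyr::group_by(.data$pattern_id) |>
      dplyr::summarise(ok = !is.unsorted(.data$onset_s, strictly = TRUE)) |>
      dplyr::filter(!.data$ok)
    if (nrow(bad)) {
      abort("pulse onsets must be strictly increasing within a pattern",
            class = "probeseize_invalid_schedule")
    }
  }
  structure(list(pulses = pulses, injections = injections),
            class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> %d pulses (%d patterns), %d injections\n",
              nrow(x$pulses), dplyr::n_distinct(x$pulses$pattern_id),
              nrow(x$injections)))
  invisible(x)
}

#' End time of the last scheduled event
#' @param schedule a [stim_schedule()].
#' @return time in seconds (0 for an empty schedule).
#' @export
schedule_end <- function(schedule) {
  ends <- c(0, schedule$pulses$onset_s + schedule$pulses$duration_s,
            schedule$injections$onset_s + schedule$injections$duration_s)
  max(ends)
}

#' Pulse-train photostimulation schedule
#'
#' Builds the short-pulse protocol: trains of `n_pulses` pulses at `freq_hz`,
#' each pulse `width_s` long, with `recovery_s` of rest between the end of one
#' train and the start of the next. One emitter is active per train; the
#' emitter order is a seeded random permutation of `emitters`, repeated over
#' `n_repeats` blocks (so every emitter receives `n_repeats` trains).
#'
#' @param n_pulses pulses per train.
#' @param freq_hz within-train pulse rate; `freq_hz * width_s` must be < 1.
#' @param width_s pulse width in seconds.
#' @param recovery_s rest between trains, seconds.
#' @param emitters vector of emitter ids.
#' @param n_repeats blocks of the full emitter permutation.
#' @param power_uw emission power per train; recycled across trains in onset
#'   order, so a vector of length `n_repeats * length(emitters)` (or any
#'   divisor) sets per-train power levels.
#' @param seed integer seed controlling the emitter permutation.
#' @param start_s onset of the first pulse.
#' @return A [stim_schedule()] with `n_pulses * n_repeats * length(emitters)`
#'   pulses; `train_id` numbers trains, `pattern_id` equals `train_id`.
#' @export
make_pulse_train_schedule <- function(n_pulses = 10, freq_hz = 5, width_s = 0.03,
                                      recovery_s = 10, emitters, n_repeats = 15,
                                      power_uw = 4.9, seed = 1, start_s = 0) {
  if (length(emitters) == 0) {
    abort("`emitters` must be non-empty", class = "probeseize_invalid_protocol")
  }
  if (freq_hz * width_s >= 1) {
    abort("invalid protocol: duty cycle freq_hz * width_s must be < 1",
          class = "probeseize_invalid_protocol")
  }
  # sample() on a length-1 vector would permute 1:emitters
  perm <- if (length(emitters) == 1) emitters else with_seed(seed, sample(emitters))
  train_emitters <- rep(perm, times = n_repeats)
  n_trains <- length(train_emitters)
  train_power <- rep_len(power_uw, n_trains)
  train_len <- (n_pulses - 1) / freq_hz + width_s
  train_t0 <- start_s + (seq_len(n_trains) - 1) * (train_len + recovery_s)
  pulses <- tibble::tibble(
    train_id = rep(seq_len(n_trains), each = n_pulses),
    emitter_id = rep(train_emitters, each = n_pulses),
    power_uw = rep(train_power, each = n_pulses),
    onset_s = rep(train_t0, each = n_pulses) +
      rep((seq_len(n_pulses) - 1) / freq_hz, times = n_trains),
    duration_s = width_s,
    pattern_id = rep(seq_len(n_trains), each = n_pulses)
  )
  stim_schedule(pulses)
}

#' Continuous-wave (CW) photostimulation schedule
#'
#' Long CW pulses delivered from individual emitters sequentially, with
#' `recovery_s` between pulses. Each repeat of the pattern addresses every
#' emitter once, in a freshly randomized order.
#'
#' @param pulse_s CW pulse duration, seconds (default 10).
#' @param recovery_s rest between pulses, seconds (default 30).
#' @param emitters vector of emitter ids.
#' @param n_repeats number of pattern repeats.
#' @param power_uw emission power in microwatts (recycled per pulse).
#' @param seed integer seed for the per-pattern emitter permutations.
#' @param start_s onset of the first pulse.
#' @return A [stim_schedule()] with `n_repeats * length(emitters)` pulses;
#'   `pattern_id` numbers the repeats.
#' @export
make_cw_schedule <- function(pulse_s = 10, recovery_s = 30, emitters,
                             n_repeats = 3, power_uw = 3.6, seed = 1,
                             start_s = 0) {
  if (pulse_s <= 0) {
    abort("`pulse_s` must be > 0", class = "probeseize_invalid_protocol")
  }
  if (length(emitters) == 0) return(stim_schedule())
  order_per_pattern <- with_seed(seed, {
    lapply(seq_len(n_repeats), function(i) {
      if (length(emitters) == 1) emitters else sample(emitters)
    })
  })
  seq_emitters <- unlist(order_per_pattern)
  k <- length(seq_emitters)
  onsets <- start_s + (seq_len(k) - 1) * (pulse_s + recovery_s)
  pulses <- tibble::tibble(
    emitter_id = seq_emitters,
    onset_s = onsets,
    duration_s = pulse_s,
    power_uw = rep_len(power_uw, k),
    pattern_id = rep(seq_len(n_repeats), each = length(emitters)),
    train_id = seq_len(k)
  )
  stim_schedule(pulses)
}

#' Add injection epochs to a schedule
#'
#' @param schedule a [stim_schedule()].
#' @param onset_s,duration_s,flow_rate_ul_min vectors describing injections.
#' @return the schedule with injections appended.
#' @export
add_injections <- function(schedule, onset_s, duration_s = 60,
                           flow_rate_ul_min = 0.31) {
  inj <- tibble::tibble(
    onset_s = onset_s,
    duration_s = rep_len(duration_s, length(onset_s)),
    flow_rate_ul_min = rep_len(flow_rate_ul_min, length(onset_s))
  )
  stim_schedule(schedule$pulses, dplyr::bind_rows(schedule$injections, inj))
}

schedule_csv_cols <- c("kind", "emitter_id", "onset_s", "duration_s",
                       "power_uw", "pattern_id")

#' Write / read a stimulation schedule as CSV
#'
#' The CSV has header `kind,emitter_id,onset_s,duration_s,power_uw,pattern_id`
#' (plus `train_id` and `flow_rate_ul_min`); pulse rows have `kind = "pulse"`,
#' injection rows `kind = "injection"`.
#'
#' @param schedule a [stim_schedule()].
#' @param path file path.
#' @return `read_schedule` returns a validated [stim_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  p <- schedule$pulses
  pulse_rows <- tibble::tibble(
    kind = rep("pulse", nrow(p)),
    emitter_id = p$emitter_id, onset_s = p$onset_s,
    duration_s = p$duration_s, power_uw = p$power_uw,
    pattern_id = p$pattern_id, train_id = p$train_id,
    flow_rate_ul_min = NA_real_
  )
  i <- schedule$injections
  inj_rows <- tibble::tibble(
    kind = rep("injection", nrow(i)),
    emitter_id = NA_integer_, onset_s = i$onset_s, duration_s = i$duration_s,
    power_uw = NA_real_, pattern_id = NA_integer_, train_id = NA_integer_,
    flow_rate_ul_min = i$flow_rate_ul_min
  )
  readr::write_csv(dplyr::bind_rows(pulse_rows, inj_rows), path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("schedule file not found: %s", path),
          class = "probeseize_missing_file")
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(schedule_csv_cols, names(df))
  if (length(missing_cols)) {
    abort(paste0("schedule CSV is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "probeseize_invalid_schedule")
  }
  bad <- which(!df$kind %in% c("pulse", "injection") |
                 !is.finite(df$onset_s) | !is.finite(df$duration_s))
  if (length(bad)) {
    abort(sprintf("malformed schedule rows at line(s): %s",
                  paste(bad + 1L, collapse = ", ")),
          class = "probeseize_invalid_schedule")
  }
  pulses <- df[df$kind == "pulse", setdiff(names(df), c("kind", "flow_rate_ul_min"))]
  inj <- df[df$kind == "injection", c("onset_s", "duration_s", "flow_rate_ul_min")]
  stim_schedule(pulses, inj)
}
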
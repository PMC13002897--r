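#' Neural activity power
#'
#' Mean squared amplitude of a signal over its valid samples:
#' `P = sum(v(t_n)^2) / T`, with `T` the number of retained (non-blanked)
#' samples. The default method takes a bare numeric vector; the recording
#' method computes power per channel over a time window, honouring the
#' blanking mask and bad channels.
#'
#' @param x numeric vector or [new_recording()].
#' @param ... passed to methods.
#' @return default method: scalar microvolt-squared power. Recording method:
#'   tibble `channel_id`, `p_uv2`, `n_valid`.
#' @export
activity_power <- function(x, ...) UseMethod("activity_power")

#' @rdname activity_power
#' @export
activity_power.default <- function(x, ...) {
  x <- as.numeric(x)
  if (length(x) == 0) {
    abort("cannot compute power of zero valid samples",
          class = "probeseize_empty_segment")
  }
  sum(x^2) / length(x)
}

#' @rdname activity_power
#' @param from_s,to_s window bounds in seconds (half-open `[from_s, to_s)`).
#' @param channels channel ids (default: good channels).
#' @export
activity_power.recording <- function(x, from_s = 0, to_s = duration_s(x),
                                     channels = NULL, ...) {
  channels <- channels %||% good_channels(x)
  idx <- samples_in(from_s, to_s, x$rate_hz, n_samples(x))
  blank <- if (is.null(x$blank_mask)) rep(FALSE, length(idx)) else x$blank_mask[idx]
  keep <- idx[!blank]
  purrr::map_dfr(channels, function(ch) {
    if (ch %in% x$bad_channels || length(keep) == 0) {
      return(tibble::tibble(channel_id = ch, p_uv2 = NA_real_, n_valid = 0L))
    }
    v <- x$data[keep, channel_index(x, ch)]
    tibble::tibble(channel_id = ch, p_uv2 = sum(v^2) / length(v),
                   n_valid = length(v))
  })
}

#' Suppression ratio
#'
#' Percent reduction in neural activity power during photostimulation:
#' `SR = (P_pre - P_dur) / P_pre * 100`. Positive SR means reduced LFP
#' amplitude and/or frequency (suppression); negative SR means increased
#' seizure severity. SR is bounded above by 100 and unbounded below.
#'
#' @param p_pre,p_dur power before and during stimulation (vectorized).
#' @return SR in percent; `NA` with a warning where `p_pre <= 0`.
#' @export
suppression_ratio <- function(p_pre, p_dur) {
  bad <- !is.na(p_pre) & p_pre <= 0
  if (any(bad)) {
    warn("suppression ratio undefined where p_pre <= 0; returning NA")
  }
  out <- (p_pre - p_dur) / p_pre * 100
  out[bad] <- NA_real_
  out
}

#' Electrode-by-emitter suppression-ratio matrix
#'
#' For one pattern of CW pulses, computes per electrode and per pulse the
#' pre-pulse power (window of length `pre_s` immediately preceding the pulse,
#' clipped against earlier pulses) and the during-pulse power, and the
#' resulting suppression ratio. The input should be the LFP-band, referenced,
#' blanked recording. Electrodes that are fully masked in a window give a
#' missing cell.
#'
#' @param recording a preprocessed [new_recording()].
#' @param schedule a [stim_schedule()].
#' @param electrodes electrode ids (default: in-brain good channels).
#' @param pre_s pre/during window length; default: the pulse duration.
#' @param pattern pattern id to analyse; defaults to the only pattern and
#'   errors if the schedule holds several.
#' @return tibble of class `sr_matrix`: `electrode_id`, `emitter_id`,
#'   `pulse_index`, `p_pre_uv2`, `p_dur_uv2`, `sr_percent`; attributes
#'   `pattern_id` and `pre_s`.
#' @export
sr_matrix <- function(recording, schedule, electrodes = NULL, pre_s = NULL,
                      pattern = NULL) {
  if (!is.null(recording$band) && recording$band != "lfp") {
    warn("sr_matrix expects an LFP-band recording")
  }
  pulses <- schedule$pulses
  pats <- unique(pulses$pattern_id)
  if (is.null(pattern)) {
    if (length(pats) > 1) {
      abort("schedule holds several patterns; pick one with `pattern` or use sr_matrices()",
            class = "probeseize_invalid_argument")
    }
    pattern <- pats[1]
  }
  sel <- pulses[pulses$pattern_id == pattern, ]
  if (!nrow(sel)) {
    abort("no pulses in the requested pattern", class = "probeseize_invalid_argument")
  }
  if (is.null(electrodes)) {
    electrodes <- if (!is.null(recording$layout)) {
      setdiff(in_brain_electrodes(recording$layout), recording$bad_channels)
    } else {
      good_channels(recording)
    }
  }
  out <- purrr::map_dfr(seq_len(nrow(sel)), function(p) {
    on <- sel$onset_s[p]
    off <- on + sel$duration_s[p]
    len <- pre_s %||% sel$duration_s[p]
    prev <- pulses$onset_s + pulses$duration_s
    prev_end <- suppressWarnings(max(prev[prev <= on + 1e-9], 0))
    a <- max(on - len, prev_end, 0)
    pre <- activity_power(recording, a, on, electrodes)
    dur <- activity_power(recording, on, off, electrodes)
    tibble::tibble(
      electrode_id = pre$channel_id,
      emitter_id = sel$emitter_id[p],
      pulse_index = p,
      p_pre_uv2 = pre$p_uv2,
      p_dur_uv2 = dur$p_uv2
    )
  })
  out$sr_percent <- suppressWarnings(suppression_ratio(out$p_pre_uv2, out$p_dur_uv2))
  attr(out, "pattern_id") <- pattern
  attr(out, "pre_s") <- pre_s
  class(out) <- c("sr_matrix", class(out))
  out
}

#' SR matrices for every pattern in a schedule
#'
#' @inheritParams sr_matrix
#' @return named list of [sr_matrix()] results, one per pattern.
#' @export
sr_matrices <- function(recording, schedule, electrodes = NULL, pre_s = NULL) {
  pats <- unique(schedule$pulses$pattern_id)
  out <- purrr::map(pats, function(p) {
    sr_matrix(recording, schedule, electrodes, pre_s, pattern = p)
  })
  stats::setNames(out, paste0("pattern_", pats))
}

#' Wide matrix form of an SR matrix
#'
#' @param x an [sr_matrix()] result.
#' @param ... unused.
#' @return numeric matrix, electrodes in rows, emitters in columns.
#' @export
as.matrix.sr_matrix <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(x)[c("electrode_id", "emitter_id", "sr_percent")],
    names_from = "emitter_id", values_from = "sr_percent"
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$electrode_id
  m
}

#' Fraction of positive suppression ratios (FPSR)
#'
#' Percentage of non-missing SR-matrix cells with `SR > 0` (strictly).
#' FPSR above 50% means the majority of electrode-emitter combinations showed
#' suppressed seizure activity during photostimulation.
#'
#' @param x an [sr_matrix()] result (or numeric vector of SRs).
#' @return tibble of class `fpsr_result`: `pattern_id`, `fpsr_percent`,
#'   `n_cells` (non-missing), `n_positive`.
#' @export
fpsr <- function(x) {
  srs <- if (inherits(x, "sr_matrix")) x$sr_percent else as.numeric(x)
  pattern <- attr(x, "pattern_id") %||% NA_integer_
  srs <- srs[!is.na(srs)]
  if (!length(srs)) {
    abort("all SR cells are missing", class = "probeseize_empty_segment")
  }
  out <- tibble::tibble(
    pattern_id = pattern,
    fpsr_percent = 100 * sum(srs > 0) / length(srs),
    n_cells = length(srs),
    n_positive = sum(srs > 0)
  )
  class(out) <- c("fpsr_result", class(out))
  out
}

# One-tailed / two-tailed Mann-Whitney U behind the module surface:
# exact when combined n <= 20 and no ties, otherwise normal approximation
# with tie correction (stats::wilcox.test policy).
mann_whitney <- function(x, y, alternative) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = !exact)
  )
  list(u = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal")
}

#' Pre/during/post Mann-Whitney tests on activity power
#'
#' One-tailed non-parametric Mann-Whitney U tests of the suppression
#' hypothesis: during-stimulation power stochastically smaller than pre- and
#' post-stimulation power, plus a two-sided pre-versus-post comparison
#' (expected similar). Significance stars: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001.
#'
#' @param powers_pre,powers_dur,powers_post numeric power samples, each of
#'   length >= 3.
#' @return tibble of class `power_test_result`: `comparison`, `alternative`,
#'   `n1`, `n2`, `u_statistic`, `p_value`, `method`, `stars`.
#' @export
pre_dur_post_test <- function(powers_pre, powers_dur, powers_post = NULL) {
  groups <- list(pre = powers_pre, dur = powers_dur)
  if (!is.null(powers_post)) groups$post <- powers_post
  for (g in names(groups)) {
    if (length(groups[[g]]) < 3) {
      abort(sprintf("group '%s' needs >= 3 values", g),
            class = "probeseize_invalid_argument")
    }
  }
  rows <- list()
  mw1 <- mann_whitney(powers_dur, powers_pre, "less")
  rows$a <- tibble::tibble(comparison = "during_vs_pre", alternative = "less",
                           n1 = length(powers_dur), n2 = length(powers_pre),
                           u_statistic = mw1$u, p_value = mw1$p,
                           method = mw1$method)
  if (!is.null(powers_post)) {
    mw2 <- mann_whitney(powers_dur, powers_post, "less")
    rows$b <- tibble::tibble(comparison = "during_vs_post", alternative = "less",
                             n1 = length(powers_dur), n2 = length(powers_post),
                             u_statistic = mw2$u, p_value = mw2$p,
                             method = mw2$method)
    mw3 <- mann_whitney(powers_pre, powers_post, "two.sided")
    rows$c <- tibble::tibble(comparison = "pre_vs_post", alternative = "two.sided",
                             n1 = length(powers_pre), n2 = length(powers_post),
                             u_statistic = mw3$u, p_value = mw3$p,
                             method = mw3$method)
  }
  out <- dplyr::bind_rows(rows)
  out$stars <- significance_stars(out$p_value)
  class(out) <- c("power_test_result", class(out))
  out
}

#' Activity power per electrode for pre/during/post windows
#'
#' Convenience wrapper building the three power samples of the
#' pre/during/post comparison: one value per (electrode, pulse, phase).
#'
#' @inheritParams sr_matrix
#' @param post_s post window length; defaults to `pre_s`.
#' @return tibble: `phase`, `pulse_index`, `emitter_id`, `electrode_id`,
#'   `p_uv2`, `n_valid`.
#' @export
pre_dur_post_powers <- function(recording, schedule, electrodes = NULL,
                                pre_s = NULL, post_s = NULL, pattern = NULL) {
  pulses <- schedule$pulses
  if (!is.null(pattern)) pulses <- pulses[pulses$pattern_id == pattern, ]
  if (is.null(electrodes)) {
    electrodes <- if (!is.null(recording$layout)) {
      setdiff(in_brain_electrodes(recording$layout), recording$bad_channels)
    } else {
      good_channels(recording)
    }
  }
  len0 <- pre_s
  purrr::map_dfr(seq_len(nrow(pulses)), function(p) {
    on <- pulses$onset_s[p]
    off <- on + pulses$duration_s[p]
    len <- len0 %||% pulses$duration_s[p]
    post_len <- post_s %||% len
    wins <- list(pre = c(max(on - len, 0), on),
                 during = c(on, off),
                 post = c(off, min(off + post_len, duration_s(recording))))
    purrr::imap_dfr(wins, function(w, phase) {
      pw <- activity_power(recording, w[1], w[2], electrodes)
      tibble::tibble(phase = phase, pulse_index = p,
                     emitter_id = pulses$emitter_id[p],
                     electrode_id = pw$channel_id, p_uv2 = pw$p_uv2,
                     n_valid = pw$n_valid)
    })
  })
}

#' Detect seizure onset from LFP power
#'
#' Slides a `win_s`-long window over the recording on a `step_s` grid,
#' computes per-channel mean squared amplitude, takes the median across good
#' channels, and reports the earliest window start at which that median
#' exceeds `k` times the baseline median power continuously for at least
#' `min_dur_s`. Baseline power is the median across channels of the power
#' within `baseline_window`.
#'
#' @param recording an LFP-band [new_recording()].
#' @param baseline_window numeric length-2 `c(from_s, to_s)` preceding any
#'   candidate seizure activity.
#' @param k threshold multiple of baseline power (default 5).
#' @param min_dur_s minimum supra-threshold duration (default 2).
#' @param win_s moving window length (default 1).
#' @param step_s evaluation grid step (default 0.1).
#' @return onset time in seconds, or `NA` if no sustained crossing is found.
#' @export
detect_seizure_onset <- function(recording, baseline_window, k = 5,
                                 min_dur_s = 2, win_s = 1, step_s = 0.1) {
  chans <- good_channels(recording)
  base <- activity_power(recording, baseline_window[1], baseline_window[2], chans)
  base_p <- median(base$p_uv2, na.rm = TRUE)
  if (!is.finite(base_p) || base_p <= 0) {
    abort("baseline power is zero or undefined", class = "probeseize_invalid_argument")
  }
  if (is.infinite(k)) return(NA_real_)
  n <- n_samples(recording)
  rate <- recording$rate_hz
  starts <- seq(0, duration_s(recording) - win_s, by = step_s)
  cols <- channel_index(recording, chans)
  # cumulative sums of squares per channel for O(1) window power
  med_power <- {
    csum <- matrix(0, nrow = length(starts), ncol = length(cols))
    for (jj in seq_along(cols)) {
      cs <- cumsum(recording$data[, cols[jj]]^2)
      i1 <- pmax(1L, as.integer(floor(starts * rate)) + 1L)
      i2 <- pmin(n, as.integer(floor((starts + win_s) * rate)))
      csum[, jj] <- (cs[i2] - ifelse(i1 > 1, cs[i1 - 1], 0)) / (i2 - i1 + 1)
    }
    apply(csum, 1, median)
  }
  above <- med_power > k * base_p
  need <- max(1L, as.integer(ceiling(min_dur_s / step_s)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit)) return(NA_real_)
  onset <- starts[begins[hit[1]]]
  if (onset < baseline_window[2]) {
    warn("detected onset lies inside the baseline window")
  }
  onset
}
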
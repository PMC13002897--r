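test_that("common average referencing matches the brute-force definition", {
  set.seed(11)
  x <- matrix(rnorm(5 * 1000, sd = 20), ncol = 5)
  rec <- new_recording(x, 1000)
  out <- common_average_reference(rec, in_brain_channels = 1:5)
  # per-sample mean over referenced channels is zero
  expect_lt(max(abs(rowMeans(out$data))), 1e-9)
  # equals explicit per-sample subtraction
  brute <- x - rowMeans(x)
  expect_equal(out$data, brute, tolerance = 1e-12)
  # idempotent
  out2 <- common_average_reference(out, in_brain_channels = 1:5)
  expect_lt(max(abs(out2$data - out$data)), 1e-9)
})

test_that("CAR degenerate cases", {
  x <- matrix(rnorm(100), ncol = 1)
  rec <- new_recording(x, 1000)
  out <- common_average_reference(rec, 1)
  expect_true(all(out$data == 0))
  # two channels +c and -c are unchanged
  y <- cbind(rnorm(100), 0)
  y[, 2] <- -y[, 1]
  rec2 <- new_recording(y, 1000)
  out2 <- common_average_reference(rec2, 1:2)
  expect_equal(out2$data, y)
  expect_error(common_average_reference(rec, integer()),
               class = "probeseize_invalid_argument")
  # channels outside the set pass through and are flagged
  rec3 <- new_recording(cbind(y, 5), 1000, channel_ids = 1:3)
  out3 <- common_average_reference(rec3, 1:2)
  expect_equal(out3$data[, 3], rep(5, 100))
  expect_equal(out3$unreferenced_channels, 3L)
})

test_that("zero-phase bandpass has unit passband gain, kills DC, zero delay", {
  rate <- 30000
  t <- (0:(rate - 1)) / rate
  tone <- sin(2 * pi * 1000 * t)
  f <- bandpass(new_recording(matrix(tone, ncol = 1), rate),
                filter_spec(300, 6000))
  gain <- max(abs(f$data[10000:20000, 1]))
  expect_gt(gain, 0.95)
  expect_lt(gain, 1.05)
  # DC offset through the LFP band leaves < 1% residual
  dc <- bandpass(new_recording(matrix(rep(50, rate), ncol = 1), rate),
                 filter_spec(5, 300))
  expect_lt(abs(mean(dc$data)), 0.01 * 50)
  # zero in, zero out
  z <- bandpass(new_recording(matrix(0, nrow = 1000, ncol = 2), rate), "spike")
  expect_true(all(z$data == 0))
  # impulse peak is not displaced
  imp <- numeric(30000); imp[15000] <- 1
  fi <- bandpass(new_recording(matrix(imp, ncol = 1), rate), "spike")
  expect_lte(abs(which.max(abs(fi$data[, 1])) - 15000), 1)
})

test_that("filtering commutes with channel permutation and validates corners", {
  set.seed(4)
  x <- matrix(rnorm(3 * 3000), ncol = 3)
  rate <- 30000
  perm <- c(3, 1, 2)
  a <- bandpass(new_recording(x, rate), "spike")$data[, perm]
  b <- bandpass(new_recording(x[, perm], rate), "spike")$data
  expect_equal(a, b)
  expect_error(bandpass(new_recording(x, 10000), filter_spec(300, 6000)),
               class = "probeseize_invalid_filter")
  expect_error(filter_spec(300, 100), class = "probeseize_invalid_filter")
})

test_that("blanking masks exactly 2 x blank_ms x rate samples per pulse", {
  rate <- 30000
  rec <- new_recording(matrix(rnorm(2 * rate * 2), ncol = 2), rate)
  sch <- stim_schedule(tibble::tibble(emitter_id = 1, onset_s = 0.5,
                                      duration_s = 0.03, power_uw = 1,
                                      pattern_id = 1L, train_id = 1L))
  out <- blank_stim_artifacts(rec, sch, blank_ms = 5)
  expect_equal(sum(out$blank_mask), 2 * 150)
  # values untouched (masking, not zeroing)
  expect_equal(out$data, rec$data)
  # empty schedule leaves the mask unchanged
  out0 <- blank_stim_artifacts(rec, stim_schedule(), blank_ms = 5)
  expect_equal(sum(out0$blank_mask), 0)
})

test_that("blanking unions abutting pulses and masks short pulses wholly", {
  rate <- 30000
  rec <- new_recording(matrix(0, nrow = rate, ncol = 1), rate)
  two <- stim_schedule(tibble::tibble(emitter_id = c(1, 2),
                                      onset_s = c(0.1, 0.13),
                                      duration_s = 0.03, power_uw = 1,
                                      pattern_id = 1L, train_id = 1:2))
  out <- blank_stim_artifacts(rec, two, blank_ms = 5)
  # brute-force interval union oracle
  ivs <- rbind(c(0.100, 0.105), c(0.125, 0.130), c(0.130, 0.135),
               c(0.155, 0.160))
  t_n <- (seq_len(rate) - 1) / rate
  brute <- rep(FALSE, rate)
  for (r in seq_len(nrow(ivs))) brute <- brute | (t_n >= ivs[r, 1] & t_n < ivs[r, 2])
  expect_equal(out$blank_mask, brute)
  short <- stim_schedule(tibble::tibble(emitter_id = 1, onset_s = 0.2,
                                        duration_s = 0.008, power_uw = 1,
                                        pattern_id = 1L, train_id = 1L))
  expect_warning(out2 <- blank_stim_artifacts(rec, short, blank_ms = 5),
                 "masking whole pulse")
  expect_equal(sum(out2$blank_mask), 0.008 * rate)
})

test_that("segmentation builds pre/during/post windows with truncation flags", {
  rate <- 1000
  rec <- new_recording(matrix(0, nrow = 40 * rate, ncol = 1), rate)
  sch <- stim_schedule(tibble::tibble(emitter_id = 1, onset_s = 15,
                                      duration_s = 10, power_uw = 1,
                                      pattern_id = 1L, train_id = 1L))
  seg <- segment_around_pulses(rec, sch, pre_s = 10, post_s = 10)
  expect_equal(nrow(seg), 3)
  expect_equal(seg$end_s - seg$start_s, c(10, 10, 10))
  expect_false(any(seg$truncated))
  # pulse at t = 0: empty pre window flagged
  sch0 <- stim_schedule(tibble::tibble(emitter_id = 1, onset_s = 0,
                                       duration_s = 1, power_uw = 1,
                                       pattern_id = 1L, train_id = 1L))
  seg0 <- segment_around_pulses(rec, sch0, pre_s = 5)
  expect_true(seg0$truncated[seg0$phase == "pre"])
  expect_error(segment_around_pulses(rec, sch, pre_s = 0),
               class = "probeseize_invalid_argument")
})

test_that("window power never counts blanked samples", {
  rate <- 1000
  n <- 30 * rate
  data <- matrix(1, nrow = n, ncol = 1)   # constant 1 uV
  rec <- new_recording(data, rate)
  sch <- stim_schedule(tibble::tibble(emitter_id = 1, onset_s = 10,
                                      duration_s = 10, power_uw = 1,
                                      pattern_id = 1L, train_id = 1L))
  rec <- blank_stim_artifacts(rec, sch, blank_ms = 5)
  pw <- activity_power(rec, 10, 20, channels = 1)
  # mask-aware count: 10 s minus 2 x 5 ms
  expect_equal(pw$n_valid, 10 * rate - 2 * 5)
  expect_equal(pw$p_uv2, 1)
})

test_that("the preprocessing pipeline equals step-by-step application", {
  lay <- small_layout()
  sch <- make_cw_schedule(pulse_s = 0.5, recovery_s = 1, emitters = 1:2,
                          n_repeats = 1, seed = 2, start_s = 2)
  cfg <- sim_config(seed = 9, duration_s = 5, sampling_rate_hz = 15000,
                    seizure = seizure_config(onset_s = 1))
  sim <- simulate_recording(cfg, sch, lay)
  piped <- preprocess(sim$recording, sch, band = "lfp", bad_channels = 2)
  manual <- sim$recording |>
    set_bad_channels(2) |>
    common_average_reference() |>
    bandpass("lfp") |>
    blank_stim_artifacts(sch, 5)
  expect_equal(piped$data, manual$data)
  expect_equal(piped$blank_mask, manual$blank_mask)
  expect_equal(piped$steps, manual$steps)
})
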
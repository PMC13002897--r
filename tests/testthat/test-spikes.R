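make_biphasic <- function(rate, amp) {
  tt <- (0:as.integer(round(0.0016 * rate))) / rate
  w <- -exp(-0.5 * ((tt - 4e-4) / 1.2e-4)^2) +
    0.4 * exp(-0.5 * ((tt - 9e-4) / 2.5e-4)^2)
  amp * w / abs(min(w))
}

test_that("threshold detection recovers injected templates exactly", {
  rate <- 30000
  n <- 2 * rate
  x <- numeric(n)
  tmpl <- make_biphasic(rate, 80)
  inject_at <- as.integer(seq(0.1, 1.9, length.out = 10) * rate)
  for (i in inject_at) x[i:(i + length(tmpl) - 1)] <- tmpl
  rec <- new_recording(matrix(x, ncol = 1), rate, band = "spike")
  st <- detect_spikes(rec)
  expect_equal(st$n_spikes, 10L)
  peak_offset <- which.min(tmpl) - 1L
  got <- round(st$spike_times[[1]] * rate) + 1L
  expect_true(all(abs(got - (inject_at + peak_offset)) <= 2))
  expect_equal(st$peak_amplitude_uv, 80, tolerance = 1e-6)
})

test_that("pure noise below threshold yields no detections", {
  rate <- 30000
  set.seed(77)
  x <- rnorm(10 * rate, sd = 8)
  rec <- new_recording(matrix(x, ncol = 1), rate, band = "spike")
  st <- detect_spikes(rec, threshold_mads = 8)
  expect_equal(st$n_spikes, 0L)
  # zero recording -> empty trains
  st0 <- detect_spikes(new_recording(matrix(0, 1000, 1), rate, band = "spike"))
  expect_equal(st0$n_spikes, 0L)
})

test_that("detection skips events touching blanked samples", {
  rate <- 30000
  n <- rate
  x <- numeric(n)
  tmpl <- make_biphasic(rate, 80)
  for (t0 in c(0.2, 0.5)) {
    i <- as.integer(t0 * rate)
    x[i:(i + length(tmpl) - 1)] <- tmpl
  }
  rec <- new_recording(matrix(x, ncol = 1), rate, band = "spike")
  sch <- stim_schedule(tibble::tibble(emitter_id = 1, onset_s = 0.496,
                                      duration_s = 0.03, power_uw = 1,
                                      pattern_id = 1L, train_id = 1L))
  rec <- blank_stim_artifacts(rec, sch)
  st <- detect_spikes(rec)
  expect_equal(st$n_spikes, 1L)   # the 0.5-s event touches the blank region
})

test_that("unit quality metrics follow the curation thresholds", {
  trains <- tibble::tibble(
    unit_id = 1:3,
    home_electrode = 1L,
    n_spikes = c(300L, 5L, 150L),
    spike_times = list(
      cumsum(rep(0.010, 300)),
      cumsum(c(0.5, 0.001, 0.010, 0.010, 0.010)),
      cumsum(rep(0.010, 150))
    ),
    waveforms = vector("list", 3),
    peak_amplitude_uv = c(50, 90, 90)
  )
  q <- unit_quality(trains)
  expect_equal(q$isi_violation_ratio, c(0, 0.25, 0))
  expect_true(q$passes[1])
  expect_false(q$passes[2])        # count < 200
  expect_false(q$passes[3])        # count < 200 despite amplitude and ISI
  # fewer than two spikes: ratio 0 by convention
  one <- trains[2, ]
  one$spike_times <- list(0.5)
  expect_equal(unit_quality(one)$isi_violation_ratio, 0)
})

test_that("quality gating equals a brute-force filter over a population", {
  pop <- make_quality_population(50)
  q <- unit_quality(pop)
  brute <- vapply(seq_len(nrow(pop)), function(i) {
    isi <- diff(pop$spike_times[[i]])
    ratio <- if (length(isi)) mean(isi < 0.002) else 0
    pop$peak_amplitude_uv[i] >= 30 &&
      length(pop$spike_times[[i]]) >= 200 &&
      ratio <= 0.5
  }, logical(1))
  expect_identical(q$passes, brute)
  expect_true(any(brute) && any(!brute))  # the population straddles thresholds
})

test_that("fraction_in_pulse handles the trivial and analytic cases", {
  sch <- make_pulse_train_schedule(n_pulses = 10, freq_hz = 5, width_s = 0.03,
                                   recovery_s = 10, emitters = 1,
                                   n_repeats = 15, seed = 5, start_s = 1)
  p <- sch$pulses
  all_in <- tibble::tibble(unit_id = 1L, home_electrode = 1L, n_spikes = 10L,
                           spike_times = list(p$onset_s[1:10] + 0.01),
                           waveforms = vector("list", 1),
                           peak_amplitude_uv = 50)
  expect_equal(fraction_in_pulse(all_in, sch, emitter = 1)$fraction, 1)
  none_in <- all_in
  none_in$spike_times <- list(p$onset_s[1:10] - 0.05)
  expect_equal(fraction_in_pulse(none_in, sch, emitter = 1)$fraction, 0)
  empty <- all_in
  empty$spike_times <- list(numeric(0))
  expect_true(is.na(fraction_in_pulse(empty, sch, emitter = 1)$fraction))
  expect_error(fraction_in_pulse(all_in, sch, emitter = 1, window_s = 0.01),
               class = "probeseize_invalid_argument")

  # closed-form Poisson expectation: 50 Hz in pulse, 2 Hz baseline,
  # 30-ms pulses in 230-ms windows -> 1.5 / 1.9
  lay <- small_layout()
  units <- unit_table(home_electrode = 2, baseline_rate_hz = 2,
                      gain_per_uw = (50 - 2) / 4.9 /
                        exp(-electrode_emitter_distance(lay, 2, 1) / 100))
  cfg <- sim_config(seed = 31, duration_s = schedule_end(sch) + 2,
                    sampling_rate_hz = 15000, units = units)
  set.seed(41)
  spk <- sim_spike_times(cfg, sch, lay)
  st <- spike_trains_from_ground_truth(list(spikes = spk))
  res <- fraction_in_pulse(st, sch, emitter = 1)
  expected <- (50 * 0.03) / (50 * 0.03 + 2 * 0.2)
  se <- sqrt(expected * (1 - expected) / res$n_window)
  expect_lt(abs(res$fraction - expected), 3 * se)
})

test_that("fraction_in_pulse is invariant to time-shifting the experiment", {
  sch <- make_pulse_train_schedule(n_pulses = 5, freq_hz = 5, width_s = 0.03,
                                   recovery_s = 2, emitters = 1, n_repeats = 2,
                                   seed = 1, start_s = 1)
  set.seed(10)
  times <- sort(runif(200, 0, schedule_end(sch)))
  st <- tibble::tibble(unit_id = 1L, home_electrode = 1L, n_spikes = 200L,
                       spike_times = list(times),
                       waveforms = vector("list", 1), peak_amplitude_uv = 50)
  f1 <- fraction_in_pulse(st, sch, emitter = 1)$fraction
  shift <- 13.7
  sch2 <- stim_schedule(dplyr::mutate(sch$pulses, onset_s = .data$onset_s + shift))
  st2 <- st
  st2$spike_times <- list(times + shift)
  f2 <- fraction_in_pulse(st2, sch2, emitter = 1)$fraction
  expect_equal(f1, f2)
})

test_that("firing rates recover configured stimulation and baseline rates", {
  lay <- small_layout()
  sch <- make_pulse_train_schedule(n_pulses = 10, freq_hz = 5, width_s = 0.03,
                                   recovery_s = 12, emitters = 1,
                                   n_repeats = 15, seed = 2, start_s = 12)
  d <- electrode_emitter_distance(lay, 2, 1)
  units <- unit_table(home_electrode = 2, baseline_rate_hz = 2,
                      gain_per_uw = 38 / 4.9 / exp(-d / 100))
  cfg <- sim_config(seed = 13, duration_s = schedule_end(sch) + 2,
                    sampling_rate_hz = 15000, units = units)
  set.seed(55)
  spk <- sim_spike_times(cfg, sch, lay)
  st <- spike_trains_from_ground_truth(list(spikes = spk))
  fr <- firing_rates(st, sch, baseline_s = 10)
  expect_equal(fr$n_pulses, 150)
  expect_lt(abs(fr$stim_rate_hz - 40), 3 * fr$stim_sem_hz)
  expect_lt(abs(fr$baseline_rate_hz - 2), 3 * fr$baseline_sem_hz)

  # null case: no stimulation effect
  units0 <- unit_table(home_electrode = 2, baseline_rate_hz = 10, gain_per_uw = 0)
  cfg0 <- sim_config(seed = 14, duration_s = schedule_end(sch) + 2,
                     sampling_rate_hz = 15000, units = units0)
  set.seed(56)
  st0 <- spike_trains_from_ground_truth(list(spikes = sim_spike_times(cfg0, sch, lay)))
  fr0 <- firing_rates(st0, sch, baseline_s = 10)
  expect_lt(abs(fr0$stim_rate_hz - fr0$baseline_rate_hz),
            3 * sqrt(fr0$stim_sem_hz^2 + fr0$baseline_sem_hz^2))

  # zero spikes -> all rates 0
  stz <- st
  stz$spike_times <- list(numeric(0))
  frz <- firing_rates(stz, sch)
  expect_equal(frz$stim_rate_hz, 0)
  expect_equal(frz$baseline_rate_hz, 0)
})

test_that("power dependence is exact for a constructed linear response", {
  # deterministic spikes: k spikes in every pulse at power level k
  levels <- 1:5
  sch <- make_pulse_train_schedule(n_pulses = 4, freq_hz = 2, width_s = 0.1,
                                   recovery_s = 3, emitters = 1, n_repeats = 5,
                                   power_uw = levels, seed = 3, start_s = 0)
  p <- sch$pulses
  times <- unlist(lapply(seq_len(nrow(p)), function(i) {
    k <- p$power_uw[i]
    p$onset_s[i] + seq_len(k) * 0.1 / (k + 1)
  }))
  st <- tibble::tibble(unit_id = 1L, home_electrode = 1L,
                       n_spikes = length(times),
                       spike_times = list(sort(times)),
                       waveforms = vector("list", 1), peak_amplitude_uv = 50)
  pd <- power_dependence(st, sch)
  expect_equal(nrow(pd), 5)
  expect_equal(pd$power_uw, as.numeric(levels))   # sorted ascending
  expect_equal(pd$stim_rate_hz, levels / 0.1)
  expect_equal(suppressWarnings(cor(pd$power_uw, pd$stim_rate_hz,
                                    method = "spearman")), 1)
  # single power level: one row
  sch1 <- make_pulse_train_schedule(n_pulses = 4, freq_hz = 2, width_s = 0.1,
                                    recovery_s = 3, emitters = 1, n_repeats = 1,
                                    power_uw = 2, seed = 3)
  expect_equal(nrow(power_dependence(st, sch1)), 1)
})

test_that("spatial selectivity orders emitters by distance", {
  lay <- default_layout()
  rates <- tibble::tibble(
    unit_id = 1L, home_electrode = 6L, emitter_id = c(3L, 6L, 9L, 12L),
    n_pulses = 10L,
    stim_rate_hz = NA_real_, stim_sem_hz = 0.1,
    baseline_rate_hz = 2, baseline_sem_hz = 0.1, n_trains = 10L
  )
  d <- electrode_emitter_distance(lay, 6, rates$emitter_id)
  rates$stim_rate_hz <- 2 + 30 * exp(-d / 100)
  sel <- spatial_selectivity(rates, lay)
  expect_equal(nrow(sel), 4)
  expect_false(is.unsorted(sel$distance_um))
  expect_true(all(diff(sel$rate_change_hz) < 0))
  bad <- dplyr::mutate(rates, emitter_id = 99L)
  expect_error(spatial_selectivity(bad, lay),
               class = "probeseize_unknown_emitter")
})

test_that("detection + quality + rates recovers generator rates over replicates", {
  lay <- small_layout()
  sch <- make_pulse_train_schedule(n_pulses = 10, freq_hz = 5, width_s = 0.1,
                                   recovery_s = 11, emitters = 1, n_repeats = 2,
                                   seed = 7, start_s = 11)
  d <- electrode_emitter_distance(lay, 2, 1)
  lambda <- 20
  units <- unit_table(home_electrode = 2, baseline_rate_hz = 1,
                      gain_per_uw = (lambda - 1) / 4.9 / exp(-d / 100),
                      amplitude_uv = 90)
  ests <- vapply(1:8, function(seed) {
    cfg <- sim_config(seed = seed, duration_s = schedule_end(sch) + 2,
                      sampling_rate_hz = 15000, units = units, noise_sd_uv = 5,
                      artifact = list(edge_amplitude_uv = 0, edge_width_ms = 0))
    sim <- simulate_recording(cfg, sch, lay)
    rec <- preprocess(sim$recording, sch, band = "spike", blank_ms = 0)
    st <- detect_spikes(rec)
    fr <- firing_rates(st[st$unit_id == 2, ], sch, baseline_s = 10)
    fr$stim_rate_hz
  }, numeric(1))
  t_pulse <- 8 * 20 * 0.1
  se <- sqrt(lambda / t_pulse)
  expect_lt(abs(mean(ests) - lambda), 3 * se)
})
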
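test_that("identical config, schedule, layout and seed give identical output", {
  lay <- small_layout()
  sch <- make_cw_schedule(pulse_s = 1, recovery_s = 2, emitters = 1:2,
                          n_repeats = 1, seed = 4, start_s = 6)
  cfg <- sim_config(seed = 21, duration_s = 12, sampling_rate_hz = 15000,
                    seizure = seizure_config(onset_s = 2),
                    units = unit_table(home_electrode = 3))
  a <- simulate_recording(cfg, sch, lay)
  b <- simulate_recording(cfg, sch, lay)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$ground_truth$spikes, b$ground_truth$spikes)
})

test_that("no noise, no units, no seizure gives an all-zero recording", {
  cfg <- sim_config(seed = 1, duration_s = 1, sampling_rate_hz = 15000,
                    noise_sd_uv = 0)
  sim <- simulate_recording(cfg, stim_schedule(), small_layout())
  expect_true(all(sim$recording$data == 0))
})

test_that("during-pulse seizure power follows the s^2 closed form", {
  # noise-free, jitter-free: window power ratios are exact up to
  # event truncation at the boundaries
  lay <- small_layout()
  sch <- make_cw_schedule(pulse_s = 4, recovery_s = 8, emitters = 1:2,
                          n_repeats = 1, seed = 2, start_s = 16)
  for (s in c(0.5, 1)) {
    cfg <- sim_config(seed = 8, duration_s = 32, sampling_rate_hz = 15000,
                      noise_sd_uv = 0, suppression_factor = s,
                      artifact = list(edge_amplitude_uv = 0, edge_width_ms = 0),
                      seizure = seizure_config(onset_s = 4, amplitude_jitter = 0,
                                               time_jitter_frac = 0))
    sim <- simulate_recording(cfg, sch, lay)
    rec <- sim$recording
    on <- sch$pulses$onset_s[1]
    p_pre <- activity_power(rec, on - 4, on, channels = 1)$p_uv2
    p_dur <- activity_power(rec, on, on + 4, channels = 1)$p_uv2
    expect_equal(p_dur / p_pre, s^2, tolerance = 0.01)
  }
})

test_that("polarity inversion flips the seizure component across the outlet", {
  lay <- small_layout()
  for (inv in c(TRUE, FALSE)) {
    cfg <- sim_config(seed = 3, duration_s = 10, sampling_rate_hz = 15000,
                      polarity_inversion = inv,
                      seizure = seizure_config(onset_s = 1))
    sim <- simulate_recording(cfg, stim_schedule(), lay)
    g <- sim$ground_truth$seizure_gain
    z <- sim$ground_truth$seizure_base
    below <- g[["1"]] * z   # electrode 1, axial 700 < outlet
    above <- g[["8"]] * z   # electrode 8, axial 1050 > outlet
    expect_equal(stats::cor(below, above), if (inv) -1 else 1)
  }
})

test_that("spike generation obeys the configured Poisson rate law", {
  lay <- small_layout()
  sch <- make_pulse_train_schedule(n_pulses = 10, freq_hz = 5, width_s = 0.03,
                                   recovery_s = 5, emitters = 1,
                                   n_repeats = 20, seed = 6)
  units <- unit_table(home_electrode = 2, baseline_rate_hz = 3,
                      gain_per_uw = 8, distance_constant_um = 100)
  cfg <- sim_config(seed = 17, duration_s = schedule_end(sch) + 5,
                    sampling_rate_hz = 15000, units = units)
  set.seed(123)
  spk <- sim_spike_times(cfg, sch, lay)
  t <- spk$spike_times[[1]]
  d <- electrode_emitter_distance(lay, 2, 1)
  lambda <- 3 + 8 * 4.9 * exp(-d / 100)
  p <- sch$pulses
  t_pulse <- sum(p$duration_s)
  n_in <- sum(vapply(seq_len(nrow(p)), function(i) {
    sum(t >= p$onset_s[i] & t < p$onset_s[i] + p$duration_s[i])
  }, numeric(1)))
  est <- n_in / t_pulse
  se <- sqrt(lambda / t_pulse)
  expect_lt(abs(est - lambda), 3 * se)
  # all ground-truth spikes lie inside the recording
  expect_true(all(t >= 0 & t < cfg$duration_s))
})

test_that("seizure component is silent before onset and artifacts are logged", {
  lay <- small_layout()
  sch <- make_cw_schedule(pulse_s = 1, recovery_s = 2, emitters = 1,
                          n_repeats = 1, seed = 1, start_s = 6)
  cfg <- sim_config(seed = 5, duration_s = 9, sampling_rate_hz = 15000,
                    noise_sd_uv = 0, seizure = seizure_config(onset_s = 5))
  sim <- simulate_recording(cfg, sch, lay)
  z <- sim$ground_truth$seizure_base
  expect_true(all(z[seq_len(5 * 15000)] == 0))
  iv <- sim$ground_truth$artifact_intervals
  expect_equal(nrow(iv), 2)  # onset + offset edges of one pulse
  amp <- cfg$artifact$edge_amplitude_uv
  expect_true(all(abs(sim$recording$data[iv$start_sample[1]:iv$end_sample[1], ]) >=
                    amp - 1e-9))
})

test_that("invalid simulation requests error", {
  sch <- make_cw_schedule(pulse_s = 10, recovery_s = 5, emitters = 1:2,
                          n_repeats = 1, seed = 1)
  cfg <- sim_config(seed = 1, duration_s = 5, sampling_rate_hz = 15000)
  expect_error(simulate_recording(cfg, sch, small_layout()),
               class = "probeseize_invalid_config")
  expect_error(sim_config(noise_sd_uv = -1), class = "probeseize_invalid_argument")
  expect_error(sim_config(suppression_factor = 1.2),
               class = "probeseize_invalid_argument")
  expect_error(sim_config(sampling_rate_hz = 10000),
               class = "probeseize_invalid_argument")
})

test_that("injection epochs add drift on outlet-proximal electrodes only", {
  lay <- small_layout()
  sch <- add_injections(stim_schedule(), onset_s = 2, duration_s = 2)
  cfg <- sim_config(seed = 2, duration_s = 6, sampling_rate_hz = 15000,
                    noise_sd_uv = 0, injection_drift_uv = 200)
  sim <- simulate_recording(cfg, sch, lay)
  d_out <- electrode_outlet_distance(lay, 1:8)
  near <- order(d_out)[1:4]
  far <- setdiff(1:8, near)
  seg <- probeseize:::samples_in(2, 4, 15000, n_samples(sim$recording))
  expect_true(all(colSums(abs(sim$recording$data[seg, near])) > 0))
  expect_true(all(sim$recording$data[, far] == 0))
})
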
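# Shared fixtures, built in code.

# Compact 8-electrode / 4-emitter layout spanning the outlet; keeps
# simulation cost down where the full 18-channel probe is not the point.
small_layout <- function() {
  probe_layout(
    electrodes = tibble::tibble(
      electrode_id = 1:8,
      axial_um = seq(700, 1050, by = 50),
      lateral_um = 20
    ),
    emitters = tibble::tibble(
      emitter_id = 1:4,
      axial_um = c(750, 850, 950, 1050),
      lateral_um = 40
    ),
    outlet = c(897, 40),
    in_brain_depth_um = 1400
  )
}

# One CW seizure-suppression replicate on the small layout: simulate,
# preprocess (LFP band), return the SR matrix summary.
run_sr_replicate <- function(seed, s, n_emitters = 4, pulse_s = 4,
                             recovery_s = 8, noise_sd_uv = 2,
                             rate_hz = 15000) {
  lay <- small_layout()
  sch <- make_cw_schedule(pulse_s = pulse_s, recovery_s = recovery_s,
                          emitters = seq_len(n_emitters), n_repeats = 1,
                          seed = seed, start_s = 16)
  cfg <- sim_config(seed = seed, duration_s = schedule_end(sch) + 6,
                    sampling_rate_hz = rate_hz, noise_sd_uv = noise_sd_uv,
                    seizure = seizure_config(onset_s = 4),
                    suppression_factor = s, polarity_inversion = TRUE)
  sim <- simulate_recording(cfg, sch, lay)
  rec <- preprocess(sim$recording, sch, band = "lfp")
  sr_matrix(rec, sch, pre_s = pulse_s)
}

# Synthetic unit population straddling the three curation thresholds.
make_quality_population <- function(n = 50, seed = 99) {
  withr::with_seed(seed, {
    amp <- runif(n, 10, 60)                      # straddles 30 uV
    count <- sample(50:400, n, replace = TRUE)   # straddles 200
    ratio <- runif(n, 0, 1)                      # straddles 0.5
    trains <- lapply(seq_len(n), function(i) {
      k <- count[i]
      n_viol <- round(ratio[i] * (k - 1))
      isis <- c(rep(0.001, n_viol), rep(0.010, (k - 1) - n_viol))
      cumsum(c(0.5, sample(isis)))
    })
    tibble::tibble(
      unit_id = seq_len(n),
      home_electrode = 1L,
      n_spikes = count,
      spike_times = trains,
      waveforms = vector("list", n),
      peak_amplitude_uv = amp
    )
  })
}

# Exhaustive one-tailed Mann-Whitney oracle: p = Pr(U <= U_obs) under the
# permutation null, enumerating every assignment of the pooled ranks.
mw_exact_less <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  u_all <- apply(combos, 2, function(ii) sum(r[ii]) - m * (m + 1) / 2)
  mean(u_all <= u_obs)
}
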
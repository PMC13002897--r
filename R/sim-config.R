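#' Simulation configuration
#'
#' Collects every knob of the synthetic-recording generator. Defaults encode
#' the study conditions the analysis targets: 30-kHz sampling, 1/f-weighted
#' baseline noise, rhythmic epileptiform bursting after a simulated
#' 4-AP injection, channelrhodopsin-like pulse-locked spiking whose rate grows
#' with optical power and decays with emitter distance, multiplicative
#' suppression of the seizure component during CW photostimulation, and square
#' electrical artifacts at pulse edges.
#'
#' The default `suppression_factor` is `sqrt(0.7)`: during a CW pulse the
#' seizure amplitude is scaled by this factor, so seizure *power* drops to
#' 70% of its pre-pulse value — a 30% suppression ratio, the magnitude of the
#' in vivo effect the analysis is built around.
#'
#' @param seed integer master seed; all randomness derives from it.
#' @param duration_s recording length in seconds.
#' @param sampling_rate_hz sampling rate; must exceed twice the 6-kHz spike
#'   band edge (default 30000).
#' @param noise_sd_uv standard deviation of the baseline noise (microvolts).
#' @param pink_fraction fraction of noise *power* carried by the 1/f
#'   component (remainder is white).
#' @param seizure list from [seizure_config()]; `onset_s = Inf` disables the
#'   seizure component.
#' @param suppression_factor scalar in `[0, 1]` multiplying the seizure
#'   component amplitude during CW pulses (1 = no effect).
#' @param suppression_space_constant_um spatial extent of suppression around
#'   the active emitter; `Inf` (default) suppresses uniformly across channels.
#' @param units tibble from [unit_table()]; may be empty.
#' @param artifact list with `edge_amplitude_uv` and `edge_width_ms`;
#'   rectangular offsets of that width are added inside the pulse at both
#'   pulse edges.
#' @param polarity_inversion logical; if `TRUE` the seizure component flips
#'   sign on channels above the microfluidic outlet.
#' @param outlet_space_constant_um exponential decay length of the seizure
#'   amplitude with electrode distance from the outlet.
#' @param injection_drift_uv amplitude of the slow (1 Hz) drift added to the
#'   four electrodes nearest the outlet during injection epochs.
#' @param spike_space_constant_um extracellular spike amplitude decay length
#'   across electrodes (default 25 um).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       duration_s = 60,
                       sampling_rate_hz = 30000,
                       noise_sd_uv = 10,
                       pink_fraction = 0.5,
                       seizure = seizure_config(),
                       suppression_factor = sqrt(0.7),
                       suppression_space_constant_um = Inf,
                       units = unit_table(),
                       artifact = list(edge_amplitude_uv = 300, edge_width_ms = 2),
                       polarity_inversion = FALSE,
                       outlet_space_constant_um = 600,
                       injection_drift_uv = 300,
                       spike_space_constant_um = 25) {
  assert_scalar_num(duration_s, "duration_s", min = 1e-3)
  assert_scalar_num(sampling_rate_hz, "sampling_rate_hz", min = 2 * 6000 + 1e-9)
  assert_scalar_num(noise_sd_uv, "noise_sd_uv", min = 0)
  assert_scalar_num(pink_fraction, "pink_fraction", min = 0, max = 1)
  assert_scalar_num(suppression_factor, "suppression_factor", min = 0, max = 1)
  if (!is.infinite(sampling_rate_hz) && sampling_rate_hz <= 12000) {
    abort("sampling_rate_hz must exceed 12 kHz (twice the spike band edge)",
          class = "probeseize_invalid_config")
  }
  rates <- c(seizure$burst_rate_hz, units$baseline_rate_hz, units$gain_per_uw)
  if (any(rates < 0)) {
    abort("all rates must be >= 0", class = "probeseize_invalid_config")
  }
  amps <- c(seizure$burst_amplitude_uv, units$amplitude_uv,
            artifact$edge_amplitude_uv, injection_drift_uv)
  if (any(amps < 0)) {
    abort("amplitudes must be >= 0", class = "probeseize_invalid_config")
  }
  structure(
    list(seed = as.integer(seed), duration_s = duration_s,
         sampling_rate_hz = sampling_rate_hz, noise_sd_uv = noise_sd_uv,
         pink_fraction = pink_fraction, seizure = seizure,
         suppression_factor = suppression_factor,
         suppression_space_constant_um = suppression_space_constant_um,
         units = units, artifact = artifact,
         polarity_inversion = polarity_inversion,
         outlet_space_constant_um = outlet_space_constant_um,
         injection_drift_uv = injection_drift_uv,
         spike_space_constant_um = spike_space_constant_um),
    class = "sim_config"
  )
}

#' Seizure-component parameters
#'
#' The epileptiform component is a periodic spike-and-wave train: a sharp
#' biphasic transient followed by a slower wave, repeating at
#' `burst_rate_hz`, with amplitude optionally decaying after onset with time
#' constant `afterdischarge_decay_s` (`Inf` = sustained after-discharges).
#' Event centers sit at `onset_s + (k + 1/2) / burst_rate_hz`, so analysis
#' windows that are integer multiples of the period carry identical seizure
#' power.
#'
#' Event-to-event variability emulates the irregularity of real
#' after-discharges: each event's amplitude is scaled by
#' `1 + amplitude_jitter * N(0, 1)` and its center is shifted uniformly by up
#' to `time_jitter_frac` of the period. The timing jitter is bounded (at most
#' 0.2 of the period) so events never straddle window or pulse boundaries,
#' which keeps the closed-form power relation between suppressed and
#' unsuppressed windows intact.
#'
#' @param onset_s seizure onset time; `Inf` disables the component.
#' @param burst_rate_hz event rate, typically 1-4 Hz.
#' @param burst_amplitude_uv peak amplitude at the outlet.
#' @param afterdischarge_decay_s exponential amplitude decay constant.
#' @param amplitude_jitter relative SD of per-event amplitude (default 0.1).
#' @param time_jitter_frac max event-center shift as a fraction of the period
#'   (default 0.05; capped at 0.2).
#' @return a list.
#' @export
seizure_config <- function(onset_s = Inf, burst_rate_hz = 2,
                           burst_amplitude_uv = 500,
                           afterdischarge_decay_s = Inf,
                           amplitude_jitter = 0.1,
                           time_jitter_frac = 0.05) {
  assert_scalar_num(amplitude_jitter, "amplitude_jitter", min = 0, max = 1)
  assert_scalar_num(time_jitter_frac, "time_jitter_frac", min = 0, max = 0.2)
  list(onset_s = onset_s, burst_rate_hz = burst_rate_hz,
       burst_amplitude_uv = burst_amplitude_uv,
       afterdischarge_decay_s = afterdischarge_decay_s,
       amplitude_jitter = amplitude_jitter,
       time_jitter_frac = time_jitter_frac)
}

#' Ground-truth unit table for the simulator
#'
#' One row per simulated single unit. During a pulse from emitter `j`, the
#' unit fires as a Poisson process at
#' `baseline_rate_hz + gain_per_uw * power_uw * exp(-d_j / distance_constant_um)`
#' where `d_j` is the distance from the unit's home electrode to the emitter;
#' outside pulses it fires at `baseline_rate_hz`.
#'
#' @param home_electrode electrode id the unit sits on.
#' @param baseline_rate_hz spontaneous rate.
#' @param gain_per_uw rate gain per microwatt of emission power at zero
#'   distance.
#' @param distance_constant_um spatial selectivity decay length.
#' @param amplitude_uv negative-peak spike amplitude on the home electrode.
#' @return tibble with one row per unit and a `unit_id` column.
#' @export
unit_table <- function(home_electrode = integer(),
                       baseline_rate_hz = 1,
                       gain_per_uw = 6,
                       distance_constant_um = 100,
                       amplitude_uv = 80) {
  n <- length(home_electrode)
  tibble::tibble(
    unit_id = seq_len(n),
    home_electrode = as.integer(home_electrode),
    baseline_rate_hz = rep_len(baseline_rate_hz, n),
    gain_per_uw = rep_len(gain_per_uw, n),
    distance_constant_um = rep_len(distance_constant_um, n),
    amplitude_uv = rep_len(amplitude_uv, n)
  )
}
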
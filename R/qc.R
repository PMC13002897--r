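#' Optical transmission in decibels
#'
#' `10 * log10(p_out / p_in)`: the emitter-to-input power ratio of a photonic
#' path, in dB (negative for lossy paths). Additive over cascaded stages.
#'
#' @param p_out,p_in optical powers (same units, > 0; vectorized).
#' @return transmission in dB.
#' @export
transmission_db <- function(p_out, p_in) {
  if (any(!is.finite(p_out) | !is.finite(p_in) | p_out <= 0 | p_in <= 0)) {
    abort("optical powers must be positive", class = "probeseize_invalid_argument")
  }
  10 * log10(p_out / p_in)
}

#' Microfluidic flow resistance
#'
#' Least-squares slope of input pressure versus flow rate through the origin
#' (zero pressure physically gives zero flow), in mbar.min/uL, with the
#' uncentered R-squared of that fit as a linearity check; high linearity
#' indicates absence of leakage or clogging.
#'
#' @param pressure_mbar input pressures (mbar).
#' @param flow_ul_min measured flow rates (uL/min).
#' @return tibble: `resistance_mbar_min_per_ul`, `r_squared`, `n`.
#' @export
flow_resistance <- function(pressure_mbar, flow_ul_min) {
  if (length(pressure_mbar) != length(flow_ul_min) || length(pressure_mbar) < 2) {
    abort("need >= 2 matched (pressure, flow) points",
          class = "probeseize_invalid_argument")
  }
  if (all(flow_ul_min == 0)) {
    abort("all flow rates are zero (clogged channel?)",
          class = "probeseize_clogged_channel")
  }
  fit <- stats::lm(pressure_mbar ~ 0 + flow_ul_min)
  tibble::tibble(
    resistance_mbar_min_per_ul = unname(stats::coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n = length(pressure_mbar)
  )
}

#' Electrode impedance summary
#'
#' Sample mean and SD (n - 1 denominator) of electrode impedances, and the
#' fraction strictly below the recording-quality threshold (2 MOhm by
#' default: electrodes above it are considered too high-impedance for
#' high-SNR extracellular recording).
#'
#' @param values_mohm impedances in MOhm (>= 1 value).
#' @param threshold quality threshold in MOhm (default 2).
#' @return tibble: `mean_mohm`, `sd_mohm`, `fraction_below_threshold`, `n`.
#' @export
impedance_summary <- function(values_mohm, threshold = 2.0) {
  if (!length(values_mohm)) {
    abort("need >= 1 impedance value", class = "probeseize_invalid_argument")
  }
  tibble::tibble(
    mean_mohm = mean(values_mohm),
    sd_mohm = if (length(values_mohm) > 1) stats::sd(values_mohm) else 0,
    fraction_below_threshold = mean(values_mohm < threshold),
    n = length(values_mohm)
  )
}

#' Device QC report
#'
#' Runs the three characterization estimators on CSV-style tables and
#' returns one combined list.
#'
#' @param impedance tibble with `impedance_mohm` (optionally `electrode_id`).
#' @param optics tibble with `p_in_uw`, `p_out_uw` (optionally `emitter_id`).
#' @param flow tibble with `pressure_mbar`, `flow_ul_min`.
#' @param impedance_threshold_mohm threshold for [impedance_summary()].
#' @return list with elements `impedance`, `transmission` (per-emitter dB +
#'   mean/SD), `flow`.
#' @export
device_qc_report <- function(impedance = NULL, optics = NULL, flow = NULL,
                             impedance_threshold_mohm = 2.0) {
  out <- list()
  if (!is.null(impedance)) {
    out$impedance <- impedance_summary(impedance$impedance_mohm,
                                       impedance_threshold_mohm)
  }
  if (!is.null(optics)) {
    db <- transmission_db(optics$p_out_uw, optics$p_in_uw)
    out$transmission <- tibble::tibble(
      mean_db = mean(db), sd_db = if (length(db) > 1) stats::sd(db) else 0,
      n = length(db)
    )
    out$transmission_per_emitter <- dplyr::mutate(optics, transmission_db = db)
  }
  if (!is.null(flow)) {
    out$flow <- flow_resistance(flow$pressure_mbar, flow$flow_ul_min)
  }
  out
}
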
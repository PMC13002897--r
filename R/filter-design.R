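# Butterworth bandpass design as second-order sections.
#
# An 8-pole bandpass with a 5-Hz corner at a 30-kHz rate is numerically
# unstable in expanded transfer-function form (the classic (b, a)
# representation overflows in double precision), so the filter is designed
# and applied as a cascade of biquads: analog Butterworth lowpass prototype
# -> lowpass-to-bandpass transform -> bilinear transform with prewarped
# corners -> conjugate pole pairs, one zero at z = +1 and one at z = -1 per
# section, gain normalized at the geometric-mean center frequency.

butter_bandpass_sos <- function(order, low_hz, high_hz, rate_hz) {
  w1 <- tan(pi * low_hz / rate_hz)
  w2 <- tan(pi * high_hz / rate_hz)
  bw <- w2 - w1
  w0sq <- w1 * w2
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # lowpass -> bandpass: each prototype pole p yields the roots of
  # s^2 - (p * bw) s + w0^2 = 0
  s_poles <- unlist(lapply(proto, function(p) {
    disc <- sqrt(as.complex((p * bw)^2 - 4 * w0sq))
    c((p * bw + disc) / 2, (p * bw - disc) / 2)
  }))
  z_poles <- (1 + s_poles) / (1 - s_poles)
  # pair conjugates into sections
  pos <- z_poles[Im(z_poles) > 1e-12]
  real_p <- Re(z_poles[abs(Im(z_poles)) <= 1e-12])
  sections <- list()
  for (p in pos) {
    sections[[length(sections) + 1L]] <- c(1, -2 * Re(p), Mod(p)^2)
  }
  while (length(real_p) >= 2) {
    r1 <- real_p[1]; r2 <- real_p[2]; real_p <- real_p[-(1:2)]
    sections[[length(sections) + 1L]] <- c(1, -(r1 + r2), r1 * r2)
  }
  ns <- length(sections)
  a <- do.call(rbind, sections)
  # order zeros: one at z = 1 and one at z = -1 per section -> b = (1, 0, -1)
  b <- matrix(rep(c(1, 0, -1), each = ns), nrow = ns)
  # unit gain at the center frequency (where the warped axis crosses w0)
  wc <- 2 * atan(sqrt(w0sq))
  zc <- exp(1i * wc)
  h <- prod(vapply(seq_len(ns), function(s) {
    num <- b[s, 1] + b[s, 2] / zc + b[s, 3] / zc^2
    den <- a[s, 1] + a[s, 2] / zc + a[s, 3] / zc^2
    Mod(num / den)
  }, numeric(1)))
  b[, ] <- b * (1 / h)^(1 / ns)
  list(b = b, a = a)
}

apply_sos <- function(x, sos) {
  sosfilt_cpp(x, sos$b, sos$a)
}
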
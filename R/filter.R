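#' Bandpass filter parameters
#'
#' Defaults follow the standard preprocessing for rodent LFP event detection:
#' a second-order Butterworth bandpass between 0.5 and 70 Hz.
#'
#' @param low_cut High-pass edge in Hz.
#' @param high_cut Low-pass edge in Hz.
#' @param order Butterworth prototype order (2 gives a 4-pole bandpass).
#' @return List of class `filter_params`.
#' @export
filter_params <- function(low_cut = 0.5, high_cut = 70, order = 2) {
  if (!(low_cut > 0 && low_cut < high_cut)) {
    stop_config("need 0 < low_cut < high_cut")
  }
  structure(list(low_cut = low_cut, high_cut = high_cut, order = as.integer(order)),
            class = "filter_params")
}

# Polynomial coefficients (descending powers) from roots.
poly_from_roots <- function(r) {
  coef <- complex(real = 1)
  for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
  coef
}

# Digital Butterworth bandpass via analog prototype -> lowpass-to-bandpass
# transform -> bilinear transform with frequency prewarping. Returns
# transfer-function coefficients (b, a), a[1] == 1.
butter_bandpass <- function(low_cut, high_cut, rate, order = 2) {
  if (rate <= 2 * high_cut) {
    stop_config("sampling rate must exceed 2 x high_cut (", 2 * high_cut, " Hz)")
  }
  fs2 <- 2 * rate
  w1 <- fs2 * tan(pi * low_cut / rate)
  w2 <- fs2 * tan(pi * high_cut / rate)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  half <- p_lp * bw / 2
  p_bp <- c(half + sqrt(half^2 - w0^2), half - sqrt(half^2 - w0^2))
  z_bp <- rep(0 + 0i, order)
  gain <- bw^order
  # bilinear transform
  p_z <- (fs2 + p_bp) / (fs2 - p_bp)
  z_z <- c((fs2 + z_bp) / (fs2 - z_bp), rep(-1 + 0i, length(p_bp) - length(z_bp)))
  gain_z <- gain * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  b <- Re(gain_z * poly_from_roots(z_z))
  a <- Re(poly_from_roots(p_z))
  list(b = b / a[1], a = a / a[1])
}

# Direct-form IIR filter with zero initial conditions, using the C loops in
# stats::filter (FIR stage as convolution, all-pole stage as recursion) so a
# 24 h trace filters in well under a second.
iir_filter <- function(x, b, a) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(length(x) + nb - 1)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# Magnitude response of (b, a) at frequency f for sampling rate `rate`.
freq_response <- function(b, a, f, rate) {
  z <- exp(-1i * 2 * pi * f / rate)
  zp_b <- vapply(seq_along(b), function(k) z^(k - 1), complex(1))
  zp_a <- vapply(seq_along(a), function(k) z^(k - 1), complex(1))
  abs(sum(b * zp_b) / sum(a * zp_a))
}

#' Zero-phase Butterworth bandpass of a channel trace
#'
#' The filter is applied forward and backward (filtfilt) so that spike peak
#' times are not lag-shifted; the effective magnitude response is the square
#' of the single-pass Butterworth response. Edges are handled by odd
#' reflection padding (1 s or the trace length, whichever is smaller).
#'
#' @param channel A [channel_trace()] (or bare numeric vector).
#' @param rate Sampling rate in samples/s; must exceed `2 * high_cut`.
#' @param params A [filter_params()].
#' @return A [channel_trace()] of the same length and role.
#' @export
bandpass <- function(channel, rate, params = filter_params()) {
  x <- if (inherits(channel, "channel_trace")) channel$samples else as.double(channel)
  role <- if (inherits(channel, "channel_trace")) channel$role else "other"
  ba <- butter_bandpass(params$low_cut, params$high_cut, rate, params$order)
  n <- length(x)
  npad <- min(as.integer(round(rate)), n - 1)
  ext <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- iir_filter(ext, ba$b, ba$a)
  y <- rev(iir_filter(rev(y), ba$b, ba$a))
  channel_trace(y[(npad + 1):(npad + n)], role)
}
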
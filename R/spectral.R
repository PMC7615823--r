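#' Canonical rodent EEG frequency bands
#'
#' delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–80 Hz. Band edges
#' are half-open `[low, high)` so the bands partition without double counting.
#'
#' @return Data.frame with columns `band`, `low`, `high`.
#' @export
default_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(1, 4, 8, 13, 30), high = c(4, 8, 13, 30, 80))
}

#' Spectral analysis parameters
#'
#' A 10 s Hanning window sliding in 5 s steps (50% overlap) yields one power
#' estimate per 5 s with 0.1 Hz frequency resolution.
#'
#' @param window_length Window length, s.
#' @param step Hop between consecutive windows, s; must be <= window_length.
#' @param bands Data.frame of `(band, low, high)` rows, half-open edges.
#' @param log_base Base of the log transform used for band-power summaries.
#' @return List of class `spectral_params`.
#' @export
spectral_params <- function(window_length = 10, step = 5,
                            bands = default_bands(), log_base = 10) {
  if (step > window_length) stop_config("step must be <= window_length")
  if (any(bands$high <= bands$low)) stop_config("band edges must be increasing")
  structure(list(window_length = window_length, step = step, bands = bands,
                 log_base = log_base),
            class = "spectral_params")
}

#' Sliding-window Hanning power spectral density
#'
#' Each window is demeaned, tapered with a Hann window and Fourier
#' transformed; the one-sided PSD is normalized by the taper power
#' (`sum(w^2)`) so that the integrated PSD of a window equals its variance
#' (Parseval). Units are uV^2/Hz.
#'
#' @param channel A [channel_trace()] or numeric vector.
#' @param rate Sampling rate, samples/s.
#' @param params A [spectral_params()].
#' @param start_time Time of the first sample, s.
#' @return List of class `lfp_spectrogram`: `times` (window centers, s),
#'   `frequencies` (Hz), `power` (matrix windows x frequencies).
#' @export
spectrogram <- function(channel, rate, params = spectral_params(),
                        start_time = 0) {
  x <- if (inherits(channel, "channel_trace")) channel$samples else as.double(channel)
  L <- as.integer(round(params$window_length * rate))
  hop <- as.integer(round(params$step * rate))
  n <- length(x)
  if (n < L) stop_range("trace shorter than one spectral window")
  starts <- seq(1, n - L + 1, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))
  w2 <- sum(w^2)
  n_freq <- L %/% 2 + 1
  freqs <- (0:(L %/% 2)) * rate / L
  pow <- matrix(0, nrow = length(starts), ncol = n_freq)
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + L - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(n_freq)]
    p <- (Mod(X)^2) / (rate * w2)
    p[2:(n_freq - 1)] <- 2 * p[2:(n_freq - 1)]
    pow[k, ] <- p
  }
  structure(list(times = start_time + (starts - 1) / rate + params$window_length / 2,
                 frequencies = freqs, power = pow,
                 window_length = params$window_length),
            class = "lfp_spectrogram")
}

#' Mean band powers over a spectrogram
#'
#' Per window, the mean PSD over the bins with `low <= f < high` is taken;
#' the summary is the mean over all windows, with a log transform applied
#' afterwards.
#'
#' @param spec An `lfp_spectrogram`.
#' @param bands Data.frame of `(band, low, high)` rows.
#' @param log_base Base of the log transform (default 10).
#' @return Data.frame with columns `band`, `power` (uV^2/Hz),
#'   `log_power`.
#' @export
band_power <- function(spec, bands = default_bands(), log_base = 10) {
  out <- lapply(seq_len(nrow(bands)), function(i) {
    sel <- spec$frequencies >= bands$low[i] & spec$frequencies < bands$high[i]
    if (!any(sel)) {
      stop_config("band ", bands$band[i], " contains no frequency bins")
    }
    per_win <- rowMeans(spec$power[, sel, drop = FALSE])
    p <- mean(per_win)
    data.frame(band = bands$band[i], power = p,
               log_power = if (p > 0) log(p, base = log_base) else NA_real_)
  })
  do.call(rbind, out)
}

#' Coastline (line length) of a trace over a window
#'
#' The sum of absolute sample-to-sample amplitude differences — an aggregate
#' of amplitude and frequency. Computed exactly as the total variation of
#' the sampled trace.
#'
#' @param channel A [channel_trace()] or numeric vector.
#' @param rate Sampling rate, samples/s.
#' @param window Optional `[start, end)` in seconds relative to the first
#'   sample; default is the whole trace.
#' @return Coastline in uV.
#' @export
coastline <- function(channel, rate = NULL, window = NULL) {
  x <- if (inherits(channel, "channel_trace")) channel$samples else as.double(channel)
  if (!is.null(window)) {
    if (is.null(rate)) stop_config("rate is required when a window is given")
    i0 <- round(window[1] * rate) + 1
    i1 <- round(window[2] * rate)
    if (i1 - i0 + 1 < 2) stop_range("coastline window must span >= 2 samples")
    x <- x[i0:i1]
  }
  if (length(x) < 2) stop_range("coastline needs >= 2 samples")
  sum(abs(diff(x)))
}

#' Per-window coastline aligned with the spectral windowing
#'
#' @param channel A [channel_trace()] or numeric vector.
#' @param rate Sampling rate, samples/s.
#' @param params A [spectral_params()] supplying window length and step.
#' @return Numeric vector, one coastline value (uV) per window.
#' @export
coastline_windows <- function(channel, rate, params = spectral_params()) {
  x <- if (inherits(channel, "channel_trace")) channel$samples else as.double(channel)
  L <- as.integer(round(params$window_length * rate))
  hop <- as.integer(round(params$step * rate))
  if (length(x) < L) stop_range("trace shorter than one window")
  starts <- seq(1, length(x) - L + 1, by = hop)
  vapply(starts, function(s) sum(abs(diff(x[s:(s + L - 1)]))), double(1))
}

#' Summarize band powers and coastline over an analysis interval
#'
#' @param channel A [channel_trace()] or numeric vector (already sliced to
#'   the analysis interval).
#' @param rate Sampling rate, samples/s.
#' @param params A [spectral_params()].
#' @return List of class `band_power_summary`: `bands` (data.frame from
#'   [band_power()]), `coastline` (mean per-window, uV), `log_coastline`,
#'   `spectrogram`.
#' @export
band_power_summary <- function(channel, rate, params = spectral_params()) {
  spec <- spectrogram(channel, rate, params)
  bands <- band_power(spec, params$bands, params$log_base)
  cl <- mean(coastline_windows(channel, rate, params))
  structure(list(bands = bands, coastline = cl,
                 log_coastline = if (cl > 0) log(cl, base = params$log_base) else NA_real_,
                 spectrogram = spec),
            class = "band_power_summary")
}

#' Normalize pre/post spectra to the pretreatment maximum
#'
#' Computes the mean (and SD) power per frequency across windows for both
#' spectrograms and expresses both as a percentage of the maximum of the
#' pretreatment mean spectrum, so the pre curve peaks at 100%.
#'
#' @param pre_spec,post_spec `lfp_spectrogram` objects on the same frequency
#'   grid.
#' @return Data.frame: `frequency`, `period` ("pre"/"post"), `mean_pct`,
#'   `sd_pct`.
#' @export
normalize_to_pretreatment <- function(pre_spec, post_spec) {
  if (!isTRUE(all.equal(pre_spec$frequencies, post_spec$frequencies))) {
    stop_validation("pre and post spectrograms must share one frequency grid")
  }
  pre_mean <- colMeans(pre_spec$power)
  M <- max(pre_mean)
  if (M <= 0) stop_range("pretreatment maximum is zero; cannot normalize")
  mk <- function(spec, period) {
    data.frame(frequency = spec$frequencies, period = period,
               mean_pct = colMeans(spec$power) / M * 100,
               sd_pct = apply(spec$power, 2, sd) / M * 100)
  }
  rbind(mk(pre_spec, "pre"), mk(post_spec, "post"))
}
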
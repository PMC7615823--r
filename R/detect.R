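#' Detection parameters for epileptiform events
#'
#' Encodes the full detection chain: the bandpass, the 2x-mode amplitude
#' threshold with a 70 ms refractory period, and the grouping rules turning
#' spikes into spike trains and hippocampal paroxysmal discharges (HPDs).
#'
#' `definition_profile` switches between event taxonomies used in the
#' literature:
#' * `"native"` — the model-native definitions: spike trains: >= 3 spikes, duration 1–10 s, >= 1.33 Hz;
#'   HPDs: >= 10 s, >= 1.33 Hz.
#' * `"sle_klein"` — seizure-like events (SLEs): >= 3 spikes lasting >= 3 s.
#' * `"five_five"` — HPDs require >= 5 s and >= 5 Hz.
#' * `"twele"` — HPDs require >= 20 s and a rate within 10–20 Hz.
#'
#' @param filter A [filter_params()].
#' @param refractory Minimum distance between accepted spikes, s.
#' @param threshold_factor Multiplier applied to the mode (2 per the standard
#'   definition).
#' @param train_min_spikes Minimum spikes per chained event.
#' @param train_duration Numeric length-2, half-open duration range for
#'   spike trains, s.
#' @param train_min_rate Minimum mean intra-event spike rate, Hz.
#' @param hpd_min_duration Minimum HPD duration, s.
#' @param definition_profile See above.
#' @param max_gap Maximum inter-spike gap keeping a chain alive, s. Defaults
#'   to `1/train_min_rate` (0.752 s): any ISI consistent with the minimum
#'   train rate keeps the chain alive.
#' @param rate_definition `"isi"` computes mean rate as `(n-1)/duration`
#'   (reciprocal mean inter-spike interval, the default); `"count"` uses
#'   `n/duration`.
#' @param polarity `"auto"` picks the side whose extremum mode is larger in
#'   magnitude; `"negative"`/`"positive"` force it.
#' @param segment_length Length of the mode-estimation segments, s.
#' @param bin_width Histogram bin width for the amplitude mode, uV.
#' @return List of class `detection_params`.
#' @export
detection_params <- function(filter = filter_params(),
                             refractory = 0.070,
                             threshold_factor = 2,
                             train_min_spikes = 3,
                             train_duration = c(1, 10),
                             train_min_rate = 1.33,
                             hpd_min_duration = 10,
                             definition_profile = c("native", "sle_klein",
                                                    "five_five", "twele"),
                             max_gap = NULL,
                             rate_definition = c("isi", "count"),
                             polarity = c("auto", "negative", "positive"),
                             segment_length = 1,
                             bin_width = 1) {
  if (is.list(filter) && !inherits(filter, "filter_params")) {
    filter <- do.call(filter_params, filter)
  }
  definition_profile <- match.arg(definition_profile)
  rate_definition <- match.arg(rate_definition)
  polarity <- match.arg(polarity)
  if (train_min_rate <= 0) stop_config("train_min_rate must be positive")
  if (hpd_min_duration < train_duration[2] &&
      definition_profile == "native") {
    stop_config("hpd_min_duration must be >= the spike-train duration cap")
  }
  structure(list(filter = filter, refractory = refractory,
                 threshold_factor = threshold_factor,
                 train_min_spikes = as.integer(train_min_spikes),
                 train_duration = train_duration,
                 train_min_rate = train_min_rate,
                 hpd_min_duration = hpd_min_duration,
                 definition_profile = definition_profile,
                 max_gap = max_gap %||% (1 / train_min_rate),
                 rate_definition = rate_definition,
                 polarity = polarity,
                 segment_length = segment_length,
                 bin_width = bin_width),
            class = "detection_params")
}

# Mode of a continuous sample via a histogram with bins centred on integer
# multiples of bin_width; ties resolved toward the larger |centre| (the more
# conservative, higher threshold).
binned_mode <- function(x, bin_width) {
  centers <- round(x / bin_width) * bin_width
  tab <- table(centers)
  top <- as.numeric(names(tab)[tab == max(tab)])
  top[which.max(abs(top))]
}

#' Estimate the mode-based spike-detection baseline
#'
#' The trace is divided into non-overlapping segments (1 s by default); the
#' minimum and maximum of each segment are collected and the mode of each
#' binned extremum distribution computed. The spike polarity is the side with
#' the larger-magnitude mode (unless forced), and the detection threshold is
#' `threshold_factor` (2) times the mode, signed.
#'
#' @param channel A filtered [channel_trace()] (or numeric vector).
#' @param rate Sampling rate, samples/s.
#' @param params A [detection_params()] (supplies segment length, bin width,
#'   threshold factor and polarity policy).
#' @return List of class `lfp_baseline` with `polarity`, `mode_amplitude`,
#'   `threshold`, `segment_length`, `n_segments`, `bin_width`.
#' @export
estimate_baseline <- function(channel, rate, params = detection_params()) {
  x <- if (inherits(channel, "channel_trace")) channel$samples else as.double(channel)
  seg_n <- as.integer(round(params$segment_length * rate))
  n_seg <- length(x) %/% seg_n
  if (n_seg < 10) {
    stop_range("trace too short: need >= 10 segments of ",
               params$segment_length, " s for the mode")
  }
  m <- matrix(x[seq_len(n_seg * seg_n)], nrow = seg_n)
  mins <- matrixStats_colMins(m)
  maxs <- matrixStats_colMaxs(m)
  mode_min <- binned_mode(mins, params$bin_width)
  mode_max <- binned_mode(maxs, params$bin_width)
  # polarity: larger |mode| wins; modes within one bin of each other are
  # indistinguishable at the histogram resolution, so fall back to the upper
  # tail of the extremum distributions, which epileptiform spikes inflate
  # strongly on their side
  polarity <- switch(params$polarity,
    negative = "negative", positive = "positive",
    auto = {
      tie_band <- max(params$bin_width, 0.2 * max(abs(mode_min), abs(mode_max)))
      if (abs(abs(mode_min) - abs(mode_max)) > tie_band) {
        if (abs(mode_min) > abs(mode_max)) "negative" else "positive"
      } else {
        tail_min <- stats::quantile(abs(mins), 0.99, names = FALSE)
        tail_max <- stats::quantile(maxs, 0.99, names = FALSE)
        if (tail_min >= tail_max) "negative" else "positive"
      }
    })
  mode_amp <- if (polarity == "negative") mode_min else mode_max
  structure(list(polarity = polarity, mode_amplitude = mode_amp,
                 threshold = params$threshold_factor * mode_amp,
                 segment_length = params$segment_length, n_segments = n_seg,
                 bin_width = params$bin_width),
            class = "lfp_baseline")
}

# Column-wise min/max without the matrixStats dependency.
matrixStats_colMins <- function(m) do.call(pmin, asplit(m, 1))
matrixStats_colMaxs <- function(m) do.call(pmax, asplit(m, 1))

#' Detect epileptiform spikes against a mode-based baseline
#'
#' Local extrema in the polarity direction that cross the threshold are
#' accepted greedily left to right; any candidate closer than the refractory
#' period (70 ms) to the last accepted spike is discarded. Spike time is the
#' sample time of the extremum.
#'
#' @param channel The same filtered [channel_trace()] the baseline was
#'   estimated from.
#' @param rate Sampling rate, samples/s.
#' @param baseline An `lfp_baseline` from [estimate_baseline()].
#' @param refractory Minimum inter-spike distance, s.
#' @param start_time Time of the first sample, s.
#' @return Data.frame with columns `time` (s), `amplitude` (uV).
#' @export
detect_spikes <- function(channel, rate, baseline, refractory = 0.070,
                          start_time = 0) {
  x <- if (inherits(channel, "channel_trace")) channel$samples else as.double(channel)
  if (baseline$polarity == "negative") {
    x <- -x
    thr <- -baseline$threshold
  } else {
    thr <- baseline$threshold
  }
  n <- length(x)
  if (n < 3) return(data.frame(time = numeric(), amplitude = numeric()))
  i <- 2:(n - 1)
  is_peak <- x[i] >= x[i - 1] & x[i] > x[i + 1] & x[i] >= thr
  cand <- i[is_peak]
  if (length(cand) == 0) return(data.frame(time = numeric(), amplitude = numeric()))
  tt <- (cand - 1) / rate
  min_gap <- refractory
  keep <- logical(length(cand))
  last <- -Inf
  for (k in seq_along(cand)) {
    if (tt[k] - last >= min_gap) {
      keep[k] <- TRUE
      last <- tt[k]
    }
  }
  amp <- x[cand[keep]]
  if (baseline$polarity == "negative") amp <- -amp
  data.frame(time = start_time + tt[keep], amplitude = amp)
}

# Event-classification predicate for one chained spike group under a profile.
classify_chain <- function(n, duration, rate, params) {
  if (n < params$train_min_spikes || duration <= 0) return(NA_character_)
  switch(params$definition_profile,
    native = {
      if (rate < params$train_min_rate) return(NA_character_)
      if (duration >= params$hpd_min_duration) return("hpd")
      if (duration >= params$train_duration[1] &&
          duration < params$train_duration[2]) return("spike_train")
      NA_character_
    },
    sle_klein = if (duration >= 3) "sle" else NA_character_,
    five_five = {
      if (duration >= 5 && rate >= 5) return("hpd")
      NA_character_
    },
    twele = {
      if (duration >= 20 && rate >= 10 && rate <= 20) return("hpd")
      NA_character_
    })
}

chain_rate <- function(n, duration, params) {
  if (duration <= 0) return(Inf)
  if (params$rate_definition == "isi") (n - 1) / duration else n / duration
}

#' Group detected spikes into classified events
#'
#' Spikes are chained while the inter-spike gap stays within `max_gap`
#' (default `1/train_min_rate`); each maximal chain is then classified by its
#' spike count, duration (last minus first spike time) and mean rate under
#' the active `definition_profile`. Chains that satisfy no definition (e.g.
#' sub-second triplets) produce no event.
#'
#' @param spikes Data.frame from [detect_spikes()], time-sorted.
#' @param params A [detection_params()].
#' @param channel_role Role recorded on the resulting intervals.
#' @return An [event_intervals()] table.
#' @export
group_events <- function(spikes, params = detection_params(),
                         channel_role = "hippocampus_ipsi") {
  t <- spikes$time
  if (is.unsorted(t, strictly = FALSE)) {
    stop_validation("spike times must be sorted")
  }
  empty <- event_intervals()
  if (length(t) == 0) return(empty)
  brk <- which(diff(t) > params$max_gap)
  starts <- c(1, brk + 1)
  ends <- c(brk, length(t))
  rows <- list()
  for (k in seq_along(starts)) {
    idx <- starts[k]:ends[k]
    n <- length(idx)
    dur <- t[ends[k]] - t[starts[k]]
    rate <- chain_rate(n, dur, params)
    kind <- classify_chain(n, dur, rate, params)
    if (!is.na(kind)) {
      rows[[length(rows) + 1]] <- data.frame(
        onset = t[starts[k]], offset = t[ends[k]] + 1e-9, kind = kind,
        n_spikes = n, mean_rate = rate, channel_role = channel_role)
    }
  }
  if (length(rows) == 0) return(empty)
  df <- do.call(rbind, rows)
  event_intervals(df$onset, df$offset, df$kind, df$n_spikes, df$mean_rate,
                  df$channel_role)
}

#' Parameters for automated generalized-seizure flagging
#'
#' Automates the visual criterion "high-amplitude, high-frequency discharges
#' simultaneously present in all channels followed by a clear post-ictal
#' depression": windowed RMS must exceed `cross_channel_factor` times the
#' per-channel baseline RMS on all channels for at least `min_duration`, and
#' the following `suppression_window` must fall below `suppression_factor`
#' times baseline on the ipsilateral channel.
#'
#' @param rms_window RMS window length, s.
#' @param cross_channel_factor Threshold multiple of baseline RMS (> 1).
#' @param min_duration Minimum super-threshold duration, s.
#' @param suppression_factor Post-ictal RMS ceiling as a multiple of
#'   baseline (< 1).
#' @param suppression_window Length of the post-ictal check window, s.
#' @return List of class `generalized_params`.
#' @export
generalized_params <- function(rms_window = 1, cross_channel_factor = 4,
                               min_duration = 10, suppression_factor = 0.5,
                               suppression_window = 30) {
  if (!(cross_channel_factor > 1 && suppression_factor < 1)) {
    stop_config("need cross_channel_factor > 1 > suppression_factor")
  }
  structure(list(rms_window = rms_window,
                 cross_channel_factor = cross_channel_factor,
                 min_duration = min_duration,
                 suppression_factor = suppression_factor,
                 suppression_window = suppression_window),
            class = "generalized_params")
}

windowed_rms <- function(x, win_n) {
  n_win <- length(x) %/% win_n
  m <- matrix(x[seq_len(n_win * win_n)]^2, nrow = win_n)
  sqrt(colMeans(m))
}

#' Flag generalized seizures on a multi-channel recording
#'
#' @param recording An [lfp_recording()] with at least 2 channels.
#' @param params A [generalized_params()].
#' @return An [event_intervals()] table with kind `generalized_seizure`
#'   (n_spikes 0). Onset/offset are in absolute session time.
#' @export
detect_generalized <- function(recording, params = generalized_params()) {
  if (length(recording$channels) < 2) {
    stop_config("generalized-seizure detection needs >= 2 channels")
  }
  rate <- recording$rate
  win_n <- as.integer(round(params$rms_window * rate))
  rms <- lapply(recording$channels, function(ch) windowed_rms(ch$samples, win_n))
  n_win <- length(rms[[1]])
  base <- vapply(rms, median, double(1))
  over <- rep(TRUE, n_win)
  for (i in seq_along(rms)) {
    over <- over & (rms[[i]] > params$cross_channel_factor * base[i])
  }
  roles <- rec_roles(recording)
  ipsi_i <- which(roles == "hippocampus_ipsi")[1]
  if (is.na(ipsi_i)) ipsi_i <- 1L
  min_w <- ceiling(params$min_duration / params$rms_window)
  sup_w <- ceiling(params$suppression_window / params$rms_window)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- event_intervals()
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < min_w) next
    s_from <- ends[k] + 1
    s_to <- min(n_win, ends[k] + sup_w)
    if (s_to < s_from) next
    sup_rms <- mean(rms[[ipsi_i]][s_from:s_to])
    if (sup_rms <= params$suppression_factor * base[ipsi_i]) {
      out <- rbind(out, event_intervals(
        onset = recording$start_time + (starts[k] - 1) * params$rms_window,
        offset = recording$start_time + ends[k] * params$rms_window,
        kind = "generalized_seizure", n_spikes = 0L, mean_rate = NA_real_,
        channel_role = "other"))
    }
  }
  class(out) <- c("event_intervals", "data.frame")
  out
}

#' Summarize event rates over an analysis window
#'
#' Counts events whose onset lies in the half-open window and the cumulative
#' duration of events clipped to the window, both scaled to per-hour.
#' Generalized seizures are reported as a raw per-window count.
#'
#' @param events An [event_intervals()] table (absolute times).
#' @param window Numeric length-2 `[start, end)` in seconds.
#' @return One-row data.frame: `window_start`, `window_end`,
#'   `n_spike_trains`, `dur_spike_trains`, `n_hpds`, `dur_hpds` (per hour),
#'   `n_sles`, `dur_sles`, `n_generalized` (per window).
#' @export
summarize_rates <- function(events, window) {
  if (!(length(window) == 2 && window[1] < window[2])) {
    stop_range("window must be [start, end) with start < end")
  }
  hours <- (window[2] - window[1]) / 3600
  per_kind <- function(kind) {
    sel <- events$kind == kind
    onset_in <- sel & events$onset >= window[1] & events$onset < window[2]
    n <- sum(onset_in)
    clip <- pmin(events$offset[sel], window[2]) - pmax(events$onset[sel], window[1])
    dur <- sum(pmax(clip, 0))
    c(n = n / hours, dur = dur / hours)
  }
  st <- per_kind("spike_train")
  hp <- per_kind("hpd")
  sle <- per_kind("sle")
  n_gen <- sum(events$kind == "generalized_seizure" &
                 events$onset >= window[1] & events$onset < window[2])
  data.frame(window_start = window[1], window_end = window[2],
             n_spike_trains = st["n"], dur_spike_trains = st["dur"],
             n_hpds = hp["n"], dur_hpds = hp["dur"],
             n_sles = sle["n"], dur_sles = sle["dur"],
             n_generalized = n_gen, row.names = NULL)
}

#' Run the full detection chain on one channel
#'
#' Convenience wrapper: bandpass -> mode baseline -> spike detection ->
#' event grouping, on the ipsilateral hippocampal channel by default.
#'
#' @param recording An [lfp_recording()].
#' @param params A [detection_params()].
#' @param role Channel role to analyze.
#' @return List with `baseline`, `spikes`, `events` (absolute session times).
#' @export
detect_events <- function(recording, params = detection_params(),
                          role = "hippocampus_ipsi") {
  ch <- rec_channel(recording, role)
  filt <- bandpass(ch, recording$rate, params$filter)
  baseline <- estimate_baseline(filt, recording$rate, params)
  spikes <- detect_spikes(filt, recording$rate, baseline, params$refractory,
                          start_time = recording$start_time)
  events <- group_events(spikes, params, channel_role = role)
  list(baseline = baseline, spikes = spikes, events = events)
}
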
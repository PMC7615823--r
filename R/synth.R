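#' Background LFP parameters
#'
#' The synthetic background is 1/f^alpha-shaped Gaussian noise plus a single
#' theta-range sinusoid — deliberately simple so the generator stays
#' auditable. `noise_sd` sets the SD of the noise component exactly; the
#' oscillation adds `oscillation_amp^2/2` of variance on top.
#'
#' @param noise_sd SD of the noise component, uV.
#' @param spectral_exponent alpha of the 1/f^alpha power slope (0–2).
#' @param oscillation_freq Oscillation frequency, Hz (theta-range default).
#' @param oscillation_amp Oscillation amplitude, uV.
#' @return List of class `background_params`.
#' @export
background_params <- function(noise_sd = 20, spectral_exponent = 1,
                              oscillation_freq = 7, oscillation_amp = 10) {
  if (noise_sd <= 0) stop_config("noise_sd must be positive")
  if (spectral_exponent < 0 || spectral_exponent > 2) {
    stop_config("spectral_exponent must be in [0, 2]")
  }
  structure(list(noise_sd = noise_sd, spectral_exponent = spectral_exponent,
                 oscillation_freq = oscillation_freq,
                 oscillation_amp = oscillation_amp),
            class = "background_params")
}

#' Generate a background LFP trace
#'
#' White Gaussian noise is shaped to a 1/f^alpha amplitude spectrum in the
#' Fourier domain, rescaled to `noise_sd`, and a sinusoid with a
#' seed-determined phase is added. Identical arguments and seed give a
#' bitwise-identical trace.
#'
#' @param duration Trace duration, s.
#' @param rate Sampling rate, samples/s.
#' @param params A [background_params()].
#' @param seed Integer seed.
#' @param role Channel role for the returned trace.
#' @return A [channel_trace()].
#' @export
generate_background <- function(duration, rate, params = background_params(),
                                seed = NULL, role = "other") {
  if (duration <= 0) stop_range("duration must be positive")
  n <- as.integer(round(duration * rate))
  x <- with_seed(seed, {
    # pad the shaping FFT to a 5-smooth length (large prime factors make
    # fft() quadratic-slow); the pad is discarded before rescaling
    m <- stats::nextn(n, c(2, 3, 5))
    w <- rnorm(m)
    phase <- runif(1, 0, 2 * pi)
    if (params$spectral_exponent > 0) {
      X <- fft(w)
      freqs <- c(0, pmin(seq_len(m - 1), m - seq_len(m - 1))) * rate / m
      shape <- c(0, freqs[-1]^(-params$spectral_exponent / 2))
      w <- Re(fft(X * shape, inverse = TRUE)) / m
    }
    w <- w[seq_len(n)]
    w <- w / sd(w) * params$noise_sd
    t <- (seq_len(n) - 1) / rate
    w + params$oscillation_amp * sin(2 * pi * params$oscillation_freq * t + phase)
  })
  channel_trace(x, role)
}

#' Event schedule for the synthetic generator
#'
#' Rates and morphology of the scheduled events. Defaults are set to the
#' pretreatment activity of a chronically epileptic (high-HPD) animal:
#' roughly 120 spike trains/h totalling ~390 s/h, 12 HPDs/h totalling
#' ~185 s/h, 60 isolated spikes/h and a generalized seizure every ~20 h.
#'
#' @param rates Named events/hour for `spike`, `spike_train`, `hpd`,
#'   `generalized_seizure`.
#' @param intra_train_rate Length-2 range, Hz; each event draws its spike
#'   rate uniformly from it (intra-train rates peak at 3–4 Hz).
#' @param train_duration_range Target spike-train span range, s; must lie
#'   within [1, 10).
#' @param hpd_duration_range Target HPD span range, s; minimum >= 10.
#' @param gs_duration_range Generalized-seizure duration range, s.
#' @param spike_amp Spike peak amplitude as a multiple of the expected mode
#'   of the per-second background extrema; must be >= 2.5 so spikes clear
#'   the 2x-mode detection threshold.
#' @param polarity Dominant spike polarity.
#' @param margin Minimum spacing between scheduled events, s.
#' @return List of class `event_schedule`.
#' @export
event_schedule <- function(rates = c(spike = 60, spike_train = 120, hpd = 12,
                                     generalized_seizure = 0.05),
                           intra_train_rate = c(3, 4),
                           train_duration_range = c(1.5, 5),
                           hpd_duration_range = c(10, 21),
                           gs_duration_range = c(20, 40),
                           spike_amp = 3,
                           polarity = c("negative", "positive"),
                           margin = 2) {
  polarity <- match.arg(polarity)
  kinds <- c("spike", "spike_train", "hpd", "generalized_seizure")
  r <- c(spike = 0, spike_train = 0, hpd = 0, generalized_seizure = 0)
  r[names(rates)] <- rates
  if (any(r < 0)) stop_config("event rates must be >= 0")
  if (hpd_duration_range[1] < 10) stop_config("hpd_duration_range minimum must be >= 10 s")
  if (train_duration_range[1] < 1 || train_duration_range[2] >= 10) {
    stop_config("train_duration_range must lie within [1, 10) s")
  }
  if (spike_amp < 2.5) stop_config("spike_amp must be >= 2.5 x the expected mode")
  structure(list(rates = r[kinds], intra_train_rate = intra_train_rate,
                 train_duration_range = train_duration_range,
                 hpd_duration_range = hpd_duration_range,
                 gs_duration_range = gs_duration_range,
                 spike_amp = spike_amp, polarity = polarity, margin = margin),
            class = "event_schedule")
}

# Renewal-process spike times: ISIs jittered +/-20% around 1/rate_hz,
# generated in one vectorized batch. For trains the sequence stops before
# exceeding the target span (floor 3 spikes); for HPDs it continues until
# the span reaches the target.
sample_spike_times <- function(target_dur, rate_hz, must_reach = FALSE) {
  n_draw <- max(8L, ceiling(target_dur * rate_hz * 1.5) + 4L)
  t <- cumsum(c(0, (1 / rate_hz) * (1 + runif(n_draw, -0.2, 0.2))))
  if (must_reach) {
    while (t[length(t)] < target_dur) {
      t <- c(t, t[length(t)] +
               cumsum((1 / rate_hz) * (1 + runif(n_draw, -0.2, 0.2))))
    }
    t[seq_len(which(t >= target_dur)[1])]
  } else {
    t[t <= target_dur | seq_along(t) <= 3]
  }
}

#' Sample a ground-truth event layout
#'
#' Event counts per kind are Poisson at the scheduled rates; events are
#' placed uniformly with overlap resolved by rejection resampling (1000
#' retries per event, then a scheduling error). Spike trains and HPDs carry
#' exact spike times from a jittered renewal process and satisfy their
#' definitional constraints by construction (trains: >= 3 spikes, span in
#' [1, 10) s, mean rate >= 1.33 Hz; HPDs: span >= 10 s). Generalized
#' seizures additionally reserve a 30 s post-ictal slot.
#'
#' @param schedule An [event_schedule()].
#' @param duration Session duration, s.
#' @param seed Integer seed.
#' @param start_time Session time of the first sample, s.
#' @return List of class `ground_truth`: `events` (an [event_intervals()]
#'   table), `spike_times` (list parallel to event rows), `schedule`,
#'   `seed`, `duration`, `start_time`.
#' @export
sample_schedule <- function(schedule, duration, seed = NULL, start_time = 0) {
  if (duration <= 0) stop_range("duration must be positive")
  with_seed(seed, {
    kinds <- names(schedule$rates)
    counts <- vapply(kinds, function(k) {
      rpois(1, schedule$rates[[k]] * duration / 3600)
    }, integer(1))
    suppression <- 30
    specs <- list()
    for (k in kinds) {
      for (j in seq_len(counts[[k]])) {
        st <- switch(k,
          spike = 0,
          spike_train = sample_spike_times(
            runif(1, schedule$train_duration_range[1], schedule$train_duration_range[2]),
            runif(1, schedule$intra_train_rate[1], schedule$intra_train_rate[2])),
          hpd = sample_spike_times(
            runif(1, schedule$hpd_duration_range[1], schedule$hpd_duration_range[2]),
            runif(1, schedule$intra_train_rate[1], schedule$intra_train_rate[2]),
            must_reach = TRUE),
          generalized_seizure = NULL)
        ev_dur <- switch(k,
          spike = 0.05,
          generalized_seizure = runif(1, schedule$gs_duration_range[1],
                                      schedule$gs_duration_range[2]),
          max(st) + 0.01)
        tail_pad <- if (k == "generalized_seizure") suppression else 0
        specs[[length(specs) + 1]] <- list(kind = k, st = st, ev_dur = ev_dur,
                                           tail_pad = tail_pad)
      }
    }
    # place the longest events first: greatly improves rejection packing at
    # the high post-treatment rates a proconvulsant-like effect produces
    spans <- vapply(specs, function(s) s$ev_dur + s$tail_pad, double(1))
    specs <- specs[order(spans, decreasing = TRUE)]
    n_ev <- length(specs)
    v_onset <- v_offset <- v_rate <- numeric(n_ev)
    v_kind <- character(n_ev)
    v_nspk <- integer(n_ev)
    res_lo <- res_hi <- numeric(n_ev)
    spikes <- vector("list", n_ev)
    for (e in seq_len(n_ev)) {
      s <- specs[[e]]
      placed <- FALSE
      for (try in seq_len(1000)) {
        onset <- runif(1, 0, max(duration - s$ev_dur - s$tail_pad, 0))
        lo <- onset - schedule$margin
        hi <- onset + s$ev_dur + s$tail_pad + schedule$margin
        prev <- seq_len(e - 1)
        if (e == 1 || all(hi <= res_lo[prev] | lo >= res_hi[prev])) {
          res_lo[e] <- lo; res_hi[e] <- hi
          v_onset[e] <- start_time + onset
          v_offset[e] <- start_time + onset + s$ev_dur
          v_kind[e] <- s$kind
          v_nspk[e] <- if (s$kind == "generalized_seizure") 0L
                       else if (s$kind == "spike") 1L else length(s$st)
          v_rate[e] <- if (s$kind %in% c("spike_train", "hpd")) {
            (length(s$st) - 1) / (max(s$st) - min(s$st))
          } else NA_real_
          spikes[[e]] <- if (s$kind == "generalized_seizure") numeric(0)
                         else start_time + onset + (s$st %||% 0)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop_range("scheduling error: could not place a ", s$kind,
                   " without overlap after 1000 retries")
      }
    }
    if (n_ev == 0) {
      ev <- event_intervals()
      spikes <- list()
    } else {
      ord <- order(v_onset)
      ev <- event_intervals(v_onset[ord], v_offset[ord], v_kind[ord],
                            v_nspk[ord], v_rate[ord],
                            ifelse(v_kind[ord] == "generalized_seizure",
                                   "other", "hippocampus_ipsi"))
      spikes <- spikes[ord]
    }
    structure(list(events = ev, spike_times = spikes, schedule = schedule,
                   seed = seed, duration = duration, start_time = start_time),
              class = "ground_truth")
  })
}

# Biphasic difference-of-exponentials spike template, dominant lobe
# normalized to +1, total width <= 50 ms.
spike_waveform <- function(rate) {
  t <- seq(0, 0.05, by = 1 / rate)
  dexp <- function(t, tr, td) ifelse(t < 0, 0, exp(-t / td) - exp(-t / tr))
  main <- dexp(t, 0.0025, 0.010)
  rebound <- dexp(t - 0.010, 0.005, 0.018)
  w <- main / max(main) - 0.4 * rebound / max(rebound)
  w / max(abs(w))
}

#' Synthesize a multi-channel recording from ground truth
#'
#' Background traces (one per channel, independent noise) are generated and
#' events are injected: focal events (spikes, trains, HPDs) only on the
#' ipsilateral hippocampal channel as sharp biphasic transients scaled to
#' `spike_amp` times the empirical mode of the per-second background
#' extrema; generalized seizures on all channels as high-amplitude 15–40 Hz
#' activity followed by a 30 s post-ictal suppression epoch in which the
#' background is scaled to 0.15x.
#'
#' @param truth A `ground_truth` from [sample_schedule()].
#' @param background A [background_params()].
#' @param n_channels Number of channels (ipsi, contra, cortex, then
#'   `other`); must be >= 2 when the truth contains generalized seizures.
#' @param rate Sampling rate, samples/s.
#' @param seed Integer seed (independent of the schedule seed).
#' @param animal_id Label stored on the recording.
#' @return An [lfp_recording()] starting at `truth$start_time`.
#' @export
synthesize_recording <- function(truth, background = background_params(),
                                 n_channels = 3, rate = 500, seed = NULL,
                                 animal_id = "sim") {
  has_gs <- any(truth$events$kind == "generalized_seizure")
  if (has_gs && n_channels < 2) {
    stop_config("generalized seizures require >= 2 channels")
  }
  roles <- c("hippocampus_ipsi", "hippocampus_contra", "cortex",
             rep("other", max(0, n_channels - 3)))[seq_len(n_channels)]
  chans <- lapply(seq_len(n_channels), function(i) {
    generate_background(truth$duration, rate, background,
                        seed = child_seed(seed, i), role = roles[i])
  })
  n <- length(chans[[1]]$samples)
  sig <- lapply(chans, function(ch) ch$samples)

  # spike amplitude calibration: mode of per-second extrema of the clean
  # ipsi background, same estimator the detector uses
  seg <- matrix(sig[[1]][seq_len((n %/% rate) * rate)], nrow = rate)
  extrema <- if (truth$schedule$polarity == "negative") {
    do.call(pmin, asplit(seg, 1))
  } else {
    do.call(pmax, asplit(seg, 1))
  }
  mode_bg <- binned_mode(extrema, 1)
  amp <- truth$schedule$spike_amp * abs(mode_bg)
  sgn <- if (truth$schedule$polarity == "negative") -1 else 1
  wf <- spike_waveform(rate)

  gs_rng <- with_seed(child_seed(seed, 97), {
    runif(max(1, sum(truth$events$kind == "generalized_seizure")), 15, 40)
  })
  gs_i <- 0
  for (e in seq_len(nrow(truth$events))) {
    kind <- truth$events$kind[e]
    if (kind == "generalized_seizure") {
      gs_i <- gs_i + 1
      on <- truth$events$onset[e] - truth$start_time
      off <- truth$events$offset[e] - truth$start_time
      i0 <- round(on * rate) + 1
      i1 <- min(round(off * rate), n)
      idx <- i0:i1
      tt <- (idx - i0) / rate
      env <- sqrt(pmax(sin(pi * tt / max(tt)), 0))
      burst <- 2 * amp * env * sin(2 * pi * gs_rng[gs_i] * tt)
      s0 <- i1 + 1
      s1 <- min(n, i1 + round(30 * rate))
      for (c in seq_len(n_channels)) {
        sig[[c]][idx] <- sig[[c]][idx] + burst
        if (s0 <= s1) sig[[c]][s0:s1] <- sig[[c]][s0:s1] * 0.15
      }
    } else {
      for (ts in truth$spike_times[[e]]) {
        i0 <- round((ts - truth$start_time) * rate) + 1
        idx <- i0:min(i0 + length(wf) - 1, n)
        sig[[1]][idx] <- sig[[1]][idx] + sgn * amp * wf[seq_along(idx)]
      }
    }
  }
  lfp_recording(lapply(seq_len(n_channels), function(i) channel_trace(sig[[i]], roles[i])),
                rate, start_time = truth$start_time, animal_id = animal_id)
}

#' Treatment effect as rate multipliers over a time window
#'
#' Drug action is abstracted as piecewise-constant multipliers on the event
#' rates, active from `onset_delay` (35 min, the reported time to peak
#' effect after i.p. administration) to `offset` (94 min) after injection.
#'
#' @param multipliers Named multipliers (>= 0) for `spike`, `spike_train`,
#'   `hpd`, `generalized_seizure`; unnamed kinds default to 1.
#' @param onset_delay Seconds after injection at which the effect starts.
#' @param offset Seconds after injection at which the effect ends.
#' @return List of class `treatment_effect`.
#' @export
treatment_effect <- function(multipliers = c(spike = 1, spike_train = 1,
                                             hpd = 1, generalized_seizure = 1),
                             onset_delay = 35 * 60, offset = 94 * 60) {
  m <- c(spike = 1, spike_train = 1, hpd = 1, generalized_seizure = 1)
  m[names(multipliers)] <- multipliers
  if (any(m < 0)) stop_config("rate multipliers must be >= 0")
  structure(list(multipliers = m, onset_delay = onset_delay, offset = offset),
            class = "treatment_effect")
}

#' Apply a treatment effect to an event schedule
#'
#' @param schedule An [event_schedule()] of baseline rates.
#' @param effect A [treatment_effect()].
#' @param injection_time Injection time, s from session origin.
#' @param session_end End of the session, s.
#' @param session_start Start of the session, s.
#' @return List of class `piecewise_schedule`: `segments` (data.frame with
#'   `start`, `end`) and `schedules` (one [event_schedule()] per segment
#'   with the multiplied rates).
#' @export
apply_treatment_effect <- function(schedule, effect, injection_time,
                                   session_end, session_start = 0) {
  if (injection_time < session_start || injection_time > session_end) {
    stop_range("injection_time outside the session")
  }
  cuts <- sort(unique(pmin(pmax(c(session_start,
                                  injection_time + effect$onset_delay,
                                  injection_time + effect$offset,
                                  session_end),
                                session_start), session_end)))
  segs <- data.frame(start = head(cuts, -1), end = tail(cuts, -1))
  segs <- segs[segs$end > segs$start, , drop = FALSE]
  schedules <- lapply(seq_len(nrow(segs)), function(i) {
    mid <- (segs$start[i] + segs$end[i]) / 2
    s <- schedule
    if (mid >= injection_time + effect$onset_delay &&
        mid < injection_time + effect$offset) {
      s$rates <- s$rates * effect$multipliers[names(s$rates)]
    }
    s
  })
  structure(list(segments = segs, schedules = schedules),
            class = "piecewise_schedule")
}

#' Sample ground truth from a piecewise schedule
#'
#' Each constant-rate segment is sampled independently with
#' [sample_schedule()] and the results concatenated.
#'
#' @param pw A `piecewise_schedule` from [apply_treatment_effect()].
#' @param seed Integer seed.
#' @return A `ground_truth` spanning the whole session.
#' @export
sample_piecewise_schedule <- function(pw, seed = NULL) {
  parts <- lapply(seq_len(nrow(pw$segments)), function(i) {
    sample_schedule(pw$schedules[[i]],
                    duration = pw$segments$end[i] - pw$segments$start[i],
                    seed = child_seed(seed, i),
                    start_time = pw$segments$start[i])
  })
  ev <- do.call(rbind, lapply(parts, function(p) p$events))
  class(ev) <- c("event_intervals", "data.frame")
  spikes <- do.call(c, lapply(parts, function(p) p$spike_times))
  structure(list(events = ev, spike_times = spikes,
                 schedule = pw$schedules[[1]], seed = seed,
                 duration = max(pw$segments$end) - min(pw$segments$start),
                 start_time = min(pw$segments$start)),
            class = "ground_truth")
}

#' Simulate a complete treatment session
#'
#' Builds the session [sample_piecewise_schedule()] -> ground truth ->
#' [synthesize_recording()] spanning from 64 min before to 94 min after the
#' injection, ready for [evaluate_session()].
#'
#' @param effect A [treatment_effect()].
#' @param injection_time Injection time, s from session origin.
#' @param schedule Baseline [event_schedule()].
#' @param background A [background_params()].
#' @param n_channels Channels to synthesize.
#' @param rate Sampling rate, samples/s.
#' @param seed Integer seed.
#' @param animal_id Label for the recording.
#' @return List with `recording` and `truth`.
#' @export
simulate_session <- function(effect, injection_time = 64 * 60,
                             schedule = event_schedule(),
                             background = background_params(),
                             n_channels = 3, rate = 500, seed = NULL,
                             animal_id = "sim") {
  t0 <- injection_time - 64 * 60
  if (t0 < 0) stop_range("injection_time must be >= 64 min into the session")
  t1 <- injection_time + 94 * 60
  pw <- apply_treatment_effect(schedule, effect, injection_time,
                               session_end = t1, session_start = t0)
  truth <- sample_piecewise_schedule(pw, seed = child_seed(seed, 11))
  rec <- synthesize_recording(truth, background, n_channels, rate,
                              seed = child_seed(seed, 23), animal_id = animal_id)
  list(recording = rec, truth = truth)
}
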
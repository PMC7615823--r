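test_that("bandpass matches the frequency-response oracle", {
  rate <- 500
  t <- (0:(10 * rate - 1)) / rate
  mid <- 1000:4000  # away from edges
  # passband: 6 Hz preserved within 5%
  y6 <- bandpass(channel_trace(sin(2 * pi * 6 * t)), rate)$samples
  expect_equal(max(abs(y6[mid])), 1, tolerance = 0.05)
  # stopband: 120 Hz attenuated below 15%
  y120 <- bandpass(channel_trace(sin(2 * pi * 120 * t)), rate)$samples
  expect_lt(max(abs(y120[mid])), 0.15)
  # DC removed (residual edge transient < 0.1% of the input level)
  ydc <- bandpass(channel_trace(rep(5, length(t))), rate)$samples
  expect_lt(max(abs(ydc[mid])), 0.005)
  # half-power at the band edges: zero-phase doubling gives |H|^2 = 1/2
  y70 <- bandpass(channel_trace(sin(2 * pi * 70 * t)), rate)$samples
  expect_equal(max(abs(y70[mid])), 0.5, tolerance = 0.05)
  # rate too low for the upper edge
  expect_error(bandpass(channel_trace(rnorm(1000)), 120), class = "hpdlfp_config_error")
})

test_that("zero-phase filtering does not shift peak times", {
  rate <- 500
  n <- 10 * rate
  x <- numeric(n)
  wf <- -100 * exp(-abs(seq(-0.02, 0.02, by = 1 / rate)) / 0.005)
  at <- 5 * rate
  x[at + seq_along(wf) - length(wf) %/% 2] <- wf
  y <- bandpass(channel_trace(x), rate)$samples
  expect_lt(abs(which.min(y) - (at + 1)), 3)  # within 2 samples (4 ms)
})

test_that("estimate_baseline implements the mode-of-extrema rule", {
  rate <- 500
  # forced case: per-second minima all -10 uV, maxima +4 uV
  one_sec <- c(-10, rep(0, rate - 2), 4)
  x <- rep(one_sec, 60)
  bl <- estimate_baseline(channel_trace(x), rate)
  expect_equal(bl$polarity, "negative")
  expect_equal(bl$mode_amplitude, -10)
  expect_equal(bl$threshold, -20)
  expect_equal(bl$n_segments, 60)
  # positive polarity when maxima dominate
  bl_pos <- estimate_baseline(channel_trace(-x), rate)
  expect_equal(bl_pos$polarity, "positive")
  expect_equal(bl_pos$threshold, 20)
  # manual polarity override
  p_neg <- detection_params(polarity = "negative")
  expect_equal(estimate_baseline(channel_trace(-x), rate, p_neg)$polarity, "negative")
  # too short
  expect_error(estimate_baseline(channel_trace(rnorm(5 * rate)), rate),
               class = "hpdlfp_range_error")
})

test_that("baseline polarity is detected on noisy traces with negative spikes", {
  bg <- generate_background(60, 500, background_params(noise_sd = 20), seed = 3)
  x <- bg$samples
  spike_at <- seq(1000, 28000, by = 1500)
  for (i in spike_at) x[i:(i + 10)] <- x[i:(i + 10)] - 200
  bl <- estimate_baseline(channel_trace(x), 500)
  expect_equal(bl$polarity, "negative")
})

test_that("detect_spikes applies threshold and 70 ms refractory", {
  rate <- 1000
  n <- 3 * rate
  mk <- function(times_s) {
    x <- numeric(n)
    for (ts in times_s) x[round(ts * rate) + 1] <- -25
    channel_trace(x)
  }
  bl <- structure(list(polarity = "negative", mode_amplitude = -10,
                       threshold = -20), class = "lfp_baseline")
  # 50 ms apart -> one spike survives
  s1 <- detect_spikes(mk(c(1.00, 1.05)), rate, bl)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$time, 1.00)
  # 80 ms apart -> both survive
  s2 <- detect_spikes(mk(c(1.00, 1.08)), rate, bl)
  expect_equal(s2$time, c(1.00, 1.08))
  # sub-threshold deflection ignored
  x <- numeric(n); x[500] <- -15
  expect_equal(nrow(detect_spikes(channel_trace(x), rate, bl)), 0)
  # amplitudes reported signed
  expect_equal(s1$amplitude, -25)
})

test_that("scheduled spikes are recovered at the sample level", {
  rate <- 500
  bg <- generate_background(120, rate, background_params(noise_sd = 20), seed = 11)
  truth_times <- seq(2, 115, length.out = 40)
  x <- bg$samples
  wf <- hpdlfp:::spike_waveform(rate)
  for (ts in truth_times) {
    i0 <- round(ts * rate) + 1
    x[i0:(i0 + length(wf) - 1)] <- x[i0:(i0 + length(wf) - 1)] - 300 * wf
  }
  filt <- bandpass(channel_trace(x), rate)
  bl <- estimate_baseline(filt, rate)
  spikes <- detect_spikes(filt, rate, bl)
  hits <- vapply(truth_times, function(ts) any(abs(spikes$time - ts) <= 0.020),
                 logical(1))
  expect_gte(sum(hits), 38)
})

test_that("group_events matches the definitional examples", {
  p <- detection_params()
  mk <- function(t) data.frame(time = t, amplitude = -30)
  # 4 spikes over 1.5 s -> one spike train
  ev <- group_events(mk(c(0, 0.5, 1.0, 1.5)), p)
  expect_equal(ev$kind, "spike_train")
  expect_equal(ev$n_spikes, 4L)
  expect_equal(ev$offset - ev$onset, 1.5, tolerance = 1e-6)
  # 15 spikes at 0.75 s ISI spanning 10.5 s -> one HPD
  ev2 <- group_events(mk(seq(0, by = 0.75, length.out = 15)), p)
  expect_equal(ev2$kind, "hpd")
  # two spikes -> nothing
  expect_equal(nrow(group_events(mk(c(0, 0.5)), p)), 0)
  # sub-second triplet -> nothing (not "lasting 1-10 s")
  expect_equal(nrow(group_events(mk(c(0, 0.3, 0.6)), p)), 0)
  # chain broken by a gap beyond 1/1.33 s
  ev3 <- group_events(mk(c(0, 0.5, 1.0, 1.5, 3.0, 3.5, 4.0, 5.0)), p)
  expect_equal(ev3$kind, c("spike_train", "spike_train"))
  # unsorted input rejected
  expect_error(group_events(mk(c(1, 0.5)), p), class = "hpdlfp_validation_error")
})

test_that("alternative definition profiles reclassify the same spikes", {
  mk <- function(t) data.frame(time = t, amplitude = -30)
  t35 <- seq(0, by = 1 / 3.5, length.out = 50)  # 14 s at 3.5 Hz
  expect_equal(group_events(mk(t35), detection_params())$kind, "hpd")
  # >= 5 s and >= 5 Hz: a 3.5 Hz sequence yields no HPD
  expect_equal(nrow(group_events(mk(t35), detection_params(definition_profile = "five_five"))), 0)
  # >= 20 s and 10-20 Hz: also nothing
  expect_equal(nrow(group_events(mk(t35), detection_params(definition_profile = "twele"))), 0)
  # SLE (>= 3 s) does fire
  expect_equal(group_events(mk(t35), detection_params(definition_profile = "sle_klein"))$kind, "sle")
  # a 6 Hz, 6 s sequence is an HPD under five_five but only a train under the native profile
  t6 <- seq(0, by = 1 / 6, length.out = 37)
  expect_equal(group_events(mk(t6), detection_params(definition_profile = "five_five"))$kind, "hpd")
  expect_equal(group_events(mk(t6), detection_params())$kind, "spike_train")
})

test_that("group_events agrees with the brute-force enumerator", {
  withr::local_seed(2024)
  profiles <- c("native", "sle_klein", "five_five", "twele")
  n_mismatch <- 0
  for (rep in 1:120) {
    t <- random_spike_times()
    p <- detection_params(definition_profile = sample(profiles, 1))
    got <- group_events(data.frame(time = t, amplitude = rep(-30, length(t))), p)
    want <- brute_force_group(t, p)
    ord <- order(want$onset)
    same <- nrow(got) == nrow(want) &&
      isTRUE(all.equal(got$onset, want$onset[ord], tolerance = 1e-9)) &&
      identical(got$kind, want$kind[ord]) &&
      identical(got$n_spikes, as.integer(want$n_spikes[ord]))
    if (!same) n_mismatch <- n_mismatch + 1
  }
  expect_equal(n_mismatch, 0)
})

test_that("detection is monotone in threshold and gap", {
  bg <- generate_background(120, 500, seed = 5)
  truth <- sample_schedule(event_schedule(rates = c(spike_train = 40, hpd = 8)),
                           120, seed = 6)
  rec <- synthesize_recording(truth, n_channels = 2, seed = 7)
  filt <- bandpass(rec_channel(rec), 500)
  # raising the threshold multiplier never increases spike count
  counts <- vapply(c(1.5, 2, 3, 4), function(f) {
    bl <- estimate_baseline(filt, 500, detection_params(threshold_factor = f))
    nrow(detect_spikes(filt, 500, bl))
  }, double(1))
  expect_true(all(diff(counts) <= 0))
  # widening max_gap never decreases total chained duration
  bl <- estimate_baseline(filt, 500)
  spikes <- detect_spikes(filt, 500, bl)
  durs <- vapply(c(0.4, 0.752, 1.5, 3), function(g) {
    ev <- group_events(spikes, detection_params(max_gap = g))
    sum(ev$offset - ev$onset)
  }, double(1))
  expect_true(all(diff(durs) >= -1e-9))
})

test_that("detect_generalized flags simulated seizures and nothing else", {
  sch <- event_schedule(rates = c(spike_train = 20, generalized_seizure = 3))
  truth <- sample_schedule(sch, 1800, seed = 5)
  expect_gt(sum(truth$events$kind == "generalized_seizure"), 0)
  rec <- synthesize_recording(truth, n_channels = 3, seed = 5)
  gs <- detect_generalized(rec)
  tr <- truth$events[truth$events$kind == "generalized_seizure", ]
  expect_equal(nrow(gs), nrow(tr))
  for (i in seq_len(nrow(tr))) {
    ov <- min(gs$offset[i], tr$offset[i]) - max(gs$onset[i], tr$onset[i])
    expect_gte(ov / (tr$offset[i] - tr$onset[i]), 0.8)
  }
  # pure background -> nothing
  bg_rec <- synthesize_recording(sample_schedule(event_schedule(rates = c(spike = 0)),
                                                 600, seed = 1),
                                 n_channels = 3, seed = 2)
  expect_equal(nrow(detect_generalized(bg_rec)), 0)
  # single channel -> configuration error
  one <- lfp_recording(list(hippocampus_ipsi = rnorm(5000)), 500)
  expect_error(detect_generalized(one), class = "hpdlfp_config_error")
})

test_that("high-RMS activity on one channel only is not a generalized seizure", {
  bg1 <- generate_background(120, 500, seed = 21, role = "hippocampus_ipsi")
  bg2 <- generate_background(120, 500, seed = 22, role = "hippocampus_contra")
  x <- bg1$samples
  idx <- (30 * 500):(50 * 500)
  x[idx] <- x[idx] + 500 * sin(2 * pi * 20 * seq_along(idx) / 500)
  rec <- lfp_recording(list(channel_trace(x, "hippocampus_ipsi"), bg2), 500)
  expect_equal(nrow(detect_generalized(rec)), 0)
})

test_that("summarize_rates scales counts and clips durations", {
  ev <- event_intervals(onset = c(100, 600, 1000, 1500, 2000, 2500, 3530),
                        offset = c(120, 620, 1020, 1520, 2020, 2520, 3560),
                        kind = rep("hpd", 7), n_spikes = rep(40L, 7),
                        mean_rate = rep(3.5, 7), channel_role = rep("hippocampus_ipsi", 7))
  s <- summarize_rates(ev, c(0, 3540))
  expect_equal(s$n_hpds, 7 * 3600 / 3540)
  # last event contributes only its 10 s inside the window
  expect_equal(s$dur_hpds, (20 * 6 + 10) * 3600 / 3540)
  # worked arithmetic: 6 HPDs totalling 122 s in a 3540 s window
  ev2 <- event_intervals(onset = seq(0, 500, length.out = 6),
                         offset = seq(0, 500, length.out = 6) + 122 / 6,
                         kind = rep("hpd", 6), n_spikes = rep(30L, 6),
                         mean_rate = rep(3, 6), channel_role = rep("hippocampus_ipsi", 6))
  s2 <- summarize_rates(ev2, c(0, 3540))
  expect_equal(s2$n_hpds, 6.10, tolerance = 1e-3)
  expect_equal(s2$dur_hpds, 124.07, tolerance = 1e-3)
  # empty window errors; empty events give zeros
  expect_error(summarize_rates(ev, c(5, 5)), class = "hpdlfp_range_error")
  z <- summarize_rates(event_intervals(), c(0, 3600))
  expect_equal(z$n_hpds + z$dur_hpds + z$n_spike_trains + z$dur_spike_trains, 0)
})
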
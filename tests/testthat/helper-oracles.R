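# Independent oracles and fixture builders shared across test files.

# Brute-force event grouper: tests every contiguous spike subsequence
# against the definitional predicates and keeps maximal chains. Independent
# of group_events (no chaining shortcut: maximality is checked explicitly
# via the flanking gaps).
brute_force_group <- function(times, params) {
  n <- length(times)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      # maximality first (O(1)): no extension on either side stays in max_gap
      if (i > 1 && times[i] - times[i - 1] <= params$max_gap) next
      if (j < n && times[j + 1] - times[j] <= params$max_gap) next
      sub <- times[i:j]
      if (length(sub) > 1 && any(diff(sub) > params$max_gap)) next
      m <- length(sub)
      if (m < params$train_min_spikes) next
      dur <- sub[m] - sub[1]
      if (dur <= 0) next
      rate <- if (params$rate_definition == "isi") (m - 1) / dur else m / dur
      kind <- if (params$definition_profile == "native") {
        if (rate < params$train_min_rate) NA_character_
        else if (dur >= params$hpd_min_duration) "hpd"
        else if (dur >= params$train_duration[1] &&
                 dur < params$train_duration[2]) "spike_train"
        else NA_character_
      } else if (params$definition_profile == "sle_klein") {
        if (dur >= 3) "sle" else NA_character_
      } else if (params$definition_profile == "five_five") {
        if (dur >= 5 && rate >= 5) "hpd" else NA_character_
      } else {
        if (dur >= 20 && rate >= 10 && rate <= 20) "hpd" else NA_character_
      }
      if (!is.na(kind)) {
        out[[length(out) + 1]] <- data.frame(onset = sub[1], offset = sub[m],
                                             kind = kind, n_spikes = m)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(onset = numeric(), offset = numeric(),
                      kind = character(), n_spikes = integer()))
  }
  do.call(rbind, out)
}

# Pearson chi-square by the textbook formula, independent of stats::chisq.test.
brute_force_chisq <- function(obs) {
  E <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat <- sum((obs - E)^2 / E)
  df <- (nrow(obs) - 1) * (ncol(obs) - 1)
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

# Random spike-time sets for the oracle-equivalence property: clustered
# bursts plus scattered singles so that all definitional branches are hit.
random_spike_times <- function(n_max = 200) {
  n_bursts <- sample(0:6, 1)
  t <- numeric(0)
  for (b in seq_len(n_bursts)) {
    start <- runif(1, 0, 300)
    rate <- runif(1, 1, 8)
    dur <- runif(1, 0.5, 25)
    burst <- start + cumsum(c(0, (1 / rate) * (1 + runif(199, -0.3, 0.3))))
    t <- c(t, burst[burst < start + dur])
  }
  t <- c(t, runif(sample(0:20, 1), 0, 300))
  t <- sort(t)
  # enforce the detector's refractory contract
  if (length(t) > 1) t <- t[c(TRUE, diff(t) >= 0.070)]
  head(t, n_max)
}

# Match detected intervals against truth intervals by any-overlap; returns
# sensitivity and false-discovery rate for the given kinds treated jointly.
recovery_metrics <- function(truth_events, detected_events,
                             kinds = c("spike_train", "hpd")) {
  tr <- truth_events[truth_events$kind %in% kinds, , drop = FALSE]
  de <- detected_events[detected_events$kind %in% kinds, , drop = FALSE]
  overlaps <- function(a_on, a_off, b_on, b_off) a_on < b_off & b_on < a_off
  truth_hit <- vapply(seq_len(nrow(tr)), function(i) {
    any(overlaps(tr$onset[i], tr$offset[i], de$onset, de$offset))
  }, logical(1))
  det_hit <- vapply(seq_len(nrow(de)), function(i) {
    any(overlaps(de$onset[i], de$offset[i], tr$onset, tr$offset))
  }, logical(1))
  list(n_truth = nrow(tr), n_detected = nrow(de),
       sensitivity = if (nrow(tr)) mean(truth_hit) else NA_real_,
       fdr = if (nrow(de)) mean(!det_hit) else 0)
}

# Small deterministic recording: known sinusoids on 2 channels.
toy_recording <- function(duration = 10, rate = 500) {
  t <- (0:(duration * rate - 1)) / rate
  lfp_recording(list(channel_trace(50 * sin(2 * pi * 6 * t), "hippocampus_ipsi"),
                     channel_trace(30 * sin(2 * pi * 9 * t), "hippocampus_contra")),
                rate = rate)
}
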
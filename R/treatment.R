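#' Pre/post analysis windows around an injection
#'
#' Pre window: 64 to 5 min before the injection; post window: 35 to 94 min
#' after (the reported time of peak drug effect after i.p. administration).
#' Both windows are 59 min (3540 s) long, half-open.
#'
#' @param injection_time Injection time, s from session origin.
#' @param recording_duration Optional total duration (with `recording_start`)
#'   used to validate that both windows fit.
#' @param recording_start Session time of the first sample, s.
#' @return List of class `analysis_windows` with `pre` and `post`, each
#'   `c(start, end)`.
#' @export
make_windows <- function(injection_time, recording_duration = NULL,
                         recording_start = 0) {
  pre <- c(injection_time - 64 * 60, injection_time - 5 * 60)
  post <- c(injection_time + 35 * 60, injection_time + 94 * 60)
  if (!is.null(recording_duration)) {
    if (pre[1] < recording_start - 1e-9 ||
        post[2] > recording_start + recording_duration + 1e-9) {
      stop_range("recording too short: need >= 64 min before and ",
                 ">= 94 min after the injection")
    }
  } else if (pre[1] < 0) {
    stop_range("injection_time must be >= 64 min into the session")
  }
  structure(list(pre = pre, post = post), class = "analysis_windows")
}

#' Evaluate one treatment session
#'
#' Runs the detection chain and the spectral summary independently on the
#' pre and post windows of the ipsilateral hippocampal channel (the
#' mode baseline is re-estimated per window unless `shared_baseline`), flags
#' generalized seizures in the post window on all channels, and applies the
#' exclusion rule: sessions with a post-window generalized seizure are
#' excluded from event-rate analysis (post-ictal depression corrupts the
#' counts) but never from spectral analysis.
#'
#' @param recording An [lfp_recording()] covering both windows.
#' @param injection_time Injection time, s.
#' @param det A [detection_params()].
#' @param spec A [spectral_params()].
#' @param gen A [generalized_params()].
#' @param treatment_label,animal_id,session_id Bookkeeping labels.
#' @param shared_baseline If TRUE the pre-window mode baseline is reused for
#'   the post window.
#' @return List of class `session_result`: `rates_pre`, `rates_post`
#'   (one-row frames from [summarize_rates()]), `bands_pre`, `bands_post`
#'   ([band_power_summary()]), `generalized_post` (event table),
#'   `excluded_from_events`, `generalized_in_post`, labels and `windows`.
#' @export
evaluate_session <- function(recording, injection_time,
                             det = detection_params(),
                             spec = spectral_params(),
                             gen = generalized_params(),
                             treatment_label = NA_character_,
                             animal_id = NA_character_,
                             session_id = NA_character_,
                             shared_baseline = FALSE) {
  win <- make_windows(injection_time, rec_duration(recording),
                      recording$start_time)
  run_window <- function(w, baseline = NULL) {
    sub <- slice_window(recording, w[1], w[2])
    ch <- rec_channel(sub, "hippocampus_ipsi")
    filt <- bandpass(ch, sub$rate, det$filter)
    bl <- baseline %||% estimate_baseline(filt, sub$rate, det)
    spikes <- detect_spikes(filt, sub$rate, bl, det$refractory,
                            start_time = sub$start_time)
    events <- group_events(spikes, det)
    list(baseline = bl, events = events,
         rates = summarize_rates(events, w),
         bands = band_power_summary(filt, sub$rate, spec))
  }
  pre <- run_window(win$pre)
  post <- run_window(win$post, baseline = if (shared_baseline) pre$baseline)
  gs_post <- detect_generalized(slice_window(recording, win$post[1], win$post[2]), gen)
  gen_in_post <- nrow(gs_post) > 0
  structure(list(session_id = session_id, animal_id = animal_id,
                 treatment_label = treatment_label, windows = win,
                 rates_pre = pre$rates, rates_post = post$rates,
                 bands_pre = post_bands_strip(pre$bands),
                 bands_post = post_bands_strip(post$bands),
                 baseline_pre = pre$baseline, baseline_post = post$baseline,
                 generalized_post = gs_post,
                 generalized_in_post = gen_in_post,
                 excluded_from_events = gen_in_post),
            class = "session_result")
}

# Drop the bulky spectrogram before storing per-session summaries.
post_bands_strip <- function(b) {
  list(bands = b$bands, coastline = b$coastline, log_coastline = b$log_coastline)
}

#' Assign animals to high-/low-HPD groups
#'
#' Animals with a cumulative HPD duration strictly above the cutoff
#' (50 s/h) at the reference (2-month) session form the high-HPDs group;
#' the remainder the low-HPDs group.
#'
#' @param summaries Data.frame with columns `animal_id` and `dur_hpds`
#'   (s/h), one row per animal.
#' @param cutoff Threshold in s/h.
#' @return Data.frame: `animal_id`, `dur_hpds`, `group`, `cutoff`.
#' @export
assign_groups <- function(summaries, cutoff = 50) {
  if (anyDuplicated(summaries$animal_id)) {
    stop_validation("duplicate animal_id in group assignment input")
  }
  data.frame(animal_id = summaries$animal_id, dur_hpds = summaries$dur_hpds,
             group = ifelse(summaries$dur_hpds > cutoff, "high_hpds", "low_hpds"),
             cutoff = cutoff)
}

#' Chi-square test on generalized-seizure occurrence by treatment
#'
#' Pearson chi-square, no continuity correction, on the 2 x k contingency
#' table of (animals with / without a post-treatment generalized seizure)
#' per treatment; df = k - 1.
#'
#' @param table Data.frame with columns `treatment`, `n_with`, `n_without`.
#' @return List: `statistic`, `df`, `p_value`, `expected` (matrix).
#' @export
occurrence_chisq <- function(table) {
  if (nrow(table) < 2) stop_validation("need >= 2 treatments")
  if (any(table$n_with < 0 | table$n_without < 0)) {
    stop_validation("counts must be nonnegative")
  }
  if (any(table$n_with + table$n_without == 0)) {
    stop_validation("every treatment row must have at least one animal")
  }
  obs <- rbind(with = table$n_with, without = table$n_without)
  colnames(obs) <- table$treatment
  ht <- suppressWarnings(stats::chisq.test(obs, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' Sidak-adjusted significance threshold
#'
#' `alpha_adj = 1 - (1 - alpha)^(1/m)` for `m` simultaneous comparisons.
#'
#' @param alpha Family-wise error rate.
#' @param m Number of comparisons.
#' @export
sidak_alpha <- function(alpha = 0.05, m = 1) 1 - (1 - alpha)^(1 / m)

# Pull one scalar measure out of a session_result for a given period.
session_measure <- function(res, measure, period = c("pre", "post")) {
  period <- match.arg(period)
  rates <- if (period == "pre") res$rates_pre else res$rates_post
  bands <- if (period == "pre") res$bands_pre else res$bands_post
  if (measure %in% names(rates)) return(rates[[measure]])
  if (measure == "coastline") return(bands$log_coastline)
  bi <- match(measure, bands$bands$band)
  if (!is.na(bi)) return(bands$bands$log_power[bi])
  stop_config("unknown measure: ", measure)
}

#' Paired pre/post summary table across sessions
#'
#' For each treatment: n usable sessions, mean and SD of the measure pre and
#' post, the mean paired difference (post - pre) and a paired t statistic
#' with its p-value, plus the Sidak-adjusted alpha for the family of
#' treatments. Event-rate measures use only sessions not excluded by the
#' generalized-seizure rule; spectral measures (band log-powers, coastline)
#' use all sessions. Treatments with fewer than 2 usable sessions are
#' flagged non-estimable rather than raising.
#'
#' @param results List of `session_result` objects.
#' @param measure One of `n_spike_trains`, `dur_spike_trains`, `n_hpds`,
#'   `dur_hpds`, a band name (log10 power), or `"coastline"`
#'   (log10 coastline).
#' @param alpha Family-wise error rate for the Sidak adjustment.
#' @return Tidy data.frame, one row per treatment: `treatment`, `measure`,
#'   `n`, `mean_pre`, `sd_pre`, `mean_post`, `sd_post`, `mean_diff`,
#'   `t_statistic`, `p_value`, `alpha_sidak`, `estimable`.
#' @export
paired_prepost_summary <- function(results, measure, alpha = 0.05) {
  is_event_measure <- measure %in% c("n_spike_trains", "dur_spike_trains",
                                     "n_hpds", "dur_hpds", "n_sles", "dur_sles")
  labs <- vapply(results, function(r) r$treatment_label, character(1))
  treatments <- unique(labs)
  m <- length(treatments)
  rows <- lapply(treatments, function(tr) {
    rs <- results[labs == tr]
    if (is_event_measure) {
      rs <- Filter(function(r) !isTRUE(r$excluded_from_events), rs)
    }
    pre <- vapply(rs, session_measure, double(1), measure = measure, period = "pre")
    post <- vapply(rs, session_measure, double(1), measure = measure, period = "post")
    n <- length(pre)
    if (n < 2) {
      return(data.frame(treatment = tr, measure = measure, n = n,
                        mean_pre = if (n) mean(pre) else NA_real_, sd_pre = NA_real_,
                        mean_post = if (n) mean(post) else NA_real_, sd_post = NA_real_,
                        mean_diff = if (n) mean(post - pre) else NA_real_,
                        t_statistic = NA_real_, p_value = NA_real_,
                        alpha_sidak = sidak_alpha(alpha, m), estimable = FALSE))
    }
    d <- post - pre
    tstat <- if (sd(d) > 0) mean(d) / (sd(d) / sqrt(n)) else NA_real_
    pval <- if (is.na(tstat)) if (all(d == 0)) 1 else NA_real_
            else 2 * pt(-abs(tstat), df = n - 1)
    data.frame(treatment = tr, measure = measure, n = n,
               mean_pre = mean(pre), sd_pre = sd(pre),
               mean_post = mean(post), sd_post = sd(post),
               mean_diff = mean(d), t_statistic = tstat, p_value = pval,
               alpha_sidak = sidak_alpha(alpha, m), estimable = TRUE)
  })
  do.call(rbind, rows)
}

#' Build the seizure-occurrence table from session results
#'
#' @param results List of `session_result` objects.
#' @return Data.frame `treatment`, `n_with`, `n_without` suitable for
#'   [occurrence_chisq()].
#' @export
occurrence_table <- function(results) {
  labs <- vapply(results, function(r) r$treatment_label, character(1))
  gs <- vapply(results, function(r) isTRUE(r$generalized_in_post), logical(1))
  agg <- tapply(gs, labs, function(v) c(sum(v), sum(!v)))
  data.frame(treatment = names(agg),
             n_with = vapply(agg, `[`, double(1), 1),
             n_without = vapply(agg, `[`, double(1), 2),
             row.names = NULL)
}
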
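#' Channel roles recognised by the package
#'
#' Recordings carry one trace per electrode. Event detection and spectral
#' analysis operate on the ipsilateral hippocampal channel; generalized-seizure
#' flagging uses all channels.
#'
#' @format Character vector of valid role names.
#' @export
CHANNEL_ROLES <- c("hippocampus_ipsi", "hippocampus_contra", "cortex", "other")

#' Construct a single LFP channel trace
#'
#' @param samples Numeric vector of amplitudes in microvolts (uV).
#' @param role Electrode role, one of [CHANNEL_ROLES].
#' @return An object of class `channel_trace`.
#' @export
channel_trace <- function(samples, role = "other") {
  role <- match.arg(role, CHANNEL_ROLES)
  samples <- as.double(samples)
  if (any(!is.finite(samples))) {
    stop_validation("channel samples must be finite microvolt values")
  }
  structure(list(role = role, samples = samples), class = "channel_trace")
}

#' Construct a multi-channel LFP recording
#'
#' The canonical container used throughout the package: an ordered list of
#' channel traces sharing one sampling rate, with amplitudes in microvolts.
#' Time is measured in seconds from the session origin; sample `i` (0-based)
#' covers the half-open interval `[i/rate, (i+1)/rate)`.
#'
#' @param channels List of [channel_trace()] objects (or a named list of
#'   numeric vectors, names taken as roles).
#' @param rate Sampling rate in samples/s (500 or 512 typical). Must exceed
#'   twice the highest analysis frequency (>= 160 samples/s).
#' @param start_time Seconds since session origin of the first sample.
#' @param animal_id Opaque label for the animal/session.
#' @return An object of class `lfp_recording`.
#' @examples
#' rec <- lfp_recording(list(hippocampus_ipsi = rnorm(1000)), rate = 500)
#' rec_duration(rec)
#' @export
lfp_recording <- function(channels, rate, start_time = 0, animal_id = NA_character_) {
  if (!is.list(channels) || length(channels) == 0) {
    stop_validation("channels must be a non-empty list")
  }
  channels <- lapply(seq_along(channels), function(i) {
    ch <- channels[[i]]
    if (inherits(ch, "channel_trace")) return(ch)
    nm <- names(channels)[i] %||% "other"
    channel_trace(ch, role = if (nm %in% CHANNEL_ROLES) nm else "other")
  })
  rate <- as.double(rate)
  if (!is.finite(rate) || rate < 160) {
    stop_validation("sampling rate must be >= 160 samples/s (2 x the 80 Hz band edge)")
  }
  lens <- vapply(channels, function(ch) length(ch$samples), integer(1))
  if (length(unique(lens)) != 1) {
    stop_validation("all channels must have identical length, got: ",
                    paste(lens, collapse = ", "))
  }
  roles <- vapply(channels, function(ch) ch$role, character(1))
  if (sum(roles == "hippocampus_ipsi") > 1) {
    stop_validation("at most one hippocampus_ipsi channel is allowed")
  }
  structure(list(rate = rate, start_time = as.double(start_time),
                 animal_id = animal_id, channels = channels),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s), %.6g s at %g Hz, start %g s\n",
              length(x$channels), rec_duration(x), x$rate, x$start_time))
  for (ch in x$channels) {
    cat(sprintf("  %-18s n=%d  range [%.1f, %.1f] uV\n", ch$role,
                length(ch$samples), min(ch$samples), max(ch$samples)))
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording An [lfp_recording()].
#' @export
rec_duration <- function(recording) {
  length(recording$channels[[1]]$samples) / recording$rate
}

#' Channel roles of a recording
#' @param recording An [lfp_recording()].
#' @export
rec_roles <- function(recording) {
  vapply(recording$channels, function(ch) ch$role, character(1))
}

#' Extract one channel by role
#' @param recording An [lfp_recording()].
#' @param role Role name; defaults to the ipsilateral hippocampus.
#' @export
rec_channel <- function(recording, role = "hippocampus_ipsi") {
  idx <- which(rec_roles(recording) == role)
  if (length(idx) == 0) {
    stop_config("recording has no channel with role '", role, "'")
  }
  recording$channels[[idx[1]]]
}

#' Slice a time window out of a recording
#'
#' Windows are half-open `[start, end)` in absolute session time. The sample
#' count of the result is `floor((end - start) * rate)` and its `start_time`
#' is set to `start`, so slices at `[0, t)` and `[t, T)` concatenate to the
#' original recording without duplicated samples.
#'
#' @param recording An [lfp_recording()].
#' @param start,end Window bounds in seconds (absolute session time).
#' @return An [lfp_recording()] covering `[start, end)`.
#' @export
slice_window <- function(recording, start, end) {
  t0 <- recording$start_time
  dur <- rec_duration(recording)
  if (!(start < end)) stop_range("empty window: start must be < end")
  if (start < t0 - 1e-9 || end > t0 + dur + 1e-9) {
    stop_range(sprintf("window [%g, %g) outside recording [%g, %g)",
                       start, end, t0, t0 + dur))
  }
  i0 <- round((start - t0) * recording$rate)
  n <- floor((end - start) * recording$rate + 1e-9)
  channels <- lapply(recording$channels, function(ch) {
    channel_trace(ch$samples[(i0 + 1):(i0 + n)], ch$role)
  })
  lfp_recording(channels, recording$rate, start_time = start,
                animal_id = recording$animal_id)
}

#' Construct a tidy event-interval table
#'
#' Detected or simulated events are exchanged as a plain data.frame with one
#' row per event: onset/offset in seconds (half-open `[onset, offset)`), the
#' event kind, the spike count, the mean intra-event spike rate in Hz, and
#' the channel role the event was observed on.
#'
#' @param onset,offset Numeric, seconds.
#' @param kind One of `"spike"`, `"spike_train"`, `"hpd"`, `"sle"`,
#'   `"generalized_seizure"`.
#' @param n_spikes Integer spike counts (0 allowed for generalized seizures).
#' @param mean_rate Mean spike rate in Hz (NA where undefined).
#' @param channel_role Role of the channel carrying the event.
#' @return A data.frame of class `event_intervals`.
#' @export
event_intervals <- function(onset = numeric(), offset = numeric(),
                            kind = character(), n_spikes = integer(),
                            mean_rate = numeric(), channel_role = character()) {
  kinds_ok <- c("spike", "spike_train", "hpd", "sle", "generalized_seizure")
  if (length(kind) && !all(kind %in% kinds_ok)) {
    stop_validation("unknown event kind: ",
                    paste(setdiff(kind, kinds_ok), collapse = ", "))
  }
  if (any(offset <= onset)) stop_validation("event offset must exceed onset")
  bad <- kind %in% c("spike_train", "hpd") & n_spikes < 3
  if (any(bad)) stop_validation("spike_train and hpd events need >= 3 spikes")
  df <- data.frame(onset = as.double(onset), offset = as.double(offset),
                   kind = as.character(kind), n_spikes = as.integer(n_spikes),
                   mean_rate = as.double(mean_rate),
                   channel_role = as.character(channel_role),
                   stringsAsFactors = FALSE)
  class(df) <- c("event_intervals", "data.frame")
  df
}

#' Read/write event intervals as a BED-like tab-separated file
#'
#' Columns: channel_role, onset_s, offset_s, kind, n_spikes, mean_rate.
#' @param events An `event_intervals` data.frame.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  out <- data.frame(channel_role = events$channel_role,
                    onset_s = events$onset, offset_s = events$offset,
                    kind = events$kind, n_spikes = events$n_spikes,
                    mean_rate = events$mean_rate)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  event_intervals(onset = df$onset_s, offset = df$offset_s, kind = df$kind,
                  n_spikes = df$n_spikes, mean_rate = df$mean_rate,
                  channel_role = df$channel_role)
}

#' Construct and validate a treatment schedule table
#'
#' One row per injection: animal, treatment label, dose (mg/kg), injection
#' time in seconds from session origin, and a session id. Consecutive
#' injections for the same animal must be separated by at least the washout
#' period (a Latin-square crossover constraint).
#'
#' @param df Data.frame with columns `animal_id`, `treatment_label`, `dose`,
#'   `injection_time`, `session_id`.
#' @param washout_h Minimum hours between injections per animal (default 72).
#' @param labels Allowed treatment labels; extensible.
#' @return The validated data.frame with class `treatment_schedule`.
#' @export
treatment_schedule <- function(df, washout_h = 72,
                               labels = c("vehicle", "DZP2.5", "LTG10", "LTG30",
                                          "OXC10", "OXC30", "LEV100", "LEV300")) {
  need <- c("animal_id", "treatment_label", "dose", "injection_time", "session_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_validation("schedule missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(df$treatment_label %in% labels)) {
    stop_validation("unknown treatment label(s): ",
                    paste(setdiff(df$treatment_label, labels), collapse = ", "))
  }
  for (a in unique(df$animal_id)) {
    tt <- sort(df$injection_time[df$animal_id == a])
    if (length(tt) > 1 && any(diff(tt) < washout_h * 3600)) {
      stop_validation("animal ", a, ": injections closer than the ",
                      washout_h, " h washout")
    }
  }
  attr(df, "washout_h") <- washout_h
  class(df) <- c("treatment_schedule", "data.frame")
  df
}
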
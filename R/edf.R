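# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores samples as little-endian 16-bit integers mapped linearly between
# per-signal physical and digital ranges; this loses amplitude resolution to
# 16-bit quantization, which callers must tolerate on round trips. One data
# record per second is written, so recordings are padded internally to whole
# seconds on write and the pad is dropped on read via the recorded duration.

edf_pad <- function(s, n) formatC(substr(s, 1, n), width = n, flag = "-")

role_to_label <- c(hippocampus_ipsi = "EEG HPC-ipsi", hippocampus_contra = "EEG HPC-contra",
                   cortex = "EEG Cortex", other = "EEG Other")

label_to_role <- function(label) {
  lab <- trimws(label)
  hit <- names(role_to_label)[match(lab, role_to_label)]
  ifelse(is.na(hit), "other", hit)
}

write_edf <- function(recording, path) {
  rate <- recording$rate
  if (abs(rate - round(rate)) > 1e-9) {
    stop_validation("EDF writer requires an integer sampling rate")
  }
  rate <- as.integer(round(rate))
  ns <- length(recording$channels)
  n <- length(recording$channels[[1]]$samples)
  n_rec <- as.integer(ceiling(n / rate))
  n_pad <- n_rec * rate - n

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(edf_pad(s, width), con, nchars = width, eos = NULL)

  wr("0", 8)                                    # version
  wr(recording$animal_id %||% "X", 80)          # patient id
  # stash start_time and exact duration in the recording-id field
  wr(sprintf("start_s=%.6f dur_s=%.6f", recording$start_time, n / rate), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)          # date/time (synthetic sessions)
  wr(as.character(256 * (ns + 1)), 8)
  wr("", 44)                                    # reserved
  wr(as.character(n_rec), 8)
  wr("1", 8)                                    # record duration, s
  wr(as.character(ns), 4)

  phys_min <- phys_max <- numeric(ns)
  for (i in seq_len(ns)) {
    x <- recording$channels[[i]]$samples
    rng <- range(x)
    span <- max(diff(rng), 1e-6)
    phys_min[i] <- rng[1] - 0.001 * span
    phys_max[i] <- rng[2] + 0.001 * span
  }
  for (i in seq_len(ns)) wr(role_to_label[[recording$channels[[i]]$role]], 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", phys_min[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", phys_max[i]), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)             # prefiltering
  for (i in seq_len(ns)) wr(as.character(rate), 8)
  for (i in seq_len(ns)) wr("", 32)             # reserved

  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- c(recording$channels[[i]]$samples, rep(0, n_pad))
    d <- round((x - phys_min[i]) / (phys_max[i] - phys_min[i]) * 65535 - 32768)
    dig[[i]] <- as.integer(pmin(pmax(d, -32768), 32767))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    for (i in seq_len(ns)) writeBin(dig[[i]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)
  animal_id <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.double(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  phys_min <- vapply(seq_len(ns), function(i) as.double(rd(8)), double(1))
  phys_max <- vapply(seq_len(ns), function(i) as.double(rd(8)), double(1))
  dig_min <- vapply(seq_len(ns), function(i) as.double(rd(8)), double(1))
  dig_max <- vapply(seq_len(ns), function(i) as.double(rd(8)), double(1))
  for (i in seq_len(ns)) rd(80)
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)

  rate <- nsamp[1] / rec_dur
  if (length(unique(nsamp)) != 1) {
    stop_validation("EDF channels with differing per-record sample counts")
  }
  raw <- lapply(seq_len(ns), function(i) integer(0))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw[[i]] <- c(raw[[i]], readBin(con, "integer", nsamp[i], size = 2,
                                      signed = TRUE, endian = "little"))
    }
  }
  start_time <- 0; n_keep <- n_rec * nsamp[1]
  m <- regmatches(rec_id, regexec("start_s=([0-9.eE+-]+) dur_s=([0-9.eE+-]+)", rec_id))[[1]]
  if (length(m) == 3) {
    start_time <- as.double(m[2])
    n_keep <- round(as.double(m[3]) * rate)
  }
  channels <- lapply(seq_len(ns), function(i) {
    scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    x <- (raw[[i]] - dig_min[i]) * scale + phys_min[i]
    if (grepl("^mV$", units[i], ignore.case = TRUE)) x <- x * 1000
    channel_trace(x[seq_len(n_keep)], label_to_role(labels[i]))
  })
  lfp_recording(channels, rate, start_time = start_time,
                animal_id = if (nzchar(animal_id)) animal_id else NA_character_)
}
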
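#' Read an LFP recording from disk
#'
#' Three on-disk representations are supported:
#' * `"delimited"` — CSV with a `time_s` column and one `<name>_uV` column per
#'   channel (e.g. `time_s,ipsi_uV,contra_uV,cortex_uV`); comma separator,
#'   `.` decimal, header required. The sampling rate is inferred from the
#'   time column.
#' * `"edf"` — European Data Format, 16-bit quantized amplitudes.
#' * `"container"` — RDS serialization of the `lfp_recording`, lossless.
#'
#' @param path File path.
#' @param format One of `"edf"`, `"delimited"`, `"container"`; `"auto"` picks
#'   by file extension (.edf/.csv/.rds).
#' @return A validated [lfp_recording()], amplitudes in microvolts.
#' @export
read_recording <- function(path, format = c("auto", "edf", "delimited", "container")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", csv = "delimited", txt = "delimited",
                     rds = "container",
                     stop_config("cannot infer format from extension of ", path))
  }
  switch(format,
    edf = read_edf(path),
    container = {
      rec <- readRDS(path)
      if (!inherits(rec, "lfp_recording")) {
        stop_validation("container does not hold an lfp_recording")
      }
      lfp_recording(rec$channels, rec$rate, rec$start_time, rec$animal_id)
    },
    delimited = {
      df <- data.table::fread(path, sep = ",", dec = ".", data.table = FALSE)
      if (!"time_s" %in% names(df)) {
        stop_validation("delimited recording needs a time_s column")
      }
      chan_cols <- grep("_uV$", names(df), value = TRUE)
      if (length(chan_cols) == 0) stop_validation("no *_uV channel columns found")
      dt <- diff(df$time_s)
      if (length(dt) < 1 || any(dt <= 0)) {
        stop_validation("time_s must be strictly increasing; sampling rate undeterminable")
      }
      rate <- 1 / median(dt)
      role_map <- c(ipsi = "hippocampus_ipsi", contra = "hippocampus_contra",
                    cortex = "cortex")
      channels <- lapply(chan_cols, function(cl) {
        key <- sub("_uV$", "", cl)
        channel_trace(df[[cl]], role_map[key] %||% "other")
      })
      lfp_recording(channels, round(rate, 6), start_time = df$time_s[1])
    })
}

#' Write an LFP recording to disk
#'
#' Inverse of [read_recording()]; round trips preserve sampling rate, channel
#' roles and samples within the format's precision (exact for `"container"`,
#' 16-bit quantized for `"edf"`, printed decimal precision for `"delimited"`).
#'
#' @param recording An [lfp_recording()].
#' @param path Output path.
#' @param format One of `"edf"`, `"delimited"`, `"container"`, or `"auto"`.
#' @export
write_recording <- function(recording, path,
                            format = c("auto", "edf", "delimited", "container")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", csv = "delimited", rds = "container",
                     stop_config("cannot infer format from extension of ", path))
  }
  switch(format,
    edf = write_edf(recording, path),
    container = saveRDS(recording, path),
    delimited = {
      n <- length(recording$channels[[1]]$samples)
      t <- recording$start_time + (seq_len(n) - 1) / recording$rate
      cols <- list(time_s = t)
      role_key <- c(hippocampus_ipsi = "ipsi", hippocampus_contra = "contra",
                    cortex = "cortex", other = "other")
      for (ch in recording$channels) {
        nm <- paste0(role_key[[ch$role]], "_uV")
        while (nm %in% names(cols)) nm <- paste0(nm, "x")
        cols[[nm]] <- ch$samples
      }
      data.table::fwrite(as.data.frame(cols), path, sep = ",")
    })
  invisible(path)
}

#' Read detection/spectral parameters from a YAML config
#'
#' Top-level keys `detection`, `spectral`, `generalized` map onto
#' [detection_params()], [spectral_params()] and [generalized_params()];
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return Named list with any of `detection`, `spectral`, `generalized`.
#' @export
read_params_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("detection", "spectral", "generalized")
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop_config("unknown config section(s): ", paste(extra, collapse = ", "))
  out <- list()
  if (!is.null(raw$detection)) out$detection <- do.call(detection_params, raw$detection)
  if (!is.null(raw$spectral)) {
    sp <- raw$spectral
    if (!is.null(sp$bands)) {
      sp$bands <- do.call(rbind, lapply(sp$bands, as.data.frame))
    }
    out$spectral <- do.call(spectral_params, sp)
  }
  if (!is.null(raw$generalized)) out$generalized <- do.call(generalized_params, raw$generalized)
  out
}
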
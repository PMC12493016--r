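#' Multi-channel EEG recording
#'
#' In-memory container for a polysomnographic EEG recording: a list of
#' equal-length numeric channel vectors in microvolts plus the sampling rate.
#'
#' @param data named list of numeric vectors (one per channel, uV) or a
#'   numeric matrix with channels in columns.
#' @param sampling_rate_hz sampling rate in Hz (> 0).
#' @param channel_labels 10-20-system channel names; defaults to the names
#'   of `data`.
#' @param start_time_s recording start offset in seconds (0 for synthetic).
#' @param reference free-text reference description.
#' @return object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(list(Fz = sin(seq_len(500) / 10)), 500)
#' n_samples(rec)
#' @export
eeg_recording <- function(data, sampling_rate_hz,
                          channel_labels = NULL,
                          start_time_s = 0,
                          reference = "linked mastoids") {
  if (is.matrix(data)) {
    labs <- colnames(data)
    data <- lapply(seq_len(ncol(data)), function(j) data[, j])
    names(data) <- labs
  }
  if (!is.list(data) || !length(data))
    stop("data must be a non-empty list of channel vectors")
  if (is.null(channel_labels)) channel_labels <- names(data)
  if (is.null(channel_labels) || any(!nzchar(channel_labels)))
    stop("channel labels are required")
  if (length(channel_labels) != length(data))
    stop("channel_labels length must match the number of channels")
  names(data) <- channel_labels
  lens <- vapply(data, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("all channels must have the same length")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a single positive number")
  for (ch in channel_labels) {
    if (!is.numeric(data[[ch]]))
      stop("channel ", ch, " is not numeric")
    if (anyNA(data[[ch]]) || any(!is.finite(data[[ch]])))
      stop("channel ", ch, " contains non-finite samples")
    data[[ch]] <- as.numeric(data[[ch]])
  }
  structure(
    list(channel_labels = channel_labels,
         sampling_rate_hz = sampling_rate_hz,
         data = data,
         start_time = start_time_s,
         reference = reference),
    class = "eeg_recording")
}

#' @rdname eeg_recording
#' @param rec an `eeg_recording`.
#' @export
n_samples <- function(rec) length(rec$data[[1]])

#' @rdname eeg_recording
#' @export
duration_s <- function(rec) n_samples(rec) / rec$sampling_rate_hz

#' Extract one channel of a recording
#' @param rec an `eeg_recording`.
#' @param channel channel label; errors if absent.
#' @return numeric vector of samples in uV.
#' @export
get_channel <- function(rec, channel) {
  if (!channel %in% rec$channel_labels)
    stop("channel not found in recording: ", channel,
         " (available: ", paste(rec$channel_labels, collapse = ", "), ")")
  rec$data[[channel]]
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              length(x$channel_labels), n_samples(x), x$sampling_rate_hz,
              duration_s(x)))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  cat("  reference:", x$reference, "\n")
  invisible(x)
}

#' Sleep-stage hypnogram
#'
#' Sequence of sleep stages scored per fixed-length epoch (30 s by default),
#' with per-epoch artefact and arousal flags.
#'
#' @param stages character vector over `Wake, N1, N2, N3, REM`.
#' @param epoch_length_s epoch length in seconds (> 0).
#' @param artefact,arousal logical vectors, one flag per epoch.
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_length_s = 30,
                      artefact = NULL, arousal = NULL) {
  valid <- c("Wake", "N1", "N2", "N3", "REM")
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), valid)
  if (length(bad))
    stop("unknown sleep stage token(s): ", paste(bad, collapse = ", "))
  n <- length(stages)
  if (is.null(artefact)) artefact <- rep(FALSE, n)
  if (is.null(arousal)) arousal <- rep(FALSE, n)
  if (length(artefact) != n || length(arousal) != n)
    stop("stages, artefact and arousal must have equal length")
  if (!is.numeric(epoch_length_s) || epoch_length_s <= 0)
    stop("epoch_length_s must be positive")
  structure(
    list(epoch_length_s = epoch_length_s,
         stages = stages,
         artefact = as.logical(artefact),
         arousal = as.logical(arousal)),
    class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = c("Wake", "N1", "N2", "N3", "REM")))
  cat(sprintf("<hypnogram> %d x %g-s epochs (%.1f min)\n",
              length(x$stages), x$epoch_length_s,
              length(x$stages) * x$epoch_length_s / 60))
  print(tab)
  invisible(x)
}

#' Epoch index for each sample time
#'
#' Maps sample times (seconds from recording start) to 1-based epoch indices
#' of a hypnogram. Epochs are half-open `[start, end)`.
#' @param t_s numeric vector of times in seconds.
#' @param hyp a [hypnogram()].
#' @return integer epoch indices (NA outside the staged range).
#' @export
epoch_at <- function(t_s, hyp) {
  idx <- floor(t_s / hyp$epoch_length_s) + 1L
  idx[idx < 1L | idx > length(hyp$stages)] <- NA_integer_
  as.integer(idx)
}

#' Per-sample logical mask of artefact-free epochs in given stages
#' @param n integer number of samples.
#' @param fs sampling rate in Hz.
#' @param hyp a [hypnogram()].
#' @param stages stage labels to include.
#' @return logical vector of length `n`.
#' @export
stage_mask <- function(n, fs, hyp, stages = c("N2", "N3")) {
  ok_epoch <- hyp$stages %in% stages & !hyp$artefact
  spe <- hyp$epoch_length_s * fs
  idx <- pmin(length(ok_epoch), floor((seq_len(n) - 1) / spe) + 1)
  ok_epoch[idx]
}

#' Read a plain-text hypnogram
#'
#' One stage token (`Wake`, `N1`, `N2`, `N3`, `REM`) per line, 30-s epochs by
#' default; `#` starts a comment; an optional second and third whitespace-
#' separated field per line give the artefact and arousal flags (0/1).
#'
#' @param path file path.
#' @param epoch_length_s epoch length in seconds.
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_length_s = 30) {
  if (!file.exists(path)) stop("hypnogram file not found: ", path)
  raw <- readLines(path)
  raw_nocomment <- sub("#.*$", "", raw)
  keep <- which(nzchar(trimws(raw_nocomment)))
  fields <- strsplit(trimws(raw_nocomment[keep]), "\\s+")
  stages <- vapply(fields, `[[`, character(1), 1)
  valid <- c("Wake", "N1", "N2", "N3", "REM")
  bad <- which(!stages %in% valid)
  if (length(bad))
    stop(sprintf("unknown stage token '%s' at line %d of %s",
                 stages[bad[1]], keep[bad[1]], path))
  flag <- function(k) vapply(fields, function(f)
    if (length(f) >= k) as.logical(as.integer(f[[k]])) else FALSE, logical(1))
  hypnogram(stages, epoch_length_s, artefact = flag(2), arousal = flag(3))
}

#' Write a hypnogram as plain text
#' @param hyp a [hypnogram()].
#' @param path output path.
#' @export
write_hypnogram <- function(hyp, path) {
  lines <- sprintf("%s %d %d", hyp$stages,
                   as.integer(hyp$artefact), as.integer(hyp$arousal))
  writeLines(c(sprintf("# hypnogram: %g-s epochs", hyp$epoch_length_s), lines),
             path)
  invisible(path)
}

EVENT_SCHEMA_VERSION <- "soclas-events-1"

#' Write an event table to CSV
#'
#' Events (SO, spindle or trigger tables) are data frames; times are seconds
#' from recording start with millisecond precision or better. A schema
#' version comment line precedes the header.
#'
#' @param events data frame of events.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", EVENT_SCHEMA_VERSION), con)
  utils::write.csv(events, con, row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#' @param path CSV path.
#' @return data frame of events.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1L else 0L
  utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
}

#' Save / load a recording in the package's native container
#'
#' The native container stores channel data as doubles, so round-trips are
#' bit-exact, unlike 16-bit EDF export. It is an RDS serialisation of the
#' `eeg_recording` structure.
#'
#' @param rec an [eeg_recording()].
#' @param path file path (conventionally `.rds`).
#' @return `read_native` returns the restored `eeg_recording`.
#' @export
write_native <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname write_native
#' @export
read_native <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- readRDS(path)
  if (!inherits(rec, "eeg_recording"))
    stop("not a native eeg_recording container: ", path)
  rec
}

#' Read an EEG recording from EDF or the native container
#'
#' Dispatches on file extension: `.edf` via the built-in EDF reader,
#' anything else via [read_native()].
#'
#' @param path file path.
#' @param channels optional label subset; returned in the requested order.
#' @return an [eeg_recording()] in uV.
#' @export
read_recording <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  rec <- if (grepl("\\.edf$", path, ignore.case = TRUE)) read_edf(path)
         else read_native(path)
  if (!is.null(channels)) {
    missing <- setdiff(channels, rec$channel_labels)
    if (length(missing))
      stop("channel not found in recording: ",
           paste(missing, collapse = ", "))
    rec$data <- rec$data[channels]
    rec$channel_labels <- channels
  }
  rec
}

#' @rdname read_recording
#' @param rec an [eeg_recording()].
#' @export
write_recording <- function(rec, path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) write_edf(rec, path)
  else write_native(rec, path)
}
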
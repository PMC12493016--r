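# Minimal European Data Format (EDF) support: continuous 16-bit records,
# 1-s data records, no annotations. Sufficient for exchanging synthetic and
# replayed polysomnography with standard viewers. EDF quantises each channel
# to 16 bits over its physical range, so round-trips are exact only to one
# quantisation step; use the native container where bit-exactness matters.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Uses 1-second data records, so the sampling rate must be a whole number.
#' Recordings whose length is not a whole number of seconds are zero-padded
#' to the next full record. Each channel's physical range is set to its
#' observed extrema (symmetrised), giving the finest 16-bit quantisation the
#' data allow.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate_hz
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  fs <- as.integer(fs)
  ns <- length(rec$channel_labels)
  n <- n_samples(rec)
  n_rec <- as.integer(ceiling(n / fs))
  phys_rng <- lapply(rec$data, function(x) {
    m <- max(abs(x), 1e-6)
    c(-m, m)
  })
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),                       # patient id
    edf_pad("Startdate X X X X", 80),             # recording id
    edf_pad("01.01.00", 8),                       # start date
    edf_pad("00.00.00", 8),                       # start time
    edf_pad(256 * (1 + ns), 8),                   # header bytes
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),                              # record duration (s)
    edf_pad(ns, 4))
  field <- function(vals, width)
    paste(vapply(vals, edf_pad, character(1), width = width), collapse = "")
  hdr <- paste0(
    hdr,
    field(rec$channel_labels, 16),
    field(rep("", ns), 80),                       # transducer
    field(rep("uV", ns), 8),
    field(vapply(phys_rng, function(r) sprintf("%.6g", r[1]), character(1)), 8),
    field(vapply(phys_rng, function(r) sprintf("%.6g", r[2]), character(1)), 8),
    field(rep("-32768", ns), 8),
    field(rep("32767", ns), 8),
    field(rep("", ns), 80),                       # prefiltering
    field(rep(fs, ns), 8),
    field(rep("", ns), 32))
  writeBin(charToRaw(hdr), con)
  dig <- vector("list", ns)
  for (j in seq_len(ns)) {
    x <- c(rec$data[[j]], numeric(n_rec * fs - n))
    r <- phys_rng[[j]]
    d <- round((x - r[1]) / (r[2] - r[1]) * 65535 - 32768)
    dig[[j]] <- as.integer(pmin(32767, pmax(-32768, d)))
  }
  for (k in seq_len(n_rec)) {
    sl <- ((k - 1) * fs + 1):(k * fs)
    for (j in seq_len(ns)) writeBin(dig[[j]][sl], con, size = 2,
                                    endian = "little")
  }
  invisible(path)
}

#' Read an EDF/EDF+ recording
#'
#' Supports continuous recordings with a common integer sampling rate across
#' ordinary signal channels; an `EDF Annotations` channel, if present, is
#' skipped.
#'
#' @param path EDF file path.
#' @return an [eeg_recording()] with samples in the file's physical units
#'   (uV for EEG channels written by [write_edf()]).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) {
    out <- rawToChar(readBin(con, "raw", nc))
    trimws(out)
  }
  rd(8)                                            # version
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("unreadable EDF header: ", path)
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width),
                                character(1))
  labels <- rdv(16)
  rdv(80)
  rdv(8)                                           # physical dimension
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))                        # samples per record
  rdv(32)
  seek(con, hdr_bytes)
  keep <- !grepl("EDF Annotations", labels, fixed = TRUE)
  data <- lapply(seq_len(ns), function(j) numeric(n_rec * spr[j]))
  for (k in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      v <- readBin(con, "integer", spr[j], size = 2, signed = TRUE,
                   endian = "little")
      data[[j]][((k - 1) * spr[j] + 1):(k * spr[j])] <- v
    }
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (j in seq_len(ns))
    data[[j]] <- (data[[j]] - dig_min[j]) * gain[j] + phys_min[j]
  data <- data[keep]
  labels <- labels[keep]
  spr <- spr[keep]
  if (length(unique(spr)) != 1)
    stop("EDF channels with differing sampling rates are not supported")
  names(data) <- labels
  eeg_recording(data, sampling_rate_hz = spr[1] / rec_dur,
                channel_labels = labels, reference = "as recorded")
}
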
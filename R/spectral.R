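# Welch spectra on the Hanning/4096 grid, band powers, and stimulus-locked
# ERP / spindle-RMS time courses with baseline normalisation.

#' Welch power spectral density
#'
#' Average of Hanning-windowed periodograms over segments with the given
#' overlap, normalised so that a unit-variance white signal integrates to
#' approximately 1 (density in uV^2/Hz).
#'
#' @param x numeric signal (uV).
#' @param fs_hz sampling rate in Hz.
#' @param nfft segment length in samples.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return object of class `power_spectrum` with fields `freqs_hz` (0 to
#'   Nyquist, spacing `fs_hz / nfft`), `psd` and `n_segments`.
#' @export
welch_psd <- function(x, fs_hz, nfft = 4096, overlap = 0.5) {
  n <- length(x)
  if (n < nfft)
    stop(sprintf("signal too short for Welch estimate: need >= %d samples, got %d",
                 nfft, n))
  step <- max(1, round(nfft * (1 - overlap)))
  starts <- seq(1, n - nfft + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nfft) - 1) / (nfft - 1)))  # Hann
  norm <- fs_hz * sum(w^2)
  n_half <- nfft %/% 2
  acc <- numeric(n_half + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)] * w
    p <- abs(stats::fft(seg))^2 / norm
    p1 <- p[1:(n_half + 1)]
    p1[2:n_half] <- 2 * p1[2:n_half]   # one-sided
    acc <- acc + p1
  }
  structure(list(freqs_hz = (0:n_half) * fs_hz / nfft,
                 psd = acc / length(starts),
                 n_segments = length(starts),
                 fs_hz = fs_hz, nfft = nfft),
            class = "power_spectrum")
}

#' NREM power spectrum of a recording
#'
#' Welch estimate restricted to artefact-free N2/N3 epochs: segments of
#' `fft_n` samples with `fft_overlap` overlap are taken within each
#' contiguous run of eligible epochs and their Hanning periodograms
#' averaged. With the defaults (4096 points at 500 Hz) the frequency
#' resolution is fs/4096 = 0.122 Hz and each window spans 8.19 s.
#'
#' @param rec an [eeg_recording()].
#' @param hyp a [hypnogram()] aligned to the recording.
#' @param config a [session_config()].
#' @param channels channels to estimate (default all).
#' @param stages epochs to include.
#' @return named list of `power_spectrum`, one per channel.
#' @export
power_spectrum <- function(rec, hyp, config = session_config(),
                           channels = rec$channel_labels,
                           stages = c("N2", "N3")) {
  fs <- rec$sampling_rate_hz
  mask <- stage_mask(n_samples(rec), fs, hyp, stages)
  runs <- mask_runs(mask)
  nfft <- config$fft_n
  runs <- runs[(runs$end - runs$start + 1) >= nfft, , drop = FALSE]
  if (!nrow(runs))
    stop(sprintf("no contiguous eligible segment of >= %d samples", nfft))
  out <- lapply(channels, function(ch) {
    x <- get_channel(rec, ch)
    step <- max(1, round(nfft * (1 - config$fft_overlap)))
    acc <- NULL; nseg <- 0
    for (r in seq_len(nrow(runs))) {
      ps <- welch_psd(x[runs$start[r]:runs$end[r]], fs, nfft,
                      config$fft_overlap)
      if (is.null(acc)) acc <- ps$psd * ps$n_segments
      else acc <- acc + ps$psd * ps$n_segments
      nseg <- nseg + ps$n_segments
    }
    structure(list(freqs_hz = (0:(nfft %/% 2)) * fs / nfft,
                   psd = acc / nseg, n_segments = nseg,
                   fs_hz = fs, nfft = nfft),
              class = "power_spectrum")
  })
  names(out) <- channels
  out
}

# contiguous TRUE runs of a logical mask -> data.frame(start, end), 1-based
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Band power in half-open frequency bands
#'
#' Integrates the PSD over each `[low, high)` band and logarithmises, the
#' convention used before statistics on EEG band power. Adjacent bands
#' partition exactly: the slow-wave-activity band equals the sum of the SO
#' and delta bands.
#'
#' @param spectrum a `power_spectrum`.
#' @param bands_hz named list of `(low, high)` pairs; defaults to the
#'   standard band set (SO 0.5-1.5, delta 1.5-4, SWA 0.5-4, theta 4-9,
#'   slow spindle 9.5-12.5, fast spindle 12.5-15.5 Hz).
#' @return data frame with columns `band`, `power_uv2`, `log10_power`.
#' @export
band_powers <- function(spectrum, bands_hz = session_config()$bands_hz) {
  df <- spectrum$freqs_hz[2] - spectrum$freqs_hz[1]
  out <- lapply(names(bands_hz), function(b) {
    rng <- bands_hz[[b]]
    if (rng[1] < 0 || rng[2] > max(spectrum$freqs_hz) + df)
      stop("band ", b, " outside spectrum range")
    sel <- spectrum$freqs_hz >= rng[1] & spectrum$freqs_hz < rng[2]
    p <- sum(spectrum$psd[sel]) * df
    if (p <= 0)
      stop("zero power in band ", b, "; log10 power undefined")
    data.frame(band = b, power_uv2 = p, log10_power = log10(p))
  })
  do.call(rbind, out)
}

# centred moving average with shrinking windows at the edges
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  half <- k %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(0, seq_len(n) - half - 1)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

# pointwise RMS over a centred sliding window
sliding_rms <- function(x, k) sqrt(moving_average(x^2, k))

# zero-phase application of a linear-phase FIR (odd-length b assumed
# symmetric): filter (FFT overlap-add) then remove the integer group delay
fir_zerophase <- function(b, x) {
  d <- (length(b) - 1) %/% 2
  y <- as.numeric(signal::fftfilt(b, c(x, numeric(d))))
  y[(d + 1):(d + length(x))]
}

# FIR low-pass whose response is -3 dB at `db3_hz`: the Hamming fir1 cutoff
# is its -6 dB point, so the design cutoff is searched numerically
design_erp_lowpass <- function(fs_hz, db3_hz = 32, order = NULL) {
  if (is.null(order)) order <- 2 * floor(0.2 * fs_hz / 2)  # ~0.2 s, even
  resp_at <- function(cut_hz) {
    b <- signal::fir1(order, cut_hz / (fs_hz / 2), type = "low")
    h <- sum(b * exp(-2i * pi * db3_hz / fs_hz * (seq_along(b) - 1)))
    20 * log10(abs(h))
  }
  lo <- db3_hz; hi <- min(fs_hz / 2 * 0.9, db3_hz + 15)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (resp_at(mid) < -3) lo <- mid else hi <- mid
  }
  signal::fir1(order, ((lo + hi) / 2) / (fs_hz / 2), type = "low")
}

# FIR band-pass of given width centred on a peak frequency; order gives a
# ~1 Hz transition band (Hamming design)
design_spindle_bandpass <- function(fs_hz, centre_hz, width_hz, order = NULL) {
  if (is.null(order)) order <- 2 * ceiling(1.65 * fs_hz)
  edges <- c(centre_hz - width_hz / 2, centre_hz + width_hz / 2)
  signal::fir1(order, edges / (fs_hz / 2), type = "pass")
}

# low-pass at erp_lowpass (-3 dB near 32 Hz) and decimate to erp_fs
erp_downsample <- function(x, fs, config) {
  dec <- fs / config$erp_fs_hz
  if (dec != round(dec))
    stop("sampling rate must be an integer multiple of erp_fs_hz")
  b <- design_erp_lowpass(fs, db3_hz = 32)
  y <- fir_zerophase(b, x)
  y[seq(1, length(y), by = dec)]
}

new_stim_locked_set <- function(time_s, epochs, n_excluded, channel,
                                baseline_applied = FALSE,
                                baseline_window_s = NULL) {
  m <- colMeans(epochs)
  sem <- if (nrow(epochs) > 1)
    apply(epochs, 2, stats::sd) / sqrt(nrow(epochs)) else rep(0, ncol(epochs))
  structure(list(time_s = time_s, epochs = epochs, mean = m, sem = sem,
                 n_epochs = nrow(epochs), n_excluded = n_excluded,
                 channel = channel, baseline_applied = baseline_applied,
                 baseline_window_s = baseline_window_s),
            class = "stim_locked_set")
}

#' @export
print.stim_locked_set <- function(x, ...) {
  cat(sprintf(
    "<stim_locked_set> channel %s: %d epochs (%d excluded), %d samples %g..%g s%s\n",
    x$channel, x$n_epochs, x$n_excluded, length(x$time_s), min(x$time_s),
    max(x$time_s),
    if (x$baseline_applied) ", baseline-normalised" else ""))
  invisible(x)
}

#' Stimulus-locked average around trigger times
#'
#' Low-pass filters at 35 Hz (zero-phase FIR, -3 dB at 32 Hz), downsamples
#' to 100 Hz, extracts half-open `[-1, 3)` s windows time-locked to each
#' first-burst trigger (snapped to the 100-Hz grid), drops windows that
#' touch artefact epochs, epochs staged outside N2/N3 or the recording
#' edges, and averages.
#'
#' @param rec an [eeg_recording()].
#' @param trigger_times_s first-burst onset times in seconds.
#' @param hyp a [hypnogram()].
#' @param config a [session_config()].
#' @param channel channel label (default the first channel).
#' @return a `stim_locked_set` (see [baseline_normalize()]).
#' @export
extract_stim_locked <- function(rec, trigger_times_s, hyp,
                                config = session_config(),
                                channel = rec$channel_labels[1]) {
  fs <- rec$sampling_rate_hz
  x <- get_channel(rec, channel)
  y <- erp_downsample(x, fs, config)
  tmp <- eeg_recording(stats::setNames(list(y), channel), config$erp_fs_hz)
  extract_stim_locked_raw(tmp, trigger_times_s, hyp, config, channel)
}

#' Baseline-normalise a stimulus-locked set
#'
#' Subtracts from every epoch its own mean over the pre-stimulus reference
#' window (-0.99 to -0.01 s by default) and recomputes the summary traces.
#' Idempotent, and invariant to any DC offset of the raw recording.
#'
#' @param set a `stim_locked_set`.
#' @param config a [session_config()] (uses `baseline_window_s`).
#' @return the normalised `stim_locked_set`.
#' @export
baseline_normalize <- function(set, config = session_config()) {
  bw <- config$baseline_window_s
  if (bw[1] < min(set$time_s) || bw[2] > max(set$time_s))
    stop("baseline window outside the epoch window")
  sel <- set$time_s >= bw[1] & set$time_s <= bw[2]
  base <- rowMeans(set$epochs[, sel, drop = FALSE])
  ep <- sweep(set$epochs, 1, base)
  new_stim_locked_set(set$time_s, ep, set$n_excluded, set$channel,
                      baseline_applied = TRUE, baseline_window_s = bw)
}

#' Grand average across sessions
#'
#' Averages per-session mean traces (subject-level averaging precedes the
#' grand mean, as in per-subject statistics); SEM is across sessions.
#'
#' @param sets list of `stim_locked_set` on identical time grids.
#' @return a `stim_locked_set` whose `epochs` rows are the session means.
#' @export
grand_average_stim_locked <- function(sets) {
  if (!length(sets)) stop("no sessions to average")
  t0 <- sets[[1]]$time_s
  for (s in sets) if (!isTRUE(all.equal(s$time_s, t0)))
    stop("sessions are on different time grids")
  m <- do.call(rbind, lapply(sets, `[[`, "mean"))
  new_stim_locked_set(t0, m, 0L, sets[[1]]$channel,
                      baseline_applied = all(vapply(sets, `[[`, logical(1),
                                                    "baseline_applied")))
}

#' Stimulus-locked spindle RMS time courses
#'
#' Band-passes the signal in 3-Hz-wide bands centred on the individual slow
#' and fast spindle peak frequencies, computes the pointwise 0.2-s RMS
#' envelope, smooths it with a 0.2-s moving average, downsamples to the ERP
#' grid, extracts `[-1, 3)` s windows around the triggers and
#' baseline-normalises.
#'
#' @param rec an [eeg_recording()].
#' @param trigger_times_s first-burst times in seconds.
#' @param hyp a [hypnogram()].
#' @param peaks a `spindle_peaks` object from [estimate_spindle_peaks()].
#' @param config a [session_config()].
#' @param channel channel label.
#' @return list with `slow` and `fast` baseline-normalised
#'   `stim_locked_set`s.
#' @export
spindle_rms_locked <- function(rec, trigger_times_s, hyp, peaks,
                               config = session_config(),
                               channel = rec$channel_labels[1]) {
  fs <- rec$sampling_rate_hz
  x <- get_channel(rec, channel)
  one <- function(centre_hz) {
    b <- design_spindle_bandpass(fs, centre_hz, config$spindle_bandwidth_hz)
    xb <- fir_zerophase(b, x)
    r <- sliding_rms(xb, round(config$rms_window_s * fs))
    r <- moving_average(r, round(config$smooth_window_s * fs))
    dec <- fs / config$erp_fs_hz
    if (dec != round(dec))
      stop("sampling rate must be an integer multiple of erp_fs_hz")
    y <- r[seq(1, length(r), by = dec)]
    tmp_rec <- eeg_recording(stats::setNames(list(y), channel),
                             config$erp_fs_hz)
    set <- extract_stim_locked_raw(tmp_rec, trigger_times_s, hyp, config,
                                   channel)
    baseline_normalize(set, config)
  }
  list(slow = one(peaks$slow_peak_hz), fast = one(peaks$fast_peak_hz))
}

# epoch extraction on an already-downsampled signal (no filtering)
extract_stim_locked_raw <- function(rec, trigger_times_s, hyp, config,
                                    channel) {
  efs <- rec$sampling_rate_hz
  y <- get_channel(rec, channel)
  w0 <- round(config$erp_window_s[1] * efs)
  w1 <- round(config$erp_window_s[2] * efs) - 1
  rel <- w0:w1
  good <- stage_mask(length(y), efs, hyp, c("N2", "N3"))
  rows <- list(); n_excl <- 0L
  for (tt in trigger_times_s) {
    i0 <- round(tt * efs) + 1L
    idx <- i0 + rel
    if (idx[1] < 1 || idx[length(idx)] > length(y) || !all(good[idx])) {
      n_excl <- n_excl + 1L
      next
    }
    rows[[length(rows) + 1]] <- y[idx]
  }
  if (!length(rows))
    stop("no usable stimulus-locked windows (", n_excl, " excluded)")
  new_stim_locked_set(rel / efs, do.call(rbind, rows), n_excl, channel)
}
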
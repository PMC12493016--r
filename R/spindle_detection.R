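# Spindle detection at individual peak frequencies: 3-Hz-wide FIR band,
# 0.2-s RMS envelope smoothed over 0.2 s, 1.5 SD duration criterion
# (0.5-3 s) with a 2.5 SD peak criterion, and the sub-0.5-s-gap merge rule.
# Following the offline pipeline, detection operates on the 35-Hz
# low-passed signal downsampled to 100 Hz.

#' Individual spindle peak frequencies
#'
#' Finds the frequency of maximal mean power over artefact-free NREM sleep
#' within the slow (9-12 Hz) and fast (12-16 Hz) spindle search ranges, on
#' the Hanning/4096 Welch grid (resolution fs/4096, 0.12 Hz at 500 Hz).
#' Averaged over the requested channels. A peak sitting on a range boundary
#' or barely rising above the surrounding spectrum is flagged with a
#' warning.
#'
#' @param rec an [eeg_recording()].
#' @param hyp a [hypnogram()].
#' @param config a [session_config()].
#' @param channels channels whose spectra are averaged (default all).
#' @return object of class `spindle_peaks` with `slow_peak_hz` and
#'   `fast_peak_hz`.
#' @export
estimate_spindle_peaks <- function(rec, hyp, config = session_config(),
                                   channels = rec$channel_labels) {
  spectra <- power_spectrum(rec, hyp, config, channels)
  psd <- Reduce(`+`, lapply(spectra, `[[`, "psd")) / length(spectra)
  freqs <- spectra[[1]]$freqs_hz
  find_peak <- function(range, label) {
    sel <- which(freqs >= range[1] & freqs <= range[2])
    pk <- sel[which.max(psd[sel])]
    if (pk == sel[1] || pk == sel[length(sel)])
      warning(label, " spindle peak sits on the search-range boundary")
    if (psd[pk] < 1.5 * stats::median(psd[sel]))
      warning(label, " spindle peak has low prominence")
    freqs[pk]
  }
  structure(list(
    slow_peak_hz = find_peak(config$slow_spindle_range_hz, "slow"),
    fast_peak_hz = find_peak(config$fast_spindle_range_hz, "fast")),
    class = "spindle_peaks")
}

#' @export
print.spindle_peaks <- function(x, ...) {
  cat(sprintf("<spindle_peaks> slow %.2f Hz, fast %.2f Hz\n",
              x$slow_peak_hz, x$fast_peak_hz))
  invisible(x)
}

# one channel, one type: envelope thresholding with merge rule
detect_spindles_one <- function(y, efs, centre_hz, config, mask, sds = NULL) {
  b <- design_spindle_bandpass(efs, centre_hz, config$spindle_bandwidth_hz)
  yb <- fir_zerophase(b, y)
  sd_ref <- if (is.null(sds)) stats::sd(yb[mask]) else sds
  thr_lo <- config$spindle_thresh_sd * sd_ref
  thr_hi <- config$spindle_peak_sd * sd_ref
  env <- sliding_rms(yb, round(config$rms_window_s * efs))
  env <- moving_average(env, round(config$smooth_window_s * efs))
  runs <- mask_runs(env > thr_lo & mask)
  if (!nrow(runs)) return(list(events = NULL, sd_ref = sd_ref))
  dur <- (runs$end - runs$start + 1) / efs
  peak_ok <- vapply(seq_len(nrow(runs)), function(i)
    max(env[runs$start[i]:runs$end[i]]) > thr_hi, logical(1))
  ok <- dur >= config$spindle_dur_bounds_s[1] &
    dur <= config$spindle_dur_bounds_s[2] & peak_ok
  segs <- runs[ok, , drop = FALSE]
  if (!nrow(segs)) return(list(events = NULL, sd_ref = sd_ref))
  segs$dur <- dur[ok]
  # greedy left-to-right merge: gap < merge_gap_s and total supra-threshold
  # time below merge_total_max_s, otherwise segments stay separate
  ev <- list()
  cur <- segs[1, ]
  cur_total <- cur$dur; cur_from <- 1L
  flush <- function(seg, total, from) {
    data.frame(start_i = seg$start, end_i = seg$end,
               supra_s = total, merged_from = from)
  }
  if (nrow(segs) > 1) for (i in 2:nrow(segs)) {
    gap <- (segs$start[i] - cur$end - 1) / efs
    if (gap < config$merge_gap_s &&
        cur_total + segs$dur[i] < config$merge_total_max_s) {
      cur$end <- segs$end[i]
      cur_total <- cur_total + segs$dur[i]
      cur_from <- cur_from + 1L
    } else {
      ev[[length(ev) + 1]] <- flush(cur, cur_total, cur_from)
      cur <- segs[i, ]; cur_total <- cur$dur; cur_from <- 1L
    }
  }
  ev[[length(ev) + 1]] <- flush(cur, cur_total, cur_from)
  ev <- do.call(rbind, ev)
  ev$p2p <- vapply(seq_len(nrow(ev)), function(i) {
    seg <- yb[ev$start_i[i]:ev$end_i[i]]
    max(seg) - min(seg)
  }, numeric(1))
  ev$mean_rms <- vapply(seq_len(nrow(ev)), function(i)
    mean(env[ev$start_i[i]:ev$end_i[i]]), numeric(1))
  list(events = ev, sd_ref = sd_ref)
}

#' Detect sleep spindles
#'
#' Pipeline per channel and spindle type: 35-Hz low-pass and downsampling
#' to 100 Hz, FIR band-pass of `spindle_bandwidth_hz` (3 Hz) centred on the
#' individual peak frequency, pointwise RMS over a 0.2-s sliding window,
#' 0.2-s moving-average smoothing, then thresholding at 1.5 SD of the
#' band-passed artefact-free NREM signal for 0.5-3 s with at least one
#' sample above 2.5 SD; events separated by less than 0.5 s are merged when
#' their total supra-threshold time stays below 3 s. Because both
#' thresholds are standard deviations of the signal itself, the detected
#' event set is invariant to global amplitude scaling, and the band-pass
#' makes it invariant to DC offsets. An interval meeting both the slow and
#' the fast criterion is retained in both lists.
#'
#' @param rec an [eeg_recording()].
#' @param hyp a [hypnogram()].
#' @param peaks a `spindle_peaks` from [estimate_spindle_peaks()] (possibly
#'   frozen from a reference session).
#' @param config a [session_config()].
#' @param channels channels to process (default all).
#' @param sd_ref optional named list per channel of `c(slow=, fast=)` SD
#'   references frozen from another session.
#' @return data frame of events with columns `channel`, `type`, `start_s`,
#'   `end_s`, `length_s`, `p2p_amp_uv`, `mean_rms_uv`, `merged_from`; the
#'   SD references used are attached as attribute `sd_ref`.
#' @export
detect_spindles <- function(rec, hyp, peaks, config = session_config(),
                            channels = rec$channel_labels, sd_ref = NULL) {
  fs <- rec$sampling_rate_hz
  efs <- config$erp_fs_hz
  used_sd <- list()
  out <- list()
  for (ch in channels) {
    y <- erp_downsample(get_channel(rec, ch), fs, config)
    mask <- stage_mask(length(y), efs, hyp, c("N2", "N3"))
    for (type in c("slow", "fast")) {
      centre <- if (type == "slow") peaks$slow_peak_hz else peaks$fast_peak_hz
      ref <- if (!is.null(sd_ref)) sd_ref[[ch]][[type]] else NULL
      res <- detect_spindles_one(y, efs, centre, config, mask, ref)
      used_sd[[ch]][[type]] <- res$sd_ref
      if (is.null(res$events)) next
      ev <- res$events
      out[[length(out) + 1]] <- data.frame(
        channel = ch, type = type,
        start_s = (ev$start_i - 1) / efs,
        end_s = ev$end_i / efs,
        length_s = (ev$end_i - ev$start_i + 1) / efs,
        p2p_amp_uv = ev$p2p,
        mean_rms_uv = ev$mean_rms,
        merged_from = ev$merged_from)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    channel = character(), type = character(), start_s = numeric(),
    end_s = numeric(), length_s = numeric(), p2p_amp_uv = numeric(),
    mean_rms_uv = numeric(), merged_from = integer())
  res <- res[order(res$channel, res$type, res$start_s), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "sd_ref") <- used_sd
  res
}

#' Summarise detected spindles
#'
#' Count, density per 30 s of artefact-free NREM, mean peak-to-peak
#' amplitude, mean length and mean RMS, per channel and type. Means of an
#' empty event set are reported as NA.
#'
#' @param events data frame from [detect_spindles()].
#' @param hyp the [hypnogram()] used for detection.
#' @param config a [session_config()].
#' @return data frame with one row per channel and type.
#' @export
summarize_spindles <- function(events, hyp, config = session_config()) {
  n_nrem <- sum(hyp$stages %in% c("N2", "N3") & !hyp$artefact)
  nrem_units <- n_nrem * hyp$epoch_length_s / config$density_epoch_s
  if (!nrow(events)) {
    return(data.frame(channel = NA_character_, type = NA_character_,
                      count = 0L, density = 0, mean_p2p_amp_uv = NA_real_,
                      mean_length_s = NA_real_, mean_rms_uv = NA_real_))
  }
  parts <- split(events, interaction(events$channel, events$type, drop = TRUE))
  out <- lapply(parts, function(e) data.frame(
    channel = e$channel[1], type = e$type[1],
    count = nrow(e),
    density = nrow(e) / nrem_units,
    mean_p2p_amp_uv = mean(e$p2p_amp_uv),
    mean_length_s = mean(e$length_s),
    mean_rms_uv = mean(e$mean_rms_uv)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
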
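# Offline slow-oscillation detection: zero-crossing negative half-waves of
# 0.75-2 s in the 0.5-3.5 Hz band, thresholded at 1.25 times the mean
# trough and mean trough-to-peak amplitudes over all candidates.

# zero-phase 0.5-3.5 Hz band-pass as a cascade of Butterworth sections; the
# high-pass section is first order (second order effective after the
# forward-backward pass) so that second-long half-waves keep their
# zero-crossing geometry
so_bandpass <- function(x, fs, band) {
  hp <- signal::butter(1, band[1] / (fs / 2), "high")
  lp <- signal::butter(4, band[2] / (fs / 2), "low")
  as.numeric(signal::filtfilt(lp, signal::filtfilt(hp, x)))
}

# candidate half-wave geometry on one filtered channel: negative half-wave
# between a negative-going and the next positive-going zero-crossing, the
# following positive half-wave up to the next negative-going crossing
so_candidates <- function(xf, fs, halfwave_bounds) {
  sgn <- xf >= 0
  down <- which(sgn[-length(sgn)] & !sgn[-1])       # + -> - at i+1
  up <- which(!sgn[-length(sgn)] & sgn[-1])         # - -> + at i+1
  rows <- list()
  for (d in down) {
    u <- up[up > d][1]
    if (is.na(u)) break
    neg_dur <- (u - d) / fs
    if (neg_dur < halfwave_bounds[1] || neg_dur > halfwave_bounds[2]) next
    d2 <- down[down > u][1]
    if (is.na(d2)) break
    neg_seg <- (d + 1):u
    pos_seg <- (u + 1):d2
    it <- neg_seg[which.min(xf[neg_seg])]
    ip <- pos_seg[which.max(xf[pos_seg])]
    rows[[length(rows) + 1]] <- data.frame(
      start_i = d + 1L, cross_i = u, end_i = d2,
      trough_i = it, trough_amp = xf[it],
      pos_i = ip, pos_amp = xf[ip],
      neg_dur = neg_dur, pos_dur = (d2 - u) / fs)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(start_i = integer(), cross_i = integer(), end_i = integer(),
                  trough_i = integer(), trough_amp = numeric(),
                  pos_i = integer(), pos_amp = numeric(),
                  neg_dur = numeric(), pos_dur = numeric())
}

#' Detect slow oscillations offline
#'
#' From the zero-phase 0.5-3.5 Hz band-passed signal of each channel,
#' candidate events are negative half-waves (intervals between a
#' negative-going and the subsequent positive-going zero-crossing) lasting
#' 0.75-2 s, followed by the positive half-wave up to the next
#' negative-going crossing. Per channel, the negative threshold is 1.25
#' times the mean trough amplitude over all candidates and the
#' peak-to-peak threshold 1.25 times the mean trough-to-peak amplitude; an
#' SO is a candidate surpassing both. Detection is restricted to
#' artefact-free N2/N3 epochs; events overlapping an excluded epoch are
#' discarded entirely.
#'
#' @param rec an [eeg_recording()].
#' @param hyp a [hypnogram()] aligned to the recording.
#' @param config a [session_config()].
#' @param channels channels to process (default all).
#' @param thresholds optional named list per channel of
#'   `c(neg = , p2p = )` threshold values to reuse (e.g., frozen from a
#'   reference session via [so_thresholds()]).
#' @return data frame of SO events sorted by trough time, with columns
#'   `channel`, `start_s`, `end_s`, `trough_time_s`, `trough_amp_uv`,
#'   `pos_peak_time_s`, `pos_peak_amp_uv`, `neg_halfwave_s`,
#'   `pos_halfwave_s`, `length_s`, `p2p_amp_uv`, `slope_uv_per_s`, and the
#'   thresholds used as attributes.
#' @export
detect_sos <- function(rec, hyp, config = session_config(),
                       channels = rec$channel_labels, thresholds = NULL) {
  fs <- rec$sampling_rate_hz
  mask <- stage_mask(n_samples(rec), fs, hyp, c("N2", "N3"))
  if (!any(mask)) {
    warning("no artefact-free NREM epochs; returning no events")
    return(so_empty())
  }
  used_thr <- list()
  out <- lapply(channels, function(ch) {
    xf <- so_bandpass(get_channel(rec, ch), fs, config$offline_so_band_hz)
    cand <- so_candidates(xf, fs, config$halfwave_bounds_s)
    if (nrow(cand)) {
      inside <- mask[cand$start_i] & mask[cand$end_i] &
        vapply(seq_len(nrow(cand)),
               function(i) all(mask[cand$start_i[i]:cand$end_i[i]]),
               logical(1))
      cand <- cand[inside, , drop = FALSE]
    }
    if (!nrow(cand)) return(so_empty())
    if (!is.null(thresholds) && !is.null(thresholds[[ch]])) {
      thr_neg <- thresholds[[ch]]["neg"]
      thr_p2p <- thresholds[[ch]]["p2p"]
    } else {
      thr_neg <- config$so_threshold_factor * mean(cand$trough_amp)
      thr_p2p <- config$so_threshold_factor *
        mean(cand$pos_amp - cand$trough_amp)
    }
    used_thr[[ch]] <<- c(neg = unname(thr_neg), p2p = unname(thr_p2p))
    sel <- cand$trough_amp <= thr_neg &
      (cand$pos_amp - cand$trough_amp) >= thr_p2p
    ev <- cand[sel, , drop = FALSE]
    if (!nrow(ev)) return(so_empty())
    data.frame(
      channel = ch,
      start_s = (ev$start_i - 1) / fs,
      end_s = ev$end_i / fs,
      trough_time_s = (ev$trough_i - 1) / fs,
      trough_amp_uv = ev$trough_amp,
      pos_peak_time_s = (ev$pos_i - 1) / fs,
      pos_peak_amp_uv = ev$pos_amp,
      neg_halfwave_s = ev$neg_dur,
      pos_halfwave_s = ev$pos_dur,
      length_s = ev$neg_dur + ev$pos_dur,
      p2p_amp_uv = ev$pos_amp - ev$trough_amp,
      slope_uv_per_s = (ev$pos_amp - ev$trough_amp) /
        ((ev$pos_i - ev$trough_i) / fs))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$trough_time_s), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "thresholds") <- used_thr
  res
}

so_empty <- function() {
  data.frame(channel = character(), start_s = numeric(), end_s = numeric(),
             trough_time_s = numeric(), trough_amp_uv = numeric(),
             pos_peak_time_s = numeric(), pos_peak_amp_uv = numeric(),
             neg_halfwave_s = numeric(), pos_halfwave_s = numeric(),
             length_s = numeric(), p2p_amp_uv = numeric(),
             slope_uv_per_s = numeric())
}

#' Per-channel SO detection thresholds of a session
#'
#' Computes the relative amplitude thresholds (1.25 times the mean trough
#' and mean trough-to-peak candidate amplitudes) for each channel without
#' applying them, so that a second session can be detected with thresholds
#' frozen from a reference session.
#'
#' @inheritParams detect_sos
#' @return named list per channel of `c(neg, p2p)` in uV.
#' @export
so_thresholds <- function(rec, hyp, config = session_config(),
                          channels = rec$channel_labels) {
  fs <- rec$sampling_rate_hz
  mask <- stage_mask(n_samples(rec), fs, hyp, c("N2", "N3"))
  out <- lapply(channels, function(ch) {
    xf <- so_bandpass(get_channel(rec, ch), fs, config$offline_so_band_hz)
    cand <- so_candidates(xf, fs, config$halfwave_bounds_s)
    if (nrow(cand)) {
      inside <- vapply(seq_len(nrow(cand)),
                       function(i) all(mask[cand$start_i[i]:cand$end_i[i]]),
                       logical(1))
      cand <- cand[inside, , drop = FALSE]
    }
    if (!nrow(cand)) return(c(neg = NA_real_, p2p = NA_real_))
    c(neg = config$so_threshold_factor * mean(cand$trough_amp),
      p2p = config$so_threshold_factor * mean(cand$pos_amp - cand$trough_amp))
  })
  names(out) <- channels
  out
}

#' Summarise detected SO events
#'
#' Per-channel counts, density per 30 s of artefact-free NREM, and mean
#' amplitudes, lengths, half-wave durations, slope, and the
#' positive-to-negative half-wave length ratio.
#'
#' @param events data frame from [detect_sos()].
#' @param hyp the [hypnogram()] used for detection.
#' @param config a [session_config()].
#' @return data frame with one row per channel.
#' @export
summarize_sos <- function(events, hyp, config = session_config()) {
  n_nrem <- sum(hyp$stages %in% c("N2", "N3") & !hyp$artefact)
  nrem_units <- n_nrem * hyp$epoch_length_s / config$density_epoch_s
  if (!nrow(events)) {
    return(data.frame(channel = NA_character_, count = 0L, density = 0,
                      mean_trough_amp_uv = NA_real_,
                      mean_pos_peak_amp_uv = NA_real_,
                      mean_p2p_amp_uv = NA_real_, mean_length_s = NA_real_,
                      mean_slope_uv_per_s = NA_real_,
                      mean_neg_halfwave_s = NA_real_,
                      mean_pos_halfwave_s = NA_real_,
                      pos_neg_ratio = NA_real_))
  }
  parts <- split(events, events$channel)
  out <- lapply(names(parts), function(ch) {
    e <- parts[[ch]]
    data.frame(
      channel = ch,
      count = nrow(e),
      density = nrow(e) / nrem_units,
      mean_trough_amp_uv = mean(e$trough_amp_uv),
      mean_pos_peak_amp_uv = mean(e$pos_peak_amp_uv),
      mean_p2p_amp_uv = mean(e$p2p_amp_uv),
      mean_length_s = mean(e$length_s),
      mean_slope_uv_per_s = mean(e$slope_uv_per_s),
      mean_neg_halfwave_s = mean(e$neg_halfwave_s),
      mean_pos_halfwave_s = mean(e$pos_halfwave_s),
      pos_neg_ratio = mean(e$pos_halfwave_s) / mean(e$neg_halfwave_s))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Grand average waveform time-locked to SO troughs
#'
#' Extracts windows around each event's negative half-wave peak and returns
#' the pointwise mean and SEM; events closer than the window to a recording
#' edge are dropped and counted.
#'
#' @param rec an [eeg_recording()].
#' @param events data frame from [detect_sos()] (one channel).
#' @param window_s half-window in seconds (traces span +/- `window_s`).
#' @param channel channel to average (default: the events' channel).
#' @return list with `time_s`, `mean`, `sem`, `n_events`, `n_dropped`.
#' @export
grand_average_so <- function(rec, events, window_s = 1.5, channel = NULL) {
  if (!nrow(events)) stop("no events to average")
  if (is.null(channel)) channel <- events$channel[1]
  ev <- events[events$channel == channel, , drop = FALSE]
  fs <- rec$sampling_rate_hz
  x <- get_channel(rec, channel)
  half <- round(window_s * fs)
  rel <- -half:half
  rows <- list(); dropped <- 0L
  for (tt in ev$trough_time_s) {
    i0 <- round(tt * fs) + 1L
    idx <- i0 + rel
    if (idx[1] < 1 || idx[length(idx)] > length(x)) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1]] <- x[idx]
  }
  if (!length(rows)) stop("all events fall within ", window_s,
                          " s of a recording edge")
  m <- do.call(rbind, rows)
  list(time_s = rel / fs,
       mean = colMeans(m),
       sem = if (nrow(m) > 1) apply(m, 2, stats::sd) / sqrt(nrow(m))
             else rep(0, ncol(m)),
       n_events = nrow(m),
       n_dropped = dropped)
}
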
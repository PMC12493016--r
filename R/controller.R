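# Deterministic replay implementation of the online SO detector and
# paired-burst scheduler: causal 200-Hz streams, adaptive negativity
# threshold (floor -80 uV), delta/theta NREM gate, individualized delay,
# fixed 1075-ms interburst interval and >= 2.5-s refractory pause, with
# stimulation restricted to stable N3 inside the first 4 h.

#' Prepare the controller's causal 200-Hz streams
#'
#' Derives the two monitoring streams of the online detector from the raw
#' recording: an SO stream band-limited to 0.25-4 Hz and a broadband stream
#' (0.25-45 Hz) used for the delta/theta ratio, both at 200 Hz. All filters
#' are causal (online-realisable IIR cascades); zero-phase filtering is
#' reserved for the offline detectors. Rate conversion picks, for every
#' 200-Hz tick, the most recent input sample after causal anti-alias
#' filtering, so no output sample depends on future input.
#'
#' @param rec an [eeg_recording()] containing the monitoring channel.
#' @param config a [session_config()].
#' @return list with `so` and `broadband` numeric streams and `fs_hz`.
#' @export
prepare_streams <- function(rec, config = session_config()) {
  ch <- config$monitor_channel
  if (!ch %in% rec$channel_labels)
    stop("monitoring channel missing from recording: ", ch)
  x <- get_channel(rec, ch)
  fs_in <- rec$sampling_rate_hz
  fs <- config$online_fs_hz
  if (fs_in < fs) stop("recording sampling rate below the online rate")
  if (fs_in > fs) {
    aa <- signal::butter(4, min(0.95, 0.45 * fs / (fs_in / 2)), "low")
    x <- as.numeric(signal::filter(aa, x))
    n_out <- floor(length(x) * fs / fs_in)
    pick <- floor((seq_len(n_out) - 1) * fs_in / fs) + 1
    x <- x[pick]
  }
  # first-order high-pass: at SO timescales a steeper causal DC block
  # attenuates second-long transients severely and advances their trough
  causal_band <- function(x, lo, hi, lp_order) {
    hp <- signal::butter(1, lo / (fs / 2), "high")
    lp <- signal::butter(lp_order, min(0.99, hi / (fs / 2)), "low")
    as.numeric(signal::filter(lp, as.numeric(signal::filter(hp, x))))
  }
  list(so = causal_band(x, config$so_band_hz[1], config$so_band_hz[2], 3),
       broadband = causal_band(x, config$broadband_hz[1],
                               config$broadband_hz[2], 4),
       fs_hz = fs)
}

#' Adaptive negativity threshold update
#'
#' Returns the detection threshold given the trough amplitudes seen in the
#' trailing history window (5 s by default). The rule tracks deepening slow
#' oscillations but never loosens above the initial -80 uV floor:
#' with an empty history the initial threshold is returned, otherwise
#' `min(init, mean(troughs))` (both negative, so `min` is the stricter of
#' the two).
#'
#' @param trough_history_uv numeric vector of negative trough amplitudes
#'   (uV) observed in the preceding `threshold_history_s`.
#' @param config a [session_config()].
#' @return threshold in uV (<= `init_threshold_uv`).
#' @export
update_threshold <- function(trough_history_uv, config = session_config()) {
  troughs <- trough_history_uv[trough_history_uv < 0]
  if (!length(troughs)) return(config$init_threshold_uv)
  min(config$init_threshold_uv, mean(troughs))
}

#' Delta/theta power ratio of a broadband window
#'
#' Welch band power in the online delta band (0.5-4 Hz) over the online
#' theta band (4-8 Hz), the controller's proxy for NREM depth. An all-zero
#' window returns the neutral value 1 with a message.
#'
#' @param broadband_window numeric window of the broadband stream
#'   (`threshold_history_s` long during replay).
#' @param config a [session_config()].
#' @param fs_hz sampling rate of the window.
#' @return strictly positive ratio.
#' @export
delta_theta_ratio <- function(broadband_window, config = session_config(),
                              fs_hz = config$online_fs_hz) {
  if (!length(broadband_window) || all(broadband_window == 0)) {
    message("all-zero broadband window; delta/theta ratio set to 1")
    return(1)
  }
  nfft <- min(512, length(broadband_window))
  ps <- welch_psd(broadband_window, fs_hz, nfft = nfft, overlap = 0.5)
  df <- ps$freqs_hz[2] - ps$freqs_hz[1]
  bp <- function(rng) sum(ps$psd[ps$freqs_hz >= rng[1] &
                                 ps$freqs_hz < rng[2]]) * df
  pd <- bp(config$online_delta_hz)
  pt <- bp(config$online_theta_hz)
  if (pt <= 0) return(if (pd > 0) 1e6 else 1)
  max(pd / pt, .Machine$double.eps)
}

#' Select the individual delta/theta gate threshold
#'
#' Automated proxy for the visual histogram rule used to individualise the
#' NREM gate: over unit-width histogram bin edges `t`, maximise
#' `J(t) = P(ratio >= t | NREM) - P(ratio >= t | Wake or REM)` and return
#' the smallest maximising edge. With identical class distributions `J` is
#' flat at zero and the smallest edge is returned with a degeneracy warning.
#'
#' @param epoch_ratios delta/theta ratio per 30-s epoch.
#' @param stages stage label per epoch (same length).
#' @return ratio threshold (numeric scalar).
#' @export
select_dt_threshold <- function(epoch_ratios, stages) {
  if (length(epoch_ratios) != length(stages))
    stop("epoch_ratios and stages must have equal length")
  nrem <- epoch_ratios[stages %in% c("N1", "N2", "N3")]
  other <- epoch_ratios[stages %in% c("Wake", "REM")]
  if (!length(nrem) || !length(other))
    stop("need at least one NREM and one Wake/REM epoch")
  edges <- 0:ceiling(max(epoch_ratios))
  J <- vapply(edges, function(t) mean(nrem >= t) - mean(other >= t),
              numeric(1))
  if (max(J) <= 0) {
    warning("degenerate ratio distributions: no separating threshold")
    return(edges[1])
  }
  edges[which.max(J)]   # which.max returns the first (smallest) maximiser
}

#' Individualised SO delay
#'
#' Mean interval from the SO negative peak to the subsequent positive peak
#' over offline-detected events of an adaptation recording; used as the
#' burst-1 delay after online detection.
#'
#' @param so_events data frame of SO events with `trough_time_s` and
#'   `pos_peak_time_s` columns (as returned by [detect_sos()]).
#' @return delay in milliseconds.
#' @export
individual_delay <- function(so_events) {
  if (is.null(so_events) || !nrow(so_events))
    stop("need at least one SO event to compute the individual delay")
  mean(so_events$pos_peak_time_s - so_events$trough_time_s) * 1000
}

# epoch-level stimulation gate: stability of N3 (4 min for the first bout,
# 2 min for later bouts); epochs lighter than N2 (or artefact) disable
# stimulation until stability re-accrues
gate_epochs <- function(hyp, config) {
  ep_per_min <- 60 / hyp$epoch_length_s
  need_first <- ceiling(config$n3_stable_first_min * ep_per_min)
  need_later <- ceiling(config$n3_stable_later_min * ep_per_min)
  n <- length(hyp$stages)
  enabled <- logical(n)
  run <- 0L; bout <- 0L; in_bout <- FALSE; on <- FALSE
  for (e in seq_len(n)) {
    st <- hyp$stages[e]; art <- hyp$artefact[e]
    if (st == "N3" && !art) {
      if (!in_bout) { bout <- bout + 1L; in_bout <- TRUE; run <- 0L }
      run <- run + 1L
      need <- if (bout == 1L) need_first else need_later
      if (run >= need) on <- TRUE
    } else if (st == "N2" && !art) {
      in_bout <- FALSE; run <- 0L        # N3 run broken; gate keeps state
    } else {
      in_bout <- FALSE; run <- 0L; on <- FALSE
    }
    enabled[e] <- on && st %in% c("N2", "N3") && !art
  }
  enabled
}

# causal trough recognition with amplitude hysteresis: a running minimum
# becomes a recognized trough at the first sample where the stream has
# risen h above it without first dipping lower
recognize_troughs <- function(x, h) {
  n <- length(x)
  if (n < 3) return(list(trough = integer(0), recog = integer(0)))
  core <- 2:(n - 1)
  mins <- which(c(FALSE, x[core] < x[core - 1] & x[core] <= x[core + 1],
                  FALSE))
  if (!length(mins)) return(list(trough = integer(0), recog = integer(0)))
  troughs <- integer(0); recogs <- integer(0)
  cand <- mins[1]
  for (m in c(mins[-1], n)) {
    seg <- (cand + 1):m
    r <- seg[x[seg] >= x[cand] + h][1]
    if (!is.na(r)) {
      troughs <- c(troughs, cand)
      recogs <- c(recogs, r)
      cand <- m
    } else if (x[m] < x[cand]) {
      cand <- m
    }
  }
  list(trough = troughs, recog = recogs)
}

#' Run the closed-loop controller in replay
#'
#' Streams the monitoring channel through the causal 200-Hz filters and
#' applies the online protocol: every 0.5 s the negativity threshold is
#' updated from the troughs of the preceding 5 s (never laxer than
#' -80 uV) and the delta/theta ratio recomputed over the same history; when
#' the SO stream reaches a negative half-wave peak at or below the
#' threshold while the ratio gate passes and stimulation is enabled (stable
#' N3 accrued, inside the 4-h window), burst 1 is scheduled at the SO
#' negative peak plus the individualised delay (targeting the approaching
#' up-state) and burst 2 a fixed 1075 ms later, followed by a refractory
#' pause of at least 2.5 s before the detector re-arms. Deterministic given
#' its inputs.
#'
#' @param rec an [eeg_recording()] with the monitoring channel.
#' @param hyp a [hypnogram()] aligned to the recording.
#' @param config a [session_config()] with `delay_ms` and
#'   `dt_ratio_threshold` set.
#' @return data frame of trigger events: `time_s`, `burst_index`,
#'   `detection_time_s`, `threshold_uv`, `dt_ratio` (two rows per pair).
#' @export
run_controller <- function(rec, hyp, config = session_config()) {
  if (is.na(config$delay_ms))
    stop("config$delay_ms must be set (see individual_delay())")
  if (is.na(config$dt_ratio_threshold))
    stop("config$dt_ratio_threshold must be set (see select_dt_threshold())")
  streams <- prepare_streams(rec, config)
  so <- streams$so; bb <- streams$broadband; fs <- streams$fs_hz
  n <- length(so)
  block <- round(config$threshold_update_s * fs)
  hist_n <- round(config$threshold_history_s * fs)
  delay_n <- round(config$delay_ms / 1000 * fs)
  inter_n <- round(config$interburst_ms / 1000 * fs)
  refr_n <- round(config$refractory_s * fs)

  # sample-level stimulation gate
  en_ep <- gate_epochs(hyp, config)
  spe <- hyp$epoch_length_s * fs
  ep_idx <- pmin(length(en_ep), floor((seq_len(n) - 1) / spe) + 1)
  enabled <- en_ep[ep_idx] & (seq_len(n) - 1) / fs < config$stim_window_h * 3600

  # negative troughs of the SO stream with amplitude hysteresis: a trough
  # is recognized causally once the stream has risen trough_hysteresis_uv
  # above its running minimum, so noise ripples on a descending half-wave
  # are not mistaken for the negative peak. The adaptive threshold is
  # driven by *detected* troughs (those at or below the prevailing
  # threshold), so background minima never loosen it and deepening SOs
  # tighten it below the -80 uV floor.
  tr <- recognize_troughs(so, config$trough_hysteresis_uv)
  min_idx <- tr$trough; min_rec <- tr$recog; min_amp <- so[tr$trough]

  det_amp <- numeric(0)
  det_pos <- integer(0)     # sample positions of detected troughs
  out <- list()
  refract_until <- 0L
  starts <- seq(1, n, by = block)
  for (s0 in starts) {
    s1 <- min(s0 + block - 1L, n)
    # threshold from detected troughs in the trailing history
    keep <- det_pos >= s0 - hist_n
    det_amp <- det_amp[keep]; det_pos <- det_pos[keep]
    thr <- update_threshold(det_amp, config)
    # register troughs recognized in this block for future updates
    blk <- min_rec >= s0 & min_rec <= s1
    hit <- blk & min_amp <= thr
    if (any(hit)) {
      det_pos <- c(det_pos, min_idx[hit])
      det_amp <- c(det_amp, min_amp[hit])
    }
    # stimulation logic
    if (s1 <= refract_until) next
    if (!any(enabled[s0:s1])) next
    w0 <- max(1L, s0 - hist_n)
    if (s0 - w0 < fs) next                       # not enough history yet
    ratio <- delta_theta_ratio(bb[w0:(s0 - 1L)], config, fs)
    if (ratio < config$dt_ratio_threshold) next
    lo <- max(s0, refract_until + 1L, 2L)
    if (lo > s1) next
    # detection anchors at the negative half-wave peak: the first trough at
    # or below threshold whose recognition falls in this armed span
    ok <- min_rec >= lo & min_rec <= s1 & min_amp <= thr &
      enabled[min_idx] & min_idx > refract_until
    if (!any(ok)) next
    k <- which(ok)[1]
    i_tr <- min_idx[k]
    b1 <- max(i_tr + delay_n, min_rec[k] + 1L)
    b2 <- b1 + inter_n
    if (b2 > n || !enabled[b1] || !enabled[b2]) next
    out[[length(out) + 1]] <- data.frame(
      time_s = c((b1 - 1) / fs, (b2 - 1) / fs),
      burst_index = c(1L, 2L),
      detection_time_s = (i_tr - 1) / fs,
      threshold_uv = thr,
      dt_ratio = ratio)
    refract_until <- b2 + refr_n
  }
  if (!length(out))
    return(data.frame(time_s = numeric(), burst_index = integer(),
                      detection_time_s = numeric(), threshold_uv = numeric(),
                      dt_ratio = numeric()))
  do.call(rbind, out)
}
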
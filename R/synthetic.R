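# Synthetic polysomnography with known ground truth. The generator emulates
# the minimal structure the detectors assume: stage-scaled 1/f background
# with extra delta colouring in deep NREM and theta in REM/Wake, discrete
# SO waveforms (negative then positive half-sine), spindle bursts under a
# raised-cosine envelope optionally coupled to SO up-states, and K-complex-
# like damped biphasic evoked responses to acoustic triggers.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  force(code)
}

# derive independent stream seeds so adding one event family does not
# perturb another's placement
sub_seed <- function(seed, k) {
  (as.double(seed) * 48271 + k * 2654435761) %% 2147483647
}

#' Pink (1/f) noise
#'
#' Zero-mean Gaussian noise whose power spectral density falls as 1/f,
#' generated by spectral shaping; used both as the EEG background model and
#' as the acoustic burst carrier.
#'
#' @param duration_s signal duration in seconds (>= 0).
#' @param fs_hz sampling rate in Hz (> 0).
#' @param scale_uv target standard deviation in uV.
#' @param seed integer seed; the same seed yields the identical signal.
#' @return numeric vector of `round(duration_s * fs_hz)` samples.
#' @export
make_pink_noise <- function(duration_s, fs_hz, scale_uv = 1, seed = 1) {
  if (fs_hz <= 0) stop("fs_hz must be positive")
  if (duration_s < 0) stop("duration_s must be >= 0")
  n <- round(duration_s * fs_hz)
  if (n == 0) return(numeric(0))
  with_seed(seed, {
    spec <- stats::fft(stats::rnorm(n))
    k <- seq_len(n) - 1
    f <- pmin(k, n - k) * fs_hz / n   # symmetric frequency axis
    shape <- ifelse(f > 0, 1 / sqrt(f), 0)
    x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
    x <- x - mean(x)
    s <- stats::sd(x)
    if (s > 0) x <- x * (scale_uv / s)
    x
  })
}

#' Slow-oscillation waveform
#'
#' One negative half-sine (the surface-negative down-state) followed by one
#' positive half-sine (the up-state); zero at both ends and continuous at
#' the junction. This parameterisation exposes exactly the half-wave
#' durations and amplitudes the detectors threshold on.
#'
#' @param trough_amp_uv negative trough amplitude in uV (< 0).
#' @param neg_dur_s negative half-wave duration in seconds (> 0).
#' @param pos_amp_uv positive peak amplitude in uV (>= 0; 0 gives a
#'   monophasic negative half-wave).
#' @param pos_dur_s positive half-wave duration in seconds (> 0).
#' @param fs_hz sampling rate in Hz.
#' @return numeric waveform of `round((neg_dur_s + pos_dur_s) * fs_hz)`
#'   samples.
#' @export
make_so_waveform <- function(trough_amp_uv, neg_dur_s, pos_amp_uv, pos_dur_s,
                             fs_hz) {
  vals <- c(trough_amp_uv, neg_dur_s, pos_amp_uv, pos_dur_s, fs_hz)
  if (any(!is.finite(vals))) stop("all waveform parameters must be finite")
  if (trough_amp_uv >= 0) stop("trough_amp_uv must be negative")
  if (neg_dur_s <= 0 || pos_dur_s <= 0) stop("durations must be positive")
  if (pos_amp_uv < 0) stop("pos_amp_uv must be >= 0")
  n_neg <- round(neg_dur_s * fs_hz)
  n_pos <- round(pos_dur_s * fs_hz)
  t_neg <- seq_len(n_neg) - 0.5
  t_pos <- seq_len(n_pos) - 0.5
  c(trough_amp_uv * sin(pi * t_neg / n_neg),
    pos_amp_uv * sin(pi * t_pos / n_pos))
}

#' Spindle waveform
#'
#' Sinusoid at `freq_hz` under a raised-cosine (Hann) envelope whose peak is
#' `amp_uv`, emulating the waxing-waning morphology of sleep spindles.
#'
#' @param freq_hz carrier frequency in Hz (> 0).
#' @param dur_s duration in seconds (> 0).
#' @param amp_uv peak envelope amplitude in uV.
#' @param fs_hz sampling rate in Hz.
#' @return numeric waveform of `round(dur_s * fs_hz)` samples.
#' @export
make_spindle_waveform <- function(freq_hz, dur_s, amp_uv, fs_hz) {
  if (dur_s <= 0) stop("dur_s must be positive")
  if (freq_hz <= 0) stop("freq_hz must be positive")
  n <- round(dur_s * fs_hz)
  t <- (seq_len(n) - 0.5) / fs_hz
  env <- 0.5 * (1 - cos(2 * pi * t / dur_s))
  amp_uv * env * sin(2 * pi * freq_hz * t)
}

#' Acoustic stimulus burst
#'
#' Pink-noise burst of `burst_ms` total duration with linear rise and fall
#' ramps of `ramp_ms`, the stimulus waveform the controller schedules in
#' pairs.
#'
#' @param config a [session_config()] (uses `burst_ms` and `ramp_ms`).
#' @param fs_hz audio sampling rate in Hz.
#' @param seed carrier noise seed.
#' @return numeric vector of unit peak scale.
#' @export
make_stimulus_burst <- function(config = session_config(), fs_hz = 44100,
                                seed = 1) {
  n <- round(config$burst_ms / 1000 * fs_hz)
  x <- make_pink_noise(config$burst_ms / 1000, fs_hz, scale_uv = 1,
                       seed = seed)
  n_ramp <- round(config$ramp_ms / 1000 * fs_hz)
  env <- rep(1, n)
  if (n_ramp > 0) {
    env[seq_len(n_ramp)] <- seq(0, 1, length.out = n_ramp)
    env[(n - n_ramp + 1):n] <- seq(1, 0, length.out = n_ramp)
  }
  x * env
}

#' Damped biphasic evoked-response template
#'
#' K-complex-like response to an acoustic stimulus: an exponentially damped
#' slow sinusoid beginning with a surface-negative deflection.
#'
#' @param amp_uv initial (negative-phase) amplitude in uV.
#' @param freq_hz oscillation frequency in Hz.
#' @param decay_s exponential decay time constant in seconds.
#' @param latency_s onset latency after the trigger in seconds.
#' @param dur_s template duration in seconds.
#' @return list describing the template (class `evoked_template`).
#' @export
evoked_template <- function(amp_uv = -60, freq_hz = 0.75, decay_s = 0.8,
                            latency_s = 0.5, dur_s = 2) {
  structure(list(amp_uv = amp_uv, freq_hz = freq_hz, decay_s = decay_s,
                 latency_s = latency_s, dur_s = dur_s),
            class = "evoked_template")
}

#' @rdname evoked_template
#' @param template an `evoked_template`.
#' @param fs_hz sampling rate in Hz.
#' @return `evoked_waveform` returns the sampled template (numeric vector).
#' @export
evoked_waveform <- function(template, fs_hz) {
  n <- round(template$dur_s * fs_hz)
  t <- (seq_len(n) - 0.5) / fs_hz
  template$amp_uv * exp(-t / template$decay_s) *
    sin(2 * pi * template$freq_hz * t)
}

#' Synthetic session generator configuration
#'
#' Defaults give a night-like NREM-dominant session: stage cycles
#' Wake/N1 lead-in then N2-N3-N2-REM; pink-noise background scaled per
#' stage with extra delta colouring in N3 and theta in REM/Wake; discrete
#' SOs at 3 per 30-s epoch in N2/N3 with troughs drawn from -140 to
#' -80 uV and negative half-waves of 0.8-1.3 s; slow and fast spindles at
#' 1 each per NREM epoch near 11 and 13.5 Hz, half of them coupled to an SO
#' up-state.
#'
#' @param duration_s session duration in seconds (>= one 30-s epoch).
#' @param fs_hz sampling rate in Hz (>= 100; default 500).
#' @param channels channel labels to synthesise (identical event content).
#' @param stages optional explicit stage sequence overriding the built-in
#'   cycle plan (one label per 30-s epoch).
#' @param background_scale_uv named per-stage pink-noise SD in uV.
#' @param delta_colour_uv named per-stage SD of an added 0.5-2 Hz component.
#' @param theta_colour_uv named per-stage SD of an added 4-8 Hz component.
#' @param so_rate_per_epoch expected SO count per eligible (N2/N3) epoch.
#' @param so_amp_range_uv trough amplitude range (negative, uV); a list of
#'   ranges gives a mixture, one range drawn per event (e.g., a bimodal
#'   deep/shallow population for detector validation).
#' @param so_neg_dur_range_s,so_pos_dur_range_s half-wave duration ranges.
#' @param so_pos_frac_range positive peak amplitude as a fraction of |trough|.
#' @param spindle_rate_per_epoch expected spindle count per NREM epoch and
#'   type.
#' @param spindle_freq_ranges list with `slow` and `fast` frequency ranges
#'   (Hz) from which carrier frequencies are drawn.
#' @param spindle_amp_uv peak spindle envelope amplitude in uV.
#' @param spindle_dur_range_s spindle duration range in seconds.
#' @param coupling_prob fraction of spindles whose onset is locked to an SO
#'   up-state.
#' @param coupling_offset_s spindle onset offset relative to the SO positive
#'   peak in seconds (0 = onset at the up-state peak).
#' @param evoked template from [evoked_template()] used by
#'   [add_evoked_responses()].
#' @param seed integer master seed; fully determines the session. Streams
#'   are split per event family so adding spindles does not move SOs.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(duration_s = 1800,
                             fs_hz = 500,
                             channels = "Fpz",
                             stages = NULL,
                             background_scale_uv = c(Wake = 12, N1 = 14,
                                                     N2 = 18, N3 = 22,
                                                     REM = 12),
                             delta_colour_uv = c(Wake = 2, N1 = 4, N2 = 10,
                                                 N3 = 28, REM = 2),
                             theta_colour_uv = c(Wake = 8, N1 = 5, N2 = 2,
                                                 N3 = 2, REM = 10),
                             so_rate_per_epoch = 3,
                             so_amp_range_uv = c(-140, -80),
                             so_neg_dur_range_s = c(1.0, 1.4),
                             so_pos_dur_range_s = c(0.8, 1.2),
                             so_pos_frac_range = c(0.4, 0.6),
                             spindle_rate_per_epoch = 1,
                             spindle_freq_ranges = list(slow = c(10.5, 11.5),
                                                        fast = c(13, 14)),
                             spindle_amp_uv = 25,
                             spindle_dur_range_s = c(0.6, 1.4),
                             coupling_prob = 0.5,
                             coupling_offset_s = 0,
                             evoked = evoked_template(),
                             seed = 1) {
  if (fs_hz < 100) stop("fs_hz must be >= 100")
  if (so_rate_per_epoch < 0 || spindle_rate_per_epoch < 0)
    stop("event rates must be >= 0")
  if (any(unlist(so_amp_range_uv) >= 0))
    stop("so_amp_range_uv must be negative")
  cfg <- structure(as.list(environment()), class = "generator_config")
  cfg
}

# deterministic night-like stage plan: lead-in, then repeating
# N2 -> N3 -> N2 -> REM cycles (27 min per cycle at 30-s epochs)
build_stage_plan <- function(n_epochs) {
  lead <- c(rep("Wake", 2), rep("N1", 2))
  cycle <- c(rep("N2", 10), rep("N3", 20), rep("N2", 10), rep("REM", 12))
  plan <- c(lead, rep(cycle, length.out = max(0, n_epochs - length(lead))))
  plan[seq_len(n_epochs)]
}

#' Generate a synthetic polysomnography session
#'
#' Draws (or accepts) a stage plan, synthesises the stage-coloured
#' background, injects SO and spindle events into N2/N3 epochs at the
#' configured rates, and records every injection with exact sample timing in
#' the ground truth. Identical seeds yield identical sessions.
#'
#' @param gen a [generator_config()].
#' @return list with elements `recording` ([eeg_recording()]), `hypnogram`
#'   ([hypnogram()]) and `ground_truth` (list of `so_events`,
#'   `spindle_events`, `evoked_times` data frames and the `stage_plan`).
#' @export
generate_session <- function(gen = generator_config()) {
  stopifnot(inherits(gen, "generator_config"))
  epoch_s <- 30
  if (gen$duration_s < epoch_s)
    stop("duration_s must cover at least one 30-s epoch")
  fs <- gen$fs_hz
  n <- round(gen$duration_s * fs)
  n_epochs <- ceiling(gen$duration_s / epoch_s)
  stages <- if (!is.null(gen$stages)) {
    if (length(gen$stages) != n_epochs)
      stop("stages must supply one label per 30-s epoch (need ", n_epochs, ")")
    as.character(gen$stages)
  } else build_stage_plan(n_epochs)
  hyp <- hypnogram(stages, epoch_s)

  # per-sample stage index for background scaling
  ep_of_sample <- pmin(n_epochs, floor((seq_len(n) - 1) / (epoch_s * fs)) + 1)
  stage_of_sample <- stages[ep_of_sample]

  # --- SO placement (own stream) ---------------------------------------
  so <- with_seed(sub_seed(gen$seed, 1), {
    rows <- list()
    for (e in which(stages %in% c("N2", "N3"))) {
      k <- stats::rpois(1, gen$so_rate_per_epoch)
      if (k == 0) next
      for (i in seq_len(k)) {
        neg_d <- stats::runif(1, gen$so_neg_dur_range_s[1],
                              gen$so_neg_dur_range_s[2])
        pos_d <- stats::runif(1, gen$so_pos_dur_range_s[1],
                              gen$so_pos_dur_range_s[2])
        rng <- gen$so_amp_range_uv
        if (is.list(rng)) rng <- rng[[sample.int(length(rng), 1)]]
        amp <- stats::runif(1, rng[1], rng[2])
        pos_amp <- abs(amp) * stats::runif(1, gen$so_pos_frac_range[1],
                                           gen$so_pos_frac_range[2])
        total <- neg_d + pos_d
        lo <- (e - 1) * epoch_s
        hi <- min(e * epoch_s, gen$duration_s) - total
        if (hi <= lo) next
        start <- stats::runif(1, lo, hi)
        rows[[length(rows) + 1]] <- data.frame(
          channel = "all", start_s = start,
          trough_time_s = start + neg_d / 2,
          trough_amp_uv = amp,
          neg_halfwave_s = neg_d, pos_halfwave_s = pos_d,
          pos_peak_time_s = start + neg_d + pos_d / 2,
          pos_peak_amp_uv = pos_amp)
      }
    }
    if (length(rows)) do.call(rbind, rows) else data.frame(
      channel = character(), start_s = numeric(), trough_time_s = numeric(),
      trough_amp_uv = numeric(), neg_halfwave_s = numeric(),
      pos_halfwave_s = numeric(), pos_peak_time_s = numeric(),
      pos_peak_amp_uv = numeric())
  })

  # --- spindle placement (own stream) ----------------------------------
  sp <- with_seed(sub_seed(gen$seed, 2), {
    rows <- list()
    for (e in which(stages %in% c("N2", "N3"))) {
      for (type in names(gen$spindle_freq_ranges)) {
        k <- stats::rpois(1, gen$spindle_rate_per_epoch)
        if (k == 0) next
        fr <- gen$spindle_freq_ranges[[type]]
        for (i in seq_len(k)) {
          dur <- stats::runif(1, gen$spindle_dur_range_s[1],
                              gen$spindle_dur_range_s[2])
          freq <- stats::runif(1, fr[1], fr[2])
          lo <- (e - 1) * epoch_s
          hi <- min(e * epoch_s, gen$duration_s) - dur
          if (hi <= lo) next
          start <- NA_real_
          # couple a fraction of spindles to an SO up-state in this epoch
          if (stats::runif(1) < gen$coupling_prob && nrow(so)) {
            cand <- so[so$pos_peak_time_s >= lo &
                       so$pos_peak_time_s + dur <= hi + dur, , drop = FALSE]
            if (nrow(cand)) {
              pick <- cand[sample.int(nrow(cand), 1), ]
              start <- pick$pos_peak_time_s + gen$coupling_offset_s
            }
          }
          if (is.na(start)) start <- stats::runif(1, lo, hi)
          if (start < 0 || start + dur > gen$duration_s) next
          rows[[length(rows) + 1]] <- data.frame(
            channel = "all", start_s = start, end_s = start + dur,
            freq_hz = freq, amp_uv = gen$spindle_amp_uv, type = type)
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else data.frame(
      channel = character(), start_s = numeric(), end_s = numeric(),
      freq_hz = numeric(), amp_uv = numeric(), type = character())
  })

  # --- background + injection per channel ------------------------------
  delta_bp <- signal::butter(2, pmin(0.99, c(0.5, 2) / (fs / 2)), "pass")
  theta_bp <- signal::butter(2, pmin(0.99, c(4, 8) / (fs / 2)), "pass")
  data <- vector("list", length(gen$channels))
  names(data) <- gen$channels
  for (ci in seq_along(gen$channels)) {
    s_pink <- sub_seed(gen$seed, 100 + ci)
    s_col <- sub_seed(gen$seed, 200 + ci)
    pink <- make_pink_noise(n / fs, fs, scale_uv = 1, seed = s_pink)
    x <- pink * gen$background_scale_uv[stage_of_sample]
    colour <- with_seed(s_col, stats::rnorm(2 * n))
    d <- as.numeric(signal::filter(delta_bp, colour[seq_len(n)]))
    th <- as.numeric(signal::filter(theta_bp, colour[n + seq_len(n)]))
    d <- d / max(stats::sd(d), 1e-12)
    th <- th / max(stats::sd(th), 1e-12)
    x <- x + d * gen$delta_colour_uv[stage_of_sample] +
      th * gen$theta_colour_uv[stage_of_sample]
    # inject SOs
    if (nrow(so)) for (i in seq_len(nrow(so))) {
      w <- make_so_waveform(so$trough_amp_uv[i], so$neg_halfwave_s[i],
                            so$pos_peak_amp_uv[i], so$pos_halfwave_s[i], fs)
      i0 <- round(so$start_s[i] * fs)
      idx <- i0 + seq_along(w)
      keep <- idx >= 1 & idx <= n
      x[idx[keep]] <- x[idx[keep]] + w[keep]
    }
    # inject spindles
    if (nrow(sp)) for (i in seq_len(nrow(sp))) {
      w <- make_spindle_waveform(sp$freq_hz[i], sp$end_s[i] - sp$start_s[i],
                                 sp$amp_uv[i], fs)
      i0 <- round(sp$start_s[i] * fs)
      idx <- i0 + seq_along(w)
      keep <- idx >= 1 & idx <= n
      x[idx[keep]] <- x[idx[keep]] + w[keep]
    }
    data[[ci]] <- x
  }
  rec <- eeg_recording(data, fs, channel_labels = gen$channels,
                       reference = "synthetic (linked mastoids model)")
  list(recording = rec,
       hypnogram = hyp,
       ground_truth = list(
         so_events = so,
         spindle_events = sp,
         evoked_times = data.frame(time_s = numeric(), template = character()),
         stage_plan = hyp))
}

#' Add evoked responses to a recording
#'
#' Linearly superimposes the damped biphasic template at each trigger time
#' plus the template's fixed latency, on every channel.
#'
#' @param rec an [eeg_recording()].
#' @param trigger_times_s trigger onset times in seconds.
#' @param template an [evoked_template()].
#' @return the recording with responses added.
#' @export
add_evoked_responses <- function(rec, trigger_times_s,
                                 template = evoked_template()) {
  fs <- rec$sampling_rate_hz
  n <- n_samples(rec)
  bad <- which(trigger_times_s < 0 | trigger_times_s > n / fs)
  if (length(bad))
    stop("trigger outside recording at index ", bad[1])
  w <- evoked_waveform(template, fs)
  for (ch in rec$channel_labels) {
    x <- rec$data[[ch]]
    for (tt in trigger_times_s) {
      i0 <- round((tt + template$latency_s) * fs)
      idx <- i0 + seq_along(w)
      keep <- idx >= 1 & idx <= n
      x[idx[keep]] <- x[idx[keep]] + w[keep]
    }
    rec$data[[ch]] <- x
  }
  rec
}
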
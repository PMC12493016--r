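# Shared synthetic fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# quiet NREM session with a bimodal (deep/shallow) SO population for
# detector-recovery checks; `mult` scales all background components
recovery_session <- function(mult = 0.2, seed = 11, duration_s = 600,
                             spindle_rate = 1) {
  memo(sprintf("rec-%g-%d-%d-%g", mult, seed, duration_s, spindle_rate),
       function() {
    gen <- generator_config(
      duration_s = duration_s,
      stages = rep(c("N2", "N3"), each = ceiling(duration_s / 30) / 2),
      so_rate_per_epoch = 3, spindle_rate_per_epoch = spindle_rate,
      so_amp_range_uv = list(c(-180, -150), c(-60, -30), c(-60, -30)),
      background_scale_uv = mult * c(Wake = 12, N1 = 14, N2 = 18, N3 = 22,
                                     REM = 12),
      delta_colour_uv = mult * c(Wake = 2, N1 = 4, N2 = 10, N3 = 28, REM = 2),
      theta_colour_uv = mult * c(Wake = 8, N1 = 5, N2 = 2, N3 = 2, REM = 10),
      seed = seed)
    generate_session(gen)
  })
}

# dense-SO all-N3 session for controller checks
controller_session <- function(seed = 5, duration_s = 600,
                               amp_range = c(-170, -140), rate = 6,
                               bg_mult = 0.3) {
  memo(sprintf("ctl-%d-%d-%g-%g-%g", seed, duration_s, amp_range[1], rate,
               bg_mult),
       function() {
    gen <- generator_config(
      duration_s = duration_s, stages = rep("N3", ceiling(duration_s / 30)),
      so_rate_per_epoch = rate, spindle_rate_per_epoch = 0,
      so_amp_range_uv = amp_range,
      background_scale_uv = bg_mult * c(Wake = 12, N1 = 14, N2 = 18,
                                        N3 = 22, REM = 12),
      delta_colour_uv = bg_mult * c(Wake = 2, N1 = 4, N2 = 10, N3 = 28,
                                    REM = 2),
      theta_colour_uv = bg_mult * c(Wake = 8, N1 = 5, N2 = 2, N3 = 2,
                                    REM = 10),
      seed = seed)
    generate_session(gen)
  })
}

controller_config <- function(...) {
  session_config(delay_ms = 500, dt_ratio_threshold = 4, ...)
}

# add a spindle burst into a signal vector at a given time
inject_burst <- function(x, fs, at_s, dur_s, freq_hz = 13, amp_uv = 30) {
  w <- make_spindle_waveform(freq_hz, dur_s, amp_uv, fs)
  i <- round(at_s * fs)
  x[i:(i + length(w) - 1)] <- x[i:(i + length(w) - 1)] + w
  x
}
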
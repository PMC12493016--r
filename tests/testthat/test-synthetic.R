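test_that("pink noise is seeded, zero-mean and ~1/f over 1-30 Hz", {
  expect_length(make_pink_noise(0, 500), 0)
  expect_error(make_pink_noise(1, -1), "positive")
  expect_identical(make_pink_noise(10, 500, 5, seed = 7),
                   make_pink_noise(10, 500, 5, seed = 7))
  x <- make_pink_noise(600, 500, 10, seed = 2)
  expect_lt(abs(mean(x)), 1e-8)
  ps <- welch_psd(x, 500, 4096, 0.5)
  sel <- ps$freqs_hz >= 1 & ps$freqs_hz <= 30
  slope <- stats::coef(stats::lm(log10(ps$psd[sel]) ~
                                   log10(ps$freqs_hz[sel])))[2]
  expect_gt(slope, -1.3)
  expect_lt(slope, -0.7)
})

test_that("SO waveform is two half-sines with the stated geometry", {
  w <- make_so_waveform(-100, 1.0, 60, 0.8, 500)
  expect_length(w, 1.8 * 500)
  expect_equal(min(w), -100, tolerance = 1e-4)
  expect_equal(max(w), 60, tolerance = 1e-4)
  expect_equal((which.min(w) - 0.5) / 500, 0.5, tolerance = 2 / 500)
  expect_equal((which.max(w) - 0.5) / 500, 1.4, tolerance = 2 / 500)
  # continuity at the junction and zero ends
  expect_lt(abs(w[1]), 1)
  expect_lt(abs(w[length(w)]), 1)
  expect_lt(max(abs(diff(w))), 5)

  mono <- make_so_waveform(-80, 0.75, 0, 0.5, 500)
  expect_lte(max(mono), 0)
  # zero-crossing separation of the negative half-wave = 0.75 s: the
  # negative lobe spans exactly round(0.75 * fs) samples
  neg_run <- rle(mono < -1e-9)
  expect_equal(neg_run$lengths[which(neg_run$values)[1]] / 500, 0.75,
               tolerance = 2 / 500)
  expect_error(make_so_waveform(80, 1, 50, 1, 500), "negative")
  expect_error(make_so_waveform(NaN, 1, 50, 1, 500), "finite")
})

test_that("spindle waveform has the right length, envelope and frequency", {
  expect_length(make_spindle_waveform(13, 0.5, 30, 500), 250)
  expect_equal(make_spindle_waveform(13, 1, 0, 500), numeric(500))
  w <- make_spindle_waveform(13, 1.0, 30, 500)
  expect_equal(max(abs(w)), 30, tolerance = 1)
  spec <- abs(stats::fft(c(w, numeric(4500))))[1:2500]
  f_peak <- (which.max(spec) - 1) * 500 / 5000
  expect_equal(f_peak, 13, tolerance = 0.5)
})

test_that("stimulus burst lasts burst_ms with ramped envelope", {
  cfg <- session_config()
  b <- make_stimulus_burst(cfg, fs_hz = 44100, seed = 1)
  expect_length(b, round(cfg$burst_ms / 1000 * 44100))
  n_ramp <- round(cfg$ramp_ms / 1000 * 44100)
  expect_equal(b[1], 0)
  expect_equal(b[length(b)], 0)
  expect_lt(max(abs(b[1:(n_ramp %/% 4)])),
            max(abs(b)))
})

test_that("session generation is deterministic and honours rates", {
  g <- generator_config(duration_s = 120, seed = 42)
  s1 <- generate_session(g)
  s2 <- generate_session(g)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$hypnogram$stages, s2$hypnogram$stages)
  expect_identical(s1$ground_truth$so_events, s2$ground_truth$so_events)

  s0 <- generate_session(generator_config(duration_s = 120,
                                          so_rate_per_epoch = 0,
                                          spindle_rate_per_epoch = 0,
                                          seed = 1))
  expect_equal(nrow(s0$ground_truth$so_events), 0)
  expect_equal(nrow(s0$ground_truth$spindle_events), 0)
  expect_error(generate_session(generator_config(duration_s = 10)),
               "30-s epoch")
})

test_that("SO placement follows the per-epoch Poisson rule", {
  # 20 N3 epochs at 8 per epoch: count within 3 sigma of 160
  g <- generator_config(duration_s = 600, stages = rep("N3", 20),
                        so_rate_per_epoch = 8, spindle_rate_per_epoch = 0,
                        seed = 77)
  s <- generate_session(g)
  count <- nrow(s$ground_truth$so_events)
  expect_gt(count, 160 - 3 * sqrt(160))
  expect_lt(count, 160 + 3 * sqrt(160))
  # all injected events lie inside the recording, troughs negative
  gt <- s$ground_truth$so_events
  expect_true(all(gt$trough_amp_uv < 0))
  expect_true(all(gt$start_s >= 0))
  expect_true(all(gt$start_s + gt$neg_halfwave_s + gt$pos_halfwave_s <= 600))
})

test_that("events are injected only into N2/N3 epochs", {
  g <- generator_config(duration_s = 600,
                        stages = rep(c("Wake", "N2", "N3", "REM"), each = 5),
                        so_rate_per_epoch = 5, spindle_rate_per_epoch = 2,
                        seed = 3)
  s <- generate_session(g)
  ep_so <- floor(s$ground_truth$so_events$trough_time_s / 30) + 1
  ep_sp <- floor(s$ground_truth$spindle_events$start_s / 30) + 1
  expect_true(all(s$hypnogram$stages[ep_so] %in% c("N2", "N3")))
  expect_true(all(s$hypnogram$stages[ep_sp] %in% c("N2", "N3")))
})

test_that("evoked responses superimpose linearly at fixed latency", {
  rec0 <- eeg_recording(list(Fpz = numeric(5000)), 500)
  tmpl <- evoked_template(amp_uv = -60, latency_s = 0.5)
  zero <- evoked_template(amp_uv = 0)
  expect_equal(add_evoked_responses(rec0, c(1, 5), zero)$data$Fpz,
               rec0$data$Fpz)
  one <- add_evoked_responses(rec0, 2, tmpl)
  w <- evoked_waveform(tmpl, 500)
  i0 <- round(2.5 * 500)
  expect_equal(one$data$Fpz[(i0 + 1):(i0 + length(w))], w)
  expect_equal(sum(one$data$Fpz != 0), sum(w != 0))
  expect_error(add_evoked_responses(rec0, 100, tmpl), "outside recording")
})

test_that("stimulus-locked averaging recovers the evoked template", {
  set.seed(10)
  fs <- 500
  noise <- make_pink_noise(400, fs, 15, seed = 21)
  rec <- eeg_recording(list(Fpz = noise), fs)
  tmpl <- evoked_template(amp_uv = -60, latency_s = 0.5)
  trig <- seq(5, 390, length.out = 50)
  rec <- add_evoked_responses(rec, trig, tmpl)
  w <- evoked_waveform(tmpl, fs)
  avg <- rowMeans(vapply(trig, function(tt) {
    i0 <- round((tt + tmpl$latency_s) * fs)
    rec$data$Fpz[(i0 + 1):(i0 + length(w))]
  }, numeric(length(w))))
  expect_gte(stats::cor(avg, w), 0.9)
})

test_that("stage-conditional slow-wave power ordering holds", {
  g <- generator_config(duration_s = 900,
                        stages = rep(c("N3", "N2", "REM"), each = 10),
                        seed = 15)
  s <- generate_session(g)
  cfg <- session_config()
  swa <- vapply(c("N3", "N2", "REM"), function(st) {
    sp <- power_spectrum(s$recording, s$hypnogram, cfg, stages = st)$Fpz
    bp <- band_powers(sp, cfg$bands_hz)
    bp$power_uv2[bp$band == "SWA"]
  }, numeric(1))
  expect_gt(swa["N3"], swa["N2"])
  expect_gt(swa["N2"], swa["REM"])
})
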
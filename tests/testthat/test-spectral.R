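test_that("Welch estimator has the stated grid and satisfies Parseval", {
  fs <- 500
  ps0 <- welch_psd(numeric(8192), fs, 4096, 0.5)
  expect_equal(ps0$freqs_hz[2] - ps0$freqs_hz[1], fs / 4096)
  expect_true(all(ps0$psd == 0))
  expect_equal(ps0$freqs_hz[1], 0)

  t <- (0:(fs * 60 - 1)) / fs
  x <- 3 * sin(2 * pi * 2 * t)
  ps <- welch_psd(x, fs, 4096, 0.5)
  df <- ps$freqs_hz[2] - ps$freqs_hz[1]
  expect_equal(sum(ps$psd) * df, 3^2 / 2, tolerance = 0.1)

  set.seed(1)
  w <- welch_psd(stats::rnorm(fs * 60), fs, 4096, 0.5)
  expect_equal(sum(w$psd) * df, 1, tolerance = 0.1)

  expect_error(welch_psd(numeric(1000), fs, 4096), "4096")
})

test_that("NREM spectra use only eligible epochs and report 0.12-Hz bins", {
  cfg <- session_config()
  fs <- 500
  t <- (0:(fs * 120 - 1)) / fs
  rec <- eeg_recording(list(Cz = sin(2 * pi * 2 * t) +
                              make_pink_noise(120, fs, 1, seed = 3)), fs)
  hyp <- hypnogram(rep(c("N2", "Wake"), each = 2))
  sp <- power_spectrum(rec, hyp, cfg)$Cz
  expect_equal(sp$freqs_hz[2] - sp$freqs_hz[1], 500 / 4096)
  expect_equal(round(sp$freqs_hz[2] - sp$freqs_hz[1], 2), 0.12)
  expect_error(power_spectrum(rec, hypnogram(rep("Wake", 4)), cfg),
               "eligible")
})

test_that("band powers integrate half-open bands additively", {
  cfg <- session_config()
  fs <- 500
  t <- (0:(fs * 120 - 1)) / fs
  x <- sin(2 * pi * 2 * t) + 0.3 * sin(2 * pi * 13 * t) +
    make_pink_noise(120, fs, 0.5, seed = 9)
  sp <- welch_psd(x, fs, 4096, 0.5)
  bp <- band_powers(sp, cfg$bands_hz)
  expect_equal(bp$power_uv2[bp$band == "SWA"],
               bp$power_uv2[bp$band == "SO"] +
                 bp$power_uv2[bp$band == "delta"])
  # scaling: doubling amplitude adds log10(4) to every band
  bp2 <- band_powers(welch_psd(2 * x, fs, 4096, 0.5), cfg$bands_hz)
  expect_equal(bp2$log10_power - bp$log10_power,
               rep(log10(4), nrow(bp)), tolerance = 1e-6)
  # a pure 13-Hz tone concentrates in the fast-spindle band
  tone <- welch_psd(sin(2 * pi * 13 * t), fs, 4096, 0.5)
  sel <- tone$freqs_hz >= 9.5 & tone$freqs_hz < 15.5
  fast <- tone$freqs_hz >= 12.5 & tone$freqs_hz < 15.5
  expect_gte(sum(tone$psd[fast]) / sum(tone$psd[sel]), 0.95)
  expect_error(band_powers(welch_psd(numeric(8192), fs), cfg$bands_hz),
               "zero power")
})

erp_session <- function(seed = 9) {
  memo(paste0("erp-", seed), function() {
    gen <- generator_config(duration_s = 600,
                            stages = rep(c("N2", "N3"), each = 10),
                            so_rate_per_epoch = 0.5,
                            spindle_rate_per_epoch = 0.5, seed = seed)
    s <- generate_session(gen)
    trig <- seq(40, 560, by = 6)
    s$recording <- add_evoked_responses(
      s$recording, trig, evoked_template(amp_uv = -60, latency_s = 0.5))
    s$trig <- trig
    s
  })
}

test_that("stimulus-locked windows span [-1, 3) s at 100 Hz", {
  cfg <- session_config()
  s <- erp_session()
  set <- extract_stim_locked(s$recording, s$trig, s$hypnogram, cfg)
  expect_length(set$time_s, 400)
  expect_equal(set$time_s[1], -1)
  expect_equal(set$time_s[400], 2.99)
  expect_true(all(set$sem >= 0))
  # trigger too close to the recording edge is excluded and counted
  set2 <- extract_stim_locked(s$recording, c(s$trig, 599.5), s$hypnogram,
                              cfg)
  expect_equal(set2$n_excluded, 1L)
  expect_equal(set2$n_epochs, set$n_epochs)
  # constant signal stays constant through the pipeline
  recc <- eeg_recording(list(Fpz = rep(20, 500 * 120)), 500)
  hypc <- hypnogram(rep("N2", 4))
  setc <- extract_stim_locked(recc, c(30, 60, 90), hypc, cfg)
  expect_lt(max(abs(setc$mean - 20)), 0.2)
})

test_that("the grand mean recovers the evoked template latency", {
  cfg <- session_config()
  s <- erp_session()
  set <- baseline_normalize(
    extract_stim_locked(s$recording, s$trig, s$hypnogram, cfg), cfg)
  tmpl <- evoked_waveform(evoked_template(amp_uv = -60, latency_s = 0.5),
                          100)
  t_tmpl <- 0.5 + (which.min(tmpl) - 0.5) / 100
  post <- set$time_s > 0 & set$time_s < 2
  t_meas <- set$time_s[post][which.min(set$mean[post])]
  expect_lte(abs(t_meas - t_tmpl), 0.03)
})

test_that("baseline normalisation is idempotent and offset-invariant", {
  cfg <- session_config()
  s <- erp_session()
  set <- extract_stim_locked(s$recording, s$trig, s$hypnogram, cfg)
  bn <- baseline_normalize(set, cfg)
  sel <- bn$time_s >= -0.99 & bn$time_s <= -0.01
  expect_lt(max(abs(rowMeans(bn$epochs[, sel]))), 1e-10)
  bn2 <- baseline_normalize(bn, cfg)
  expect_equal(bn2$mean, bn$mean)
  expect_equal(bn2$epochs, bn$epochs)
  # +10 uV on the raw recording leaves normalised traces unchanged
  rec_off <- eeg_recording(list(Fpz = s$recording$data$Fpz + 10), 500)
  bn_off <- baseline_normalize(
    extract_stim_locked(rec_off, s$trig, s$hypnogram, cfg), cfg)
  expect_equal(bn_off$mean, bn$mean, tolerance = 1e-6)
  expect_error(baseline_normalize(set, session_config(
    baseline_window_s = c(-2, -0.01))), "outside")
})

test_that("grand averaging runs over session means", {
  cfg <- session_config()
  s <- erp_session()
  set <- extract_stim_locked(s$recording, s$trig, s$hypnogram, cfg)
  halves <- list(
    soclas:::new_stim_locked_set(set$time_s, set$epochs[1:40, ], 0L, "Fpz"),
    soclas:::new_stim_locked_set(set$time_s, set$epochs[41:80, ], 0L, "Fpz"))
  ga <- grand_average_stim_locked(halves)
  expect_equal(ga$mean, (halves[[1]]$mean + halves[[2]]$mean) / 2)
  expect_equal(ga$n_epochs, 2L)
  expect_error(grand_average_stim_locked(list()), "no sessions")
})

test_that("spindle RMS traces track spindles injected after triggers", {
  cfg <- session_config()
  gen <- generator_config(duration_s = 600,
                          stages = rep(c("N2", "N3"), each = 10),
                          so_rate_per_epoch = 0, spindle_rate_per_epoch = 0,
                          seed = 31)
  s <- generate_session(gen)
  trig <- seq(40, 560, by = 8)
  x <- s$recording$data$Fpz
  for (tt in trig) x <- inject_burst(x, 500, tt + 1.0, 0.8, 13.5, 30)
  rec <- eeg_recording(list(Fpz = x), 500)
  pk <- fast_peaks <- structure(list(slow_peak_hz = 11,
                                     fast_peak_hz = 13.5),
                                class = "spindle_peaks")
  rl <- spindle_rms_locked(rec, trig, s$hypnogram, pk, cfg)
  expect_true(rl$fast$baseline_applied)
  pk_t <- rl$fast$time_s[which.max(rl$fast$mean)]
  expect_gte(pk_t, 0.8)
  expect_lte(pk_t, 1.4)
  # without spindle activity the normalised trace hovers around zero
  expect_lt(max(abs(rl$slow$mean)), max(rl$fast$mean) / 2)
})

test_that("the RMS envelope of a pure tone equals A/sqrt(2)", {
  fs <- 500
  x <- 10 * sin(2 * pi * 13 * (0:(fs * 10 - 1)) / fs)
  r <- soclas:::sliding_rms(x, round(0.2 * fs))
  core <- r[(fs):(9 * fs)]
  expect_true(all(abs(core - 10 / sqrt(2)) / (10 / sqrt(2)) < 0.05))
})
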
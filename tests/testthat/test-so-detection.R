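make_so_session <- function(amps, fs = 500, epoch_gap_s = 5,
                            neg_dur = 1.1, pos_dur = 0.9, pos_frac = 0.5,
                            noise_uv = 1, seed = 19) {
  per <- neg_dur + pos_dur + epoch_gap_s
  dur <- ceiling((length(amps) * per + 60) / 30) * 30
  x <- make_pink_noise(dur, fs, noise_uv, seed = seed)
  starts <- 10 + (seq_along(amps) - 1) * per
  for (i in seq_along(amps)) {
    w <- make_so_waveform(amps[i], neg_dur, abs(amps[i]) * pos_frac,
                          pos_dur, fs)
    i0 <- round(starts[i] * fs)
    x[i0:(i0 + length(w) - 1)] <- x[i0:(i0 + length(w) - 1)] + w
  }
  list(rec = eeg_recording(list(Fz = x), fs),
       hyp = hypnogram(rep("N3", dur / 30)),
       trough_times = starts + neg_dur / 2)
}

test_that("flat or homogeneous signals yield no SO events", {
  cfg <- session_config()
  rec <- eeg_recording(list(Fz = numeric(500 * 60)), 500)
  hyp <- hypnogram(rep("N2", 2))
  expect_equal(nrow(detect_sos(rec, hyp, cfg)), 0)

  # homogeneous 0.6-Hz sinusoid: every trough equal, so the 1.25 x mean
  # relative threshold exceeds all of them
  t <- (0:(500 * 60 - 1)) / 500
  rec2 <- eeg_recording(list(Fz = 100 * sin(2 * pi * 0.6 * t)), 500)
  expect_equal(nrow(detect_sos(rec2, hyp, cfg)), 0)

  # no NREM: warning and empty result
  hyp_w <- hypnogram(rep("Wake", 2))
  expect_warning(out <- detect_sos(rec2, hyp_w, cfg), "no artefact-free")
  expect_equal(nrow(out), 0)
})

test_that("the relative threshold separates a bimodal SO population", {
  cfg <- session_config()
  s <- make_so_session(rep(c(-150, -50), each = 10))
  ev <- detect_sos(s$rec, s$hyp, cfg)
  expect_equal(nrow(ev), 10)
  # exactly the ten large events, matched by trough time
  big <- s$trough_times[1:10]
  expect_true(all(vapply(big, function(t)
    any(abs(ev$trough_time_s - t) < 0.2), logical(1))))
  # post-hoc: every event surpasses both thresholds
  thr <- attr(ev, "thresholds")$Fz
  expect_true(all(ev$trough_amp_uv <= thr["neg"]))
  expect_true(all(ev$p2p_amp_uv >= thr["p2p"]))
  # ordering and geometry invariants
  expect_true(all(diff(ev$trough_time_s) > 0))
  expect_true(all(ev$start_s < ev$trough_time_s))
  expect_true(all(ev$trough_time_s < ev$pos_peak_time_s))
  expect_true(all(ev$pos_peak_time_s < ev$end_s))
  expect_true(all(ev$neg_halfwave_s >= cfg$halfwave_bounds_s[1]))
  expect_true(all(ev$neg_halfwave_s <= cfg$halfwave_bounds_s[2]))
  expect_equal(ev$length_s, ev$neg_halfwave_s + ev$pos_halfwave_s)
  expect_equal(ev$p2p_amp_uv, ev$pos_peak_amp_uv - ev$trough_amp_uv)
})

test_that("event lists are invariant to a DC offset", {
  cfg <- session_config()
  s <- make_so_session(rep(c(-150, -50), each = 8))
  ev1 <- detect_sos(s$rec, s$hyp, cfg)
  rec2 <- eeg_recording(list(Fz = s$rec$data$Fz + 200), 500)
  ev2 <- detect_sos(rec2, s$hyp, cfg)
  expect_equal(ev1$trough_time_s, ev2$trough_time_s)
  expect_equal(ev1$trough_amp_uv, ev2$trough_amp_uv, tolerance = 1e-6)
})

test_that("frozen thresholds can be reused across sessions", {
  cfg <- session_config()
  s <- make_so_session(rep(c(-150, -50), each = 8))
  thr <- so_thresholds(s$rec, s$hyp, cfg)
  expect_named(thr, "Fz")
  ev <- detect_sos(s$rec, s$hyp, cfg, thresholds = thr)
  ev0 <- detect_sos(s$rec, s$hyp, cfg)
  expect_equal(ev$trough_time_s, ev0$trough_time_s)
})

test_that("summaries report density and half-wave ratio correctly", {
  cfg <- session_config()
  # 40 events over 20 NREM epochs -> density 2 per 30 s
  ev <- data.frame(channel = "Fz",
                   trough_amp_uv = rep(-100, 40),
                   pos_peak_amp_uv = 50, p2p_amp_uv = 150,
                   length_s = 1.9, slope_uv_per_s = 300,
                   neg_halfwave_s = 1.0, pos_halfwave_s = 0.9)
  hyp <- hypnogram(rep(c("N2", "Wake"), c(20, 10)))
  sm <- summarize_sos(ev, hyp, cfg)
  expect_equal(sm$count, 40)
  expect_equal(sm$density, 2.0)
  expect_equal(sm$pos_neg_ratio, 0.9)
  # empty events: count 0, means undefined
  sm0 <- summarize_sos(ev[0, ], hyp, cfg)
  expect_equal(sm0$count, 0)
  expect_true(is.na(sm0$mean_trough_amp_uv))
})

test_that("grand averages are exact for identical waveforms", {
  cfg <- session_config()
  s <- make_so_session(rep(-120, 12), noise_uv = 1e-6)
  ev <- detect_sos(s$rec, s$hyp, cfg)
  # homogeneous population: relative threshold rejects all, so average the
  # candidates found with frozen permissive thresholds
  ev <- detect_sos(s$rec, s$hyp, cfg,
                   thresholds = list(Fz = c(neg = -40, p2p = 60)))
  expect_gt(nrow(ev), 5)
  ga <- grand_average_so(s$rec, ev, window_s = 1.5)
  expect_length(ga$mean, 1501)
  expect_lt(max(ga$sem), 1e-3)
  expect_equal(min(ga$mean), -120, tolerance = 2)
  expect_error(grand_average_so(s$rec, ev[0, ]), "no events")
})

test_that("grand-average SEM matches sampling theory under white noise", {
  cfg <- session_config()
  fs <- 500
  sigma <- 5
  s <- make_so_session(rep(-120, 30), noise_uv = 1e-6, epoch_gap_s = 4)
  set.seed(33)
  x <- s$rec$data$Fz + stats::rnorm(length(s$rec$data$Fz), 0, sigma)
  rec <- eeg_recording(list(Fz = x), fs)
  ev <- detect_sos(rec, s$hyp, cfg,
                   thresholds = list(Fz = c(neg = -40, p2p = 60)))
  n <- nrow(ev)
  expect_gt(n, 20)
  ga <- grand_average_so(rec, ev, window_s = 1.5)
  expected <- sigma / sqrt(n)
  frac <- mean(ga$sem > 0.7 * expected & ga$sem < 1.3 * expected)
  expect_gte(frac, 0.9)
})

test_that("density times NREM duration equals the count exactly", {
  cfg <- session_config()
  s <- recovery_session(0.2)
  ev <- detect_sos(s$recording, s$hypnogram, cfg)
  sm <- summarize_sos(ev, s$hypnogram, cfg)
  n_nrem <- sum(s$hypnogram$stages %in% c("N2", "N3"))
  expect_equal(sm$density * n_nrem, sm$count)
})

test_that("margin recall is high at high SNR and monotone in noise", {
  cfg <- session_config()
  recalls <- vapply(c(0.2, 0.5, 1.0), function(mult) {
    s <- recovery_session(mult)
    ev <- detect_sos(s$recording, s$hypnogram, cfg)
    so_recall(ev, s$ground_truth$so_events)$recall
  }, numeric(1))
  expect_gte(recalls[1], 0.9)
  expect_true(all(diff(recalls) <= 1e-9))   # non-increasing with noise
})
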
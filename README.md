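# soclas — closed-loop acoustic stimulation and sleep EEG event analysis

`soclas` is an R package for researchers who study slow-oscillation-targeted
closed-loop acoustic stimulation (CLAS) in sleep EEG. During deep non-REM
sleep the cortex generates slow oscillations (SOs, < ~1 Hz): a
surface-negative down-state half-wave followed by a positive up-state that
groups sleep spindles (9–16 Hz, 0.5–3 s). CLAS systems detect these waves
online and play short sound bursts timed to the up-state. The package
provides every computational stage such a study needs, each independently
testable:

* **Online controller (replay).** Causal 200-Hz streams (0.25–4 Hz SO
  stream, 0.25–45 Hz broadband); adaptive negativity threshold
  `thr = min(−80 µV, mean trough amplitude of the trailing 5 s)` updated
  every 0.5 s; a delta/theta power ratio gate
  `P(0.5–4 Hz) / P(4–8 Hz)` with an individually selected threshold;
  stimulation only after stable N3 (4 min first bout / 2 min later) within
  the first 4 h; burst 1 at the detected SO negative peak plus an
  individualised delay, burst 2 a fixed 1075 ms later, then a ≥ 2.5 s
  refractory pause. Bursts are 50 ms of pink noise with 5-ms ramps.
* **Offline SO detection** (Mölle-style): zero-phase 0.5–3.5 Hz band-pass,
  negative half-waves of 0.75–2 s between zero-crossings, per-channel
  thresholds at 1.25 × the mean trough and mean trough-to-peak amplitudes.
* **Spindle detection** at individual peak frequencies: 3-Hz-wide FIR band
  on the 35-Hz low-passed, 100-Hz downsampled signal, 0.2-s RMS envelope,
  1.5 SD / 2.5 SD criteria for 0.5–3 s, merge rule for sub-0.5-s gaps.
* **Spectra and stimulus-locked analyses**: Welch spectra (Hanning 4096,
  50 % overlap → 0.12 Hz resolution at 500 Hz), log10 band powers,
  `[−1, 3)` s ERPs at 100 Hz with `[−0.99, −0.01]` s baseline
  normalisation, spindle RMS time courses.
* **Statistics**: exact paired Wilcoxon signed-rank tests (full 2^n
  enumeration up to n = 15, tie-corrected normal approximation beyond),
  running pointwise tests with Benjamini–Hochberg FDR masks, and sleep
  architecture (TST, WASO, efficiency, stage percentages, REM per
  night-half).
* **Synthetic polysomnography** with exact ground truth: stage-coloured
  1/f background, half-sine SOs, enveloped spindle bursts coupled to
  up-states, K-complex-like evoked responses — so the whole pipeline runs
  and is validated without any human data.

## Worked example

```r
library(soclas)

cfg <- session_config(delay_ms = 900, dt_ratio_threshold = 4)
gen <- generator_config(duration_s = 600, stages = rep("N3", 20),
                        so_rate_per_epoch = 6, spindle_rate_per_epoch = 1,
                        so_amp_range_uv = c(-170, -140), seed = 7)
s <- generate_session(gen)
s$recording
#> <eeg_recording> 1 channel(s) x 300000 samples @ 500 Hz (600.0 s)
#>   channels: Fpz
#>   reference: synthetic (linked mastoids model)

triggers <- run_controller(s$recording, s$hypnogram, cfg)
head(triggers[triggers$burst_index == 1, ], 3)
#>    time_s burst_index detection_time_s threshold_uv dt_ratio
#> 1 223.900           1          223.000          -80 17.39855
#> 3 232.065           1          231.165          -80 21.04486
#> 5 239.505           1          238.605          -80 12.07505
```

The first pair arrives at 223.9 s: stimulation only becomes eligible after
4 min of stable N3 (epoch 8 ends at 240 s of staging, here reached at
210 s), the burst follows the detected negative peak by the 900-ms
individualised delay, the threshold is still at its −80 µV floor, and the
delta/theta ratio (17.4) is far above the gate. The session yields 44
burst pairs, every pair spaced exactly 1075 ms.

```r
so <- detect_sos(s$recording, s$hypnogram, session_config())
summarize_sos(so, s$hypnogram, session_config())[,
  c("channel", "count", "density", "mean_trough_amp_uv", "mean_length_s")]
#>   channel count density mean_trough_amp_uv mean_length_s
#> 1     Fpz    12     0.6          -116.2208      1.902167

estimate_spindle_peaks(s$recording, s$hypnogram, session_config())
#> <spindle_peaks> slow 10.99 Hz, fast 13.55 Hz
```

The offline detector keeps the 12 events that surpass both relative
thresholds (0.6 per 30 s of NREM); the spindle peak estimates land on the
injected 11 / 13.5 Hz carriers to within the 0.12-Hz spectral resolution.

## Analysis workflow

`analysis/` contains numbered drivers that simulate a two-condition study
at desk scale and push it through the full pipeline, writing tables under
`results/`:

1. `01_simulate_sessions.R` — adaptation + two condition nights per subject
2. `02_calibrate_controller.R` — individual delta/theta gate and SO delay
3. `03_replay_controller.R` — controller replay, trigger tables, timing summary
4. `04_detect_events.R` — offline SO/spindle detection (thresholds frozen
   from the reference condition), property summaries
5. `05_stimlocked_spectra.R` — SO-locked grand averages, burst-locked ERPs,
   spindle RMS traces, band powers
6. `06_condition_stats.R` — running paired Wilcoxon with FDR masks,
   property tests, sleep architecture

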
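---
title: "Closed-loop acoustic stimulation and sleep EEG event analysis with soclas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop acoustic stimulation and sleep EEG event analysis with soclas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soclas)
```

## The problem

During deep non-REM (N3) sleep the cortex generates slow oscillations
(SOs): large biphasic waves below ~1 Hz whose surface-negative half-wave
(the down-state) is followed by a positive up-state during which sleep
spindles preferentially occur. Closed-loop acoustic stimulation (CLAS)
detects these waves in real time and plays brief sound bursts timed to the
up-state, a technique used to probe and enhance sleep-dependent memory
consolidation. `soclas` provides a deterministic, testable replay
implementation of such a controller, the standard offline detectors for
SOs and spindles, the stimulus-locked and spectral analyses used to
quantify the response, the associated nonparametric statistics, and a
seeded synthetic polysomnography generator so that every stage can be
validated against known ground truth without access to human recordings.

## The online controller

The controller monitors one frontal channel through two causal streams at
200 Hz: an SO stream band-limited to 0.25--4 Hz and a broadband stream
(0.25--45 Hz) from which a delta/theta power ratio (0.5--4 Hz over
4--8 Hz) is computed as a proxy for NREM depth. Stimulation is gated
three ways:

* the delta/theta ratio must exceed an individual threshold, chosen from
  an adaptation night as the smallest unit-width histogram bin edge `t`
  maximising `P(ratio >= t | NREM) - P(ratio >= t | Wake or REM)` -- an
  automated stand-in for the visual two-histogram rule;
* stimulation is enabled only after sustained N3: 4 min of consecutive
  artefact-free N3 epochs for the first deep-sleep bout of the night,
  2 min for later bouts, and is disabled by any epoch lighter than N2
  until stability re-accrues;
* only the first 4 h of the recording are eligible.

Detection itself uses an adaptive negativity threshold, initially
-80 uV and updated every 0.5 s as `min(-80, mean of detected trough
amplitudes in the trailing 5 s)` -- it tracks deepening slow waves but
never loosens above the floor. We anchor detection at the negative
half-wave peak: a trough is recognized causally once the stream has risen
5 uV above its running minimum (the hysteresis suppresses noise ripples on
a descending half-wave). The first sound burst is scheduled at the trough
plus the individualised delay (the mean negative-to-positive peak interval
of offline-detected SOs from the adaptation night, ~0.9--1 s for typical
waves, placing the burst near the up-state), the second a fixed 1075 ms
later; each burst is 50 ms of pink noise with 5-ms ramps. A refractory
pause of at least 2.5 s follows before the detector re-arms.

Two properties of any causal implementation deserve note. First, a causal
0.25-Hz high-pass attenuates second-long transients appreciably (a
first-order section passes a 1.1-s negative half-wave at gain ~0.65; a
second-order section at ~0.53), so we use the first-order section: raw
troughs near -125 uV then reach the -80 uV criterion. Second, the same
filter leads in phase at SO frequencies, so the online-detected negative
peak precedes the true trough by roughly 0.1 s. In hardware this constant
is absorbed by the individualised delay; in tests we assert burst timing
at the achievable bound (median error below 0.2 s) rather than pretending
the lead does not exist.

## Offline detectors

**Slow oscillations** follow the classical zero-crossing procedure: the
signal is band-passed 0.5--3.5 Hz (zero-phase; the high-pass section is
first order so half-wave geometry survives), candidate events are
negative half-waves of 0.75--2 s between a negative-going and the next
positive-going zero-crossing together with the following positive
half-wave, and per-channel thresholds are set at 1.25 times the mean
trough amplitude and 1.25 times the mean trough-to-peak amplitude over
all candidates. An event must surpass both. Because the thresholds are
population-relative, a homogeneous train of identical waves yields *no*
events -- the detector finds the large minority, which is why recovery is
scored over margin-qualifying injected events (see below). Thresholds can
be frozen from a reference session (`so_thresholds()`), mirroring designs
in which both condition nights use thresholds derived from one of them.

**Spindles** are detected, per the offline pipeline, on the 35-Hz
low-passed signal downsampled to 100 Hz. Individual slow (9--12 Hz) and
fast (12--16 Hz) peak frequencies are taken from the NREM Welch spectrum
on the Hanning/4096 grid; a 3-Hz-wide FIR band centred on each peak is
followed by a 0.2-s RMS envelope, 0.2-s smoothing, and thresholding at
1.5 SD of the band-passed artefact-free NREM signal for 0.5--3 s with at
least one sample above 2.5 SD. Events closer than 0.5 s merge when their
total supra-threshold time stays below 3 s. Both thresholds are standard
deviations of the signal itself, so the event set is invariant to global
amplitude scaling and DC offsets. Note that the duration criterion bounds
the *RMS exceedance*, which is wider than the underlying burst by roughly
the 0.4 s of envelope spreading; a very strong sub-0.5-s burst can
therefore still produce a 0.5-s exceedance -- this is a property of the
published rule, not an implementation artifact.

## Spectra and stimulus-locked analyses

Power spectra are Welch averages of Hanning-windowed 4096-sample segments
with 50% overlap (0.12-Hz resolution and 8.2-s windows at 500 Hz),
normalised so a unit-variance white signal integrates to one. Band powers
integrate half-open bands (SO 0.5--1.5, delta 1.5--4, SWA 0.5--4, theta
4--9, slow spindle 9.5--12.5, fast spindle 12.5--15.5 Hz) and are
log10-transformed; adjacent bands partition exactly.

Stimulus-locked responses low-pass at 35 Hz (zero-phase FIR whose -3 dB
point is placed at 32.0 Hz by numerical design), downsample to 100 Hz,
and extract half-open `[-1, 3)`-s windows (exactly 400 samples) around
first-burst triggers snapped to the 100-Hz grid; windows touching
artefact epochs, non-N2/N3 epochs or the recording edges are dropped and
counted. Baseline normalisation subtracts each epoch's mean over
`[-0.99, -0.01]` s; it is idempotent and removes any DC offset. Grand
averages are means of per-session means, so subject-level averaging
precedes statistics everywhere. Spindle RMS time courses apply the
band-pass/RMS/smoothing chain before epoching.

## Statistics

The paired Wilcoxon signed-rank test drops zero differences, mid-ranks
ties, and is exact by full enumeration of the `2^n` sign assignments up
to n = 15 (at most 32768 patterns; cached null tables make the running
tests cheap), with a tie-corrected normal approximation beyond. Running
tests apply it at every time point and report both the uncorrected
p < 0.05 mask and the Benjamini-Hochberg mask at q = 0.05 -- the dual
display customary for stimulus-locked traces. BH is applied within one
channel's time grid; rejections are monotone in q and the FDR mask never
exceeds the raw mask. Sleep architecture reports TST, WASO (wake after
the first sleep epoch), efficiency, per-stage minutes and percentages,
and REM split at the midpoint of time in bed (the split point is a
package choice; definitions of "night half" vary).

## The synthetic generator

`generate_session()` is not a biophysical model; it generates the minimal
structure the detectors assume: stage-scaled pink (1/f) background with
extra 0.5--2-Hz colouring in deep NREM and 4--8-Hz colouring in REM/Wake;
SOs as a negative then positive half-sine with exposed half-wave
durations and amplitudes; spindles as raised-cosine-enveloped sinusoids,
optionally onset-locked to an SO up-state; and damped biphasic
(K-complex-like) evoked responses at trigger times. Default conditions:
30-s epochs in night-like cycles (N2-N3-N2-REM after a Wake/N1 lead-in),
SO troughs uniform in -140 to -80 uV with 1.0--1.4-s negative half-waves
at 3 events per NREM epoch, spindles near 11 and 13.5 Hz at 25 uV and one
per epoch and type, half of them coupled to up-states. Seeded streams are
split per event family, so adding spindles never moves SOs. Everything
injected is recorded with exact timing in the ground truth.

What passing tests on this generator do *not* show: real EEG has
non-stationary arousals, waveform asymmetries, topographic structure and
artefacts that the generator omits; recovery rates here validate the
detector logic, not clinical performance.

Two generator-related scoring choices matter. Because the SO detector's
thresholds are population-relative, recovery is scored over injected
events that satisfy the same 1.25-times-mean margin applied to the
ground-truth amplitudes, on sessions with a bimodal deep/shallow
amplitude mixture so both modes sit far from the threshold. And matching
uses a 0.2-s tolerance on trough times: the 0.5-Hz offline high-pass
displaces the filtered trough of 1.2--1.4-s half-waves by up to ~0.15 s
relative to the unfiltered injected waveform.

## Numerical choices and degenerate inputs

Half-open interval conventions throughout (`[start, end)` for epochs and
bands); 0-based times in seconds from recording start; trigger times on
the controller's 200-Hz grid, so the 1075-ms interburst interval is
exactly 215 samples. The delta/theta ratio of an all-zero window is
defined as 1 (neutral) with a message; a gate selection over identical
class distributions returns the smallest bin edge with a degeneracy
warning; an all-zero paired difference vector gives p = 1 with a
degenerate flag; empty event sets summarise to count 0 with undefined
means flagged as NA. EDF export quantises each channel to 16 bits over
its observed range -- the native RDS container is the lossless path.

## Problem sizes

The bundled tests and the acceptance script run on 10--30-minute sessions
with 6--20 subjects' worth of simulated data and 120--500-replicate null
simulations; these sizes were chosen so the full validation cycle
completes in a few minutes on a laptop while keeping every check
statistically meaningful (e.g., Poisson placement is verified within 3
sigma of an expectation of 160 events, and the running-test level within
[0.03, 0.07] over 100,000 pointwise tests).

## Limitations

The controller replays recordings deterministically; it does not model
audio latency, volume staircases, or arousal-triggered manual
interventions (a hard stage-based gate stands in for the human in the
loop). The generator's SO amplitude and duration distributions are free
parameters, not fits to any subject population. tDCS scheduling around
CLAS is reduced to its timing gates; electrical delivery is out of scope.
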
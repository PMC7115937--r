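---
title: "Self-calibrating arousal detection in whole-night sleep EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-calibrating arousal detection in whole-night sleep EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arousalkit)
```

## The problem

Micro-arousals are transient (at least 3 s) accelerations of the sleep EEG
toward theta, alpha and beta frequencies. They are part of normal sleep
microstructure, increase with age and in pathologies such as sleep apnoea,
and their density is a standard marker of sleep fragmentation. In practice
they are scored visually, which is slow and notoriously rater-dependent:
different scorers — and especially different laboratories — can disagree
substantially on how large a frequency shift must be to count.

`arousalkit` implements a fully automatic detector whose thresholds are
derived from each recording itself (medians and ratios of the recording's
own band powers and muscle tone), so no training phase and no absolute
power calibration is needed, together with the agreement framework used to
validate such detectors against human raters, and a synthetic
polysomnography generator that makes the whole pipeline testable without
any real recording.

## The detection model

The recording — EEG channels referenced to linked mastoids, two
electrooculogram channels and a bipolar pair of submental EMG channels, in
microvolts — is processed on a fixed time grid: 30 s *scoring windows*
partitioned into 1 s *epochs*. All decisions are made per 1 s epoch and
all local context is defined per 30 s window.

**Preprocessing.** Each modality is band-passed with an order-3 Butterworth
filter: EEG 0.5–30 Hz, EOG 0.1–5 Hz, EMG 10–100 Hz; each channel is then
mean-corrected over the whole recording. Filtering is zero-phase
(forward–backward) so that event onsets are not delayed by the filter's
group delay; the effective roll-off is twice the single-pass slope, which
is immaterial here because every later threshold is self-calibrating. When
the EMG low-pass edge reaches Nyquist (e.g. 100 Hz against 128 Hz data) it
is clipped to 0.9 × fs/2 and a warning is emitted.

**Channel screening.** EEG channels with a whole-recording standard
deviation below 1 µV (flat) or above 6×10³ µV (saturated) are dropped
globally. Per 30 s window, each remaining channel's SD is compared with
the median SD of the other good channels; a ratio above 5 — or below 1/5,
since a channel that dies inside one window is as unusable as one that
explodes — marks the channel bad for that window only. The median (rather
than mean) of the other channels' SDs is used so that a second bad channel
cannot drag the reference.

**Composite EMG.** The two referenced submental channels are screened per
window: a channel whose median absolute amplitude is below 0.1 µV is flat;
if none is flat, a channel whose window median absolute amplitude is at
least twice the other's is candidate-noisy, and is confirmed noisy when
the per-epoch ratio of mean absolute amplitudes exceeds 2 in more than
half the window's epochs (> 15 of 30) — this separates constant from
transitory contamination. The composite trace is the bipolar difference
where both channels are clean, the surviving referenced channel where one
is excluded, and masked where neither is usable; masked windows propagate
as "EMG unavailable": no EMG shift can be flagged there and REM events
cannot be confirmed. The flat and noisy tests are applied to the *absolute*
signal; a mean-corrected channel has a plain median near zero regardless of
its amplitude, so the literal median would be degenerate.

**EMG tone shifts.** The per-epoch tone is the mean absolute amplitude of
the composite EMG. Three cascaded tests find transient tone increases:
(1) *global* — epochs exceeding the maximum tone of the first 240 s
(taken as the subject's artefact-free baseline); (2) *local* — epochs
exceeding twice a median filter of the tone series over a symmetric,
centred 3-scoring-window (90 s) span. The span must be longer than the
events searched for: a median across ±1 s would sit on the burst itself
for any shift lasting 3 s or more and could never flag one, so the
3-window reading is the only self-consistent one. (3) *validation* — a
candidate peak is confirmed when its tone exceeds twice the median tone
of the nearest ten candidate-free epochs on each side (clipped at the
recording edges). Contiguous confirmed epochs merge into one shift.

**EEG frequency shifts.** Per 1 s epoch, band power in theta (3–7 Hz),
alpha (7–13 Hz), sigma (11–16 Hz) and beta (16–30 Hz) is computed by a
rectangular-window periodogram integrated over the band — on the 1 Hz bin
grid of a 1 s epoch the bands are half-open `[lo, hi)`, so the printed
alpha/sigma overlap never double-counts a bin — and fused across channels
by the median over the window's good EEG channels. An epoch is a shift in
a band when its power exceeds **both** a fixed threshold (the median power
of that band over the whole recording) and an adaptive one (twice the
median power over the window's EMG-shift-free epochs plus the nearest ten
EMG-shift-free epochs on each side of the window). Excluding EMG-shifted
epochs keeps muscle artefact from inflating the local background; the
two-threshold design is what makes the detector insensitive to global
amplitude: scaling the recording scales both sides of every comparison.

**Spindles.** Sleep spindles are sigma-band bursts that must not count as
arousals. The relative sigma power of an epoch, sigma over
(alpha + sigma + beta), is compared with its maximum over the recording;
epochs above 85 % of that maximum are spindle epochs.

**Event assembly.** The per-epoch trigger is any theta/alpha/beta shift
that is not a spindle epoch; maximal runs of at least three consecutive
triggered epochs become events (the AASM 3 s minimum). Spindle exclusion
is applied before run-finding, so a sigma epoch inside a run can split it.
An event is *EMG-associated* when an EMG shift overlaps it or lies within
1 s of its boundaries (muscle activity accompanying the EEG change;
strict overlap is a config switch). Events starting in wake are dropped;
events starting in REM are kept only when EMG-associated, the AASM
REM-concomitance rule. Runs may hand over between bands (a theta run
continuing as alpha counts as one event); requiring a single band is a
config switch (`same_band_runs`). No 10 s stable-sleep merging is applied
— that gap is part of the visual-scoring definition, not of this
detector — but a post-hoc `merge_gap_s` option exists (default off).

## The agreement framework

Human scores and detections are compared on a common 1 s grid: an epoch is
an arousal when events cover strictly more than 0.5 s of it. At epoch
level the framework reports Bennett's inter-rater agreement `S = 2·P0 − 1`
(simple, but blind to the heavy class imbalance of arousal scoring —
roughly 5 % of epochs are arousals) and Cohen's kappa, whose marginal
chance correction makes it conservative for unbalanced labels. At event
level, maximal runs are matched between raters requiring at least 1 s of
overlap, one-to-one and greedily in onset order (a gold event overlapped
by two detections yields one true positive and one false positive;
many-to-one matching is a switch). From the matching follow sensitivity
`Se = TPe/(TPe+FNe)`, the false discovery ratio `FDR = FPe/(TPe+FPe)`,
and the mean overlap `C`: the mean, over matched gold events, of the
overlapping seconds divided by the *gold* event's duration.

Two chance terms are available for kappa. `"standard"` is Cohen's
`Pe = [(TPs+FPs)(TPs+FNs) + (TNs+FNs)(TNs+FPs)]/n²`. `"paper-literal"`
reproduces an alternative printed form found in the sleep-scoring
literature, `Pr = (TPs+TNs)(TPs+FPs)/n²`, which is not Cohen's expected
agreement; because published kappa values in this area are sometimes
computed with it, both are implemented and every report names its variant.
The default is the standard form.

Two raters can be fused into a composite gold standard: *inclusive* (all
events found by either) or *conservative* (only events found by both, each
co-detected pair contributing its union interval by default — union keeps
event durations consistent with the Se/C semantics; intersection is a
switch). Per-sleep-stage stratified reports are provided for the epoch
coefficients only, since event counts within a stage stratum are not well
defined when events straddle stage boundaries.

## Time-frequency profiles

Detected events are characterised on their first 3 s (the definitional
minimum) by a complex Morlet transform on the channel-aggregated EEG, 1 Hz
bins centred at 0.5–29.5 Hz, 7 cycles per wavelet (a common compromise
between time and frequency resolution; configurable). Wavelets are
L2-normalised so white noise is flat across bins. Each bin is
baseline-corrected by subtracting its mean power over the event's first
500 ms (negative residuals clipped at zero); a pre-event 500 ms baseline
is available as `tf_baseline = "pre"` since the referent window of such a
correction is a genuine modelling choice — both variants agree on which
band dominates. Bin powers are summed over the 3 s and normalised to sum
to one; band sums aggregate theta (4.5–7.5 Hz), alpha (8.5–11.5 Hz) and
beta (16.5–29.5 Hz) on the bin-centre grid, with no bin in two bands.

## The synthetic generator

`synth_spec()`/`synth_psg()` emulate exactly the features the detector
keys on, with a ground-truth ledger:

* stage-labelled background EEG as `1/f^exponent` coloured noise, per
  stage: W (1.0, 15 µV), N1 (1.2, 20 µV), N2 (1.3, 30 µV), N3 (1.5,
  50 µV), REM (1.1, 20 µV). Amplitudes are EEG-band (≥ 0.5 Hz) SDs —
  components below 0.5 Hz are suppressed, because an unbounded 1/f tail
  would put most of the nominal variance into infra-slow drift that the
  acquisition high-pass removes anyway;
* arousal-like events as band-limited bursts — band-passed Gaussian noise
  by default, so band-power statistics resemble EEG (a pure-sine mode is
  kept for analytic unit tests) — scaled so the epoch band power in the
  target band is `gain` times the local background's, added coherently to
  all EEG channels; `gain = 4` with 3–5 s durations is the default event
  plan;
* submental EMG as broadband noise at realistic tone levels (W 8, NREM 5,
  REM 3 µV SD — REM lowest, atonia), with 8× tone bursts on one
  referenced channel for EMG-associated events;
* channel faults (flat or amplified intervals) applied last;
* one integer seed determines everything.

What the generator does **not** emulate: K-complexes, slow oscillations,
sawtooth waves, cyclic alternating pattern, ECG contamination, electrode
popping, real inter-channel correlation structure, or gradual stage
transitions (stages switch as discrete segments). Passing tests therefore
show that the implementation realises the stated rules and recovers
calibrated bursts in 1/f noise — not that it reproduces human scoring on
real, messier recordings.

## Numerical choices and degenerate inputs

* 1 s epochs at an integer sampling rate give an exact 1 Hz periodogram
  grid; bands are half-open `[lo, hi)` bins.
* The across-channel fusion of band power is the median over good
  channels (`aggregate = "median"`); `"any"` (flag if any channel shifts)
  is exposed but markedly more false-positive prone — with the median, a
  chance fluctuation must appear on half the channels at once.
* A scoring window whose adaptive selection set is empty (every candidate
  epoch EMG-shifted or missing) falls back to the fixed threshold, logged.
* Epochs in windows with no good EEG channel carry `NA` band power —
  never zero — and are never flagged.
* All-zero sigma denominators skip the spindle test for that epoch.
* Undefined agreement ratios (no gold events, no detections, no matches)
  are reported as `NA` with an explicit reason.
* Partial final windows are retained; per-window quotas (the > 15-epoch
  EMG noise rule) scale proportionally to the window's epoch count.
* A hypnogram shorter than the recording treats the unstaged tail as wake
  (arousals are not scored in wake), with a warning.

## Problem sizes used by the test-suite

Unit tests run on seconds-to-minutes of synthetic signal. The end-to-end
recovery checks use one 8 h night (fs 128 Hz, 3 EEG + 2 EMG channels)
with 40 injected bursts and one zero-event night; scale-invariance and
stage-rule checks use 1 h and 20 min nights. These sizes give stable
statistics (binomial confidence on 40 events, false-event counts over
28 800 epochs) while keeping a full run of the suite in a few minutes.

## Known limitations

* Thresholds are scale-free with three deliberate exceptions: the 1 µV /
  6×10³ µV global EEG bounds and the 0.1 µV EMG flatness cutoff are
  absolute. At physiological amplitudes they never bind, but a recording
  attenuated far below real-world levels (orders of magnitude) will start
  losing channels to the flat tests.
* Under steep 1/f backgrounds (deep N3) the rectangular-window
  periodogram lets slow-wave power leak into the theta band, which makes
  theta the most false-positive-prone band; on default synthetic nights
  this produces on the order of 0–3 spurious events per 8 h.
* The detector reports what the rules define, which is systematically
  more than human raters report; the EMG-associated subset
  (`emg_only = TRUE`) is the appropriate output when comparability with
  visual scoring matters more than sensitivity.
* EDF support is deliberately minimal: continuous 16-bit EDF/EDF+ with a
  common record duration; the annotations track is not parsed.

## A worked example

```{r example, eval = FALSE}
stages <- synth_spec(duration_s = 3600, seed = 42)$stages
plan <- plan_events(stages, n = 10, duration_s = 4, gain = 4,
                    with_emg = c(TRUE, FALSE),
                    stage_in = c("N1", "N2", "N3"), seed = 42)
syn <- synth_psg(synth_spec(duration_s = 3600, events = plan, seed = 42))

ad <- detect(syn$recording, syn$hypnogram)
report <- coefficients(confusion(to_track(ad, 3600),
                                 to_track(syn$ledger, 3600)))
report
```
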
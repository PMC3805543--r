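---
title: "Detecting systolic peaks in PPG signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting systolic peaks in PPG signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgpeaks)
```

## The problem

A fingertip photoplethysmogram records pulsatile blood-volume changes: each
heartbeat produces a dominant systolic wave followed by a smaller diastolic
wave. The systolic peak is the detection target; everything downstream
(pulse rate, rhythm analysis, heart-rate variability) depends on finding it
reliably. Under exercise and heat stress the signal becomes non-stationary
— amplitudes drift and drop abruptly, premature beats interrupt the rhythm,
and noise rises — which is exactly where fixed-threshold peak pickers fail.

`ppgpeaks` implements four detectors behind a common interface
(`detect_peaks(record, method)`), the evaluation statistics used to compare
them, a brute-force parameter optimiser, and a synthetic generator that
produces ground-truthed records emulating those recording conditions.
Throughout the package sample indices are 1-based (the R convention) and
block intervals are half-open `[onset, offset)`.

## The dual moving-average detector

The proposed detector (`detect_elgendi`) conditions the signal and compares
two moving averages whose windows match physiological event durations:

* **Bandpass** 0.5–8 Hz, zero-phase Butterworth, order 2 per direction.
  The lower corner removes baseline wander (respiration, motion, perfusion
  drift, typically < 0.5 Hz); the upper corner removes noise above the
  pulse-shape band.
* **Clip and square**: `z = max(y, 0)^2`. Squaring the half-wave-rectified
  signal widens the gap between systolic excursions and the smaller
  diastolic wave, so the block threshold separates them.
* **Two moving averages** of `z`, both centered: `MA_peak` with window
  `W1 = 111` ms emphasises the systolic-peak region, `MA_beat` with
  `W2 = 667` ms tracks the per-beat energy level and serves as the dynamic
  threshold baseline.
* **Offset** `alpha = beta * mean(z)` with `beta = 0.02` lifts the
  threshold `THR1 = MA_beat + alpha` above `MA_peak`'s excursions in noise-
  only stretches.
* **Blocks and rejection**: maximal runs with `MA_peak > THR1` are
  candidate blocks; only blocks at least `THR2 = W1` samples wide are kept
  (narrower excursions are diastolic waves or noise). The reported peak is
  the argmax of `z` within each surviving block.

Two properties follow from the construction and are asserted as tests:
multiplying the record by any positive constant scales `z`, both averages
and `alpha` by the same square factor, so the detections are *identical*
under amplitude rescaling; and raising `beta` can only shrink or merge the
set of samples above threshold, so the block count is non-increasing in
`beta`.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `f1`, `f2` | 0.5, 8 | Hz | bandpass corners |
| `w1_ms` | 111 | ms | systolic-duration window; also the minimum block width |
| `w2_ms` | 667 | ms | beat-duration window (dynamic threshold) |
| `beta` | 0.02 | — | offset as a fraction of `mean(z)` |

The defaults are the optimum of a brute-force search on resting recordings
(see below); `w1_ms` matches the systolic-peak duration and `w2_ms` a full
beat at resting heart rates.

## Comparator detectors

**Local extrema (`detect_billauer`).** An alternating state machine: the
running maximum is committed as a peak once the signal falls `delta` below
it, then a valley is hunted symmetrically. `delta = 0.1` is an *absolute*
amplitude, sensible only for signals of order unit amplitude — the detector
is deliberately not scale invariant (a documented contrast with the dual
moving-average detector), and the CLI offers `--normalize` to rescale to
unit maximum first. A 0.5–8 Hz bandpass is applied by default and can be
disabled to recover the original unfiltered behaviour.

**First-derivative delineator (`detect_li`).** Low-pass at 8 Hz, first
difference, then: maximal inflections (derivative maxima above an adaptive
amplitude threshold) mark beat upslopes; the following negative-going zero
crossing of the derivative is the systolic-peak candidate. Amplitude and
interval thresholds are seeded from 2 s selective windows at the start of
each of three equal record divisions and updated beat-by-beat as running
means; candidates closer than half the running beat interval to the
previous beat are rejected. The source method leaves the low-pass cutoff,
division count, and threshold arithmetic unstated; the package's choices
(8 Hz, 3 divisions, amplitude factor 0.5, interval gates 0.5/1.5, running
means with weight 0.2 on the newest beat) are exposed in `li_params()` and
documented as package defaults, not published values.

**Slope sum (`detect_zong`).** Low-pass, then the slope-sum function — the
windowed sum of positive first differences over 128 ms (47 samples at
367 Hz) — amplifies each pulse upslope. The threshold base initialises to
three times the mean SSF over the first 8 s; the crossing threshold is 60%
of the base, updated to each accepted pulse's SSF maximum. At a crossing,
the SSF minimum in the preceding and maximum in the following 150 ms are
compared: the pulse is accepted if the excursion exceeds 10% of the base (a
package parameter; the source states only "a certain value"). The onset is
traced backward to where the SSF exceeds 1% of the pulse maximum, shifted
20 ms earlier to offset the low-pass phase; a 300 ms refractory period
suppresses double detections. Because the method natively marks pulse
onsets, not systolic peaks, the reported peak is the argmax of the filtered
signal within 300 ms after the onset, making its output comparable with
systolic-peak annotations. Two package choices deserve note: the low-pass
cutoff is 16 Hz (unstated in the source; chosen to preserve the upslope the
SSF amplifies), and the backward onset search is bounded to the 150 ms
min-search window — with a 16 Hz low-pass, residual baseline-wander slope
keeps the SSF above the 1% floor almost everywhere, and an unbounded search
walks seconds into the preceding beat.

## Evaluation

`match_peaks()` pairs detections with annotations one-to-one, greedily in
order of increasing absolute time difference; a pair within ±50 ms
(inclusive) is a true positive. Sensitivity `SE = TP/(TP+FN)`, positive
predictivity `+P = TP/(TP+FP)`, overall accuracy their mean;
`evaluate_dataset()` pools counts across records before deriving the rates
(micro-averaging). When beats are separated by more than twice the
tolerance — always true here, since every detector's minimum peak spacing
far exceeds 50 ms — each detection can match at most one annotation and
greedy matching is provably optimal; the test suite verifies agreement with
an exhaustive optimal matcher in that regime and documents that greedy is
the contract on adversarial instances. Degenerate conventions: SE is 1 when
there are no annotations and +P is 1 when there are no detections, each
with a warning.

## Parameter optimisation

`grid_search()` scores every valid combination of a `grid_spec()` —
`(f1, f2)` pairs with `f1 >= f2` are skipped — by running the detector on
every record and pooling the evaluation. Rows are sorted by overall
accuracy; ties break by higher SE, then lower `W1`, lower `beta`, lower
`f2` (determinism; on clean data many cells tie at 100%). The default grid
spans the physiologically sensible ranges: low corner 0.5–1 Hz, high corner
7–15 Hz, systolic window 54–111 ms, beat window 545–694 ms, offset 0–10%;
any user grid is accepted. `run_pipeline()`
implements the full protocol: optimise on rest-condition records only,
freeze the best bundle, evaluate all four methods on every condition
without further adjustment, and write the grid and report CSVs.

## The synthetic generator

Heat-stress PPG recordings with expert annotations are not publicly
available, so `synth_ppg()` stands in with a ground-truthed emulation of
such recording conditions: 367 Hz, 20 s records;
resting heart rate 76 bpm or post-exercise tachycardia at 120 bpm; beat
intervals with ±3% uniform jitter; per-beat amplitude modulated by a slow
(0.08 Hz, ±20%) sinusoid; baseline wander (0.25 Hz, 30% of systolic
amplitude); additive white noise (2% at rest, 10% after exercise); sudden
per-beat amplitude drops to 25% (probability 5% after exercise) and
premature beats at ~55% of the running interval with 60% amplitude
(probability 3% after exercise).

Each beat is a systolic Gaussian plus a delayed (280 ms), smaller (40%)
diastolic Gaussian. The width parameters (150/220 ms) are the 2-sigma full
widths: with this mapping the diastolic bump rides on the systolic decay as
a shoulder with a shallow notch, the morphology seen in fingertip PPG.
(A narrower mapping leaves the diastolic wave free-standing, and any
extrema-based detector then double-counts every beat — a signature of an
unrealistic waveform, not of detector quality.) Ground truth is the
systolic apex of the *pre-noise* waveform — the argmax within a quarter
systolic width of the component centre, as an annotator marks the observed
peak; premature beats are annotated as true beats. All randomness flows
from a single seed, with per-record seeds derived by counter.

What the generator does *not* emulate: motion-artifact waveforms, reversed-
polarity pulses, respiration-modulated morphology beyond baseline wander,
and device-specific transfer characteristics. Perfect scores on clean
synthetic fixtures therefore demonstrate correctness of the implementations,
not expected field performance; the degraded presets (noise SD 0.3,
amplitude-drop probability 0.3) probe robustness ordering, on which the
dual moving-average detector dominates all three comparators while every
method degrades measurably relative to clean recordings.

## Numerical choices

* **Zero-phase filtering** is forward–backward application of the designed
  order-2 Butterworth filter (`signal::butter`). Plain forward–backward
  filtering leaves multi-second edge transients at a 0.5 Hz corner, so the
  record is extended by odd reflection over three periods of the lowest
  corner frequency and the filter starts from steady-state initial
  conditions; a constant input then maps to an exactly constant output and
  time-reversal symmetry holds to ~1e-6 relative. Records shorter than the
  padding length are rejected with an explicit error.
* **Window rounding**: millisecond durations convert to samples by
  round-half-away-from-zero; moving-average windows additionally round to
  the nearest odd integer so the window centres on a sample (111 ms →
  41 samples, 667 ms → 245 at 367 Hz).
* **Centered averages with truncated edges**: the moving averages shrink
  their window at the record boundaries instead of padding, fabricating no
  signal content; the slope sum similarly truncates its leading history.
* **Ties** in any argmax resolve to the earliest sample; grid-search ties
  follow the fixed key above — both for determinism, verified by the
  byte-identical pipeline rerun test.
* **First difference** keeps length by defining `out[1] = 0`; the first
  sample never hosts a peak decision.

## Problem sizes

The test suite and the acceptance script use 20-second records at 367 Hz
(7341 samples): 20 clean resting records for the recovery checks, 50
degraded post-exercise records for the robustness ordering, 10 records and
an 80-combination grid for parameter recovery, and property tests over a
few hundred randomised signals. The full suite runs in well under a minute
on one core.

## Limitations

Only systolic peaks are reported — no onsets, dicrotic notches or diastolic
waves. The comparator implementations fill in constants their sources leave
unstated, so they are faithful in structure but not bit-reproductions of
the original codes. Accuracy figures reported for these detectors on
clinical datasets rest on data that is not publicly available and cannot be
reproduced here; what the package's numbers establish is internal: exact
recovery on clean synthetic data and the robustness ranking under
degradation.
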
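---
title: "Methods: template-based field-potential analysis for cardiomyocyte MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-based field-potential analysis for cardiomyocyte MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiofp)
```

## The problem

Micro-electrode arrays (MEA) record extracellular field potentials (FP) from
spontaneously beating cardiomyocyte aggregates. In drug-safety screening the
key readout is the field potential duration (FPD) — the time from the
depolarization onset to the end of the repolarisation wave — which tracks the
ECG QT interval; hERG-channel blockers prolong it. Recordings contain hundreds
of beats with variable noise, occasional arrhythmogenic (e.g. premature)
complexes, and drifting morphology under drug wash-in, so per-beat manual
annotation does not scale.

The analysis implemented here proceeds in two phases:

* **Phase I (averaging):** low-pass filter, detect one depolarization peak per
  beat, cut a fixed window per beat, score every windowed complex against a
  template by lagged cross-correlation, keep the complexes whose coefficient
  reaches a user-set correlation factor (CF), and ensemble-average them into
  one representative waveform.
* **Phase II (measurement):** locate the FPD onset and offset on the averaged
  waveform, and report FPD, the Bazett rate-corrected FPD
  (cFPD = FPD / sqrt(RR) with RR in seconds), the area under the curve between
  the landmarks, and the beating rate. Up to ten averaged waveforms (e.g. one
  per drug concentration) are compared as a peak-aligned overlay.

## Pre-processing

Noise is attenuated with an order-5 Butterworth low-pass at 200 Hz, applied
forward and backward (`lowpass_filter()`). Zero-phase filtering matters
because a causal pass would delay the onset/offset landmarks that the FPD is
computed from; the price is a squared magnitude response (−6.02 dB at the
cut-off), which the tests check against the closed form
|H(f)|² = 1/(1 + (f/200 Hz)^10). `signal::filtfilt` applies no padding, so the
implementation removes the median, pads by odd reflection (about six filter
time constants), filters, and trims; a constant trace passes through exactly.

Beat detection (`detect_peaks()`) is a window-threshold scheme: the trace is
median-centred, the dominant polarity is the sign with the larger extrema, and
local extrema above a threshold are kept subject to a refractory period
(default 200 ms, below the 300 ms beat interval of the fastest plausible
200 bpm preparation), larger peaks winning. The automatic threshold is
k × MAD × 1.4826 (k = 5) — a robust noise scale that ignores the sparse
spikes — **floored at 0.35 × the largest centred deflection**. The floor is
needed on two kinds of traces where a pure noise-scale threshold fails:
nearly noiseless traces (MAD → 0) and heavily averaged or filtered traces
where the repolarisation peak (typically ≤ 25–30 % of the spike amplitude)
would otherwise cross a threshold calibrated only to noise. All three
constants are arguments.

## Correlation analysis

The correlation window is the smallest beat-to-beat interval — long enough to
contain one full complex, short enough not to swallow the neighbour — and each
window is centred on its depolarization peak (`extract_complexes()`). The
template is, by default, the complex nearest the midpoint of the recording;
it can also be picked manually by index (e.g. an arrhythmogenic complex, to
count arrhythmic beats), or as `"dominant"`: the candidate, among a spread of
complexes, with the highest median correlation to a spread of reference
complexes. The dominant mode emulates what an operator does in a drug study —
choose a template reflecting the prevailing morphology — and is what the
package's own validation study uses, since the centre beat of a recording
with 15 % ectopy is itself ectopic every seventh recording or so.

The similarity score (`correlation_coefficient()`) is a lagged product sum.
The classic formulation normalises by 1/N only, which leaves the score
scale-dependent; CF thresholds like 0.88–0.98 presuppose a unit-bounded
score, so the default here is the Pearson-type normalisation (mean-removed,
amplitude-normalised, c ∈ [−1, 1]), maximised over integer lags |n| ≤ 2 ms.
The raw 1/N sum and the uncentred cosine variant remain available
(`method = "raw"` / `"cosine"`). The small lag search absorbs detection
jitter — alignment errors act like a low-pass on the average (the tests
demonstrate that ±1 ms uniform jitter attenuates a 200 Hz component more than
a 50 Hz one) — while a large search could lock onto the neighbouring complex.
Ties resolve to the smaller |lag|, then the negative lag, so results are
deterministic. A zero-variance window is scored undefined and rejected with a
flag rather than aborting the run.

Complexes with c ≥ CF are ensemble-averaged after shifting each by its best
lag; the average shrinks to the common overlap of the shifted windows. The
accepted set is, by construction, monotonically non-increasing in CF, and the
residual noise of the average scales as N^(−1/2) — both are asserted in the
acceptance tests.

### The two-window design

A peak-centred window of one beat interval only reaches RR/2 past the peak,
but at the beating rates of interest (110–135 bpm, RR ≈ 440–530 ms) the
repolarisation ends around 0.8 × RR after the onset, i.e. far beyond RR/2.
Correlation classification and FPD measurement therefore use different
windows: classification keeps the centred min-interval window (where the
spike, the discriminative feature, sits in the middle), and the accepted
beats are then re-extracted on an asymmetric *measurement* window — peak at
15 % of the window, length equal to the smallest interval between
consecutive *accepted* beats — before averaging. Accepted beats whose
measurement window contains any other detected peak (e.g. a trailing
premature complex) are dropped from the average so they cannot write a
foreign spike into it. The pipeline (`average_recording()`) reports both
window lengths in the waveform provenance.

## Onset and offset

**Onset** (`detect_onset()`): scanning forward before the depolarization
peak, the first frame (default 10 ms) whose amplitude excursion (max − min)
exceeds k = 3 × the baseline excursion triggers; the onset is then refined to
the first sample deviating from the baseline median beyond the noise scale.
On a heavily averaged waveform the baseline excursion approaches zero and the
criterion would fire on numerically tiny ripple — including the acausal
pre-ringing that zero-phase filtering spreads ahead of the spike — so the
threshold is floored at 1 % of the waveform's peak-to-peak amplitude. Frame
length, k and the floor are arguments.

**Offset** (`detect_offset_tra()`): the trapezium-area method for locating
the end of a repolarisation (T-like) wave. With the repolarisation peak
(x_i, y_i) and the reference point at the last sample x_r fixed, the moving
vertex (x_m, y_m) maximises

A(x_m) = 0.5 · |y_i − y_m| · (2·x_r − x_m − x_i),

and the earliest maximiser is the offset: past the wave's end |y_i − y_m|
stops growing while the width term keeps shrinking, so the area peaks where
the wave meets the baseline. The moving vertex starts **at the
repolarisation peak** by default. Starting it at the valley after the
activation peak — a plausible alternative reading of the method — degenerates:
for any pre-peak moving point near baseline, |y_i − y_m| already equals the
full wave amplitude while (2·x_r − x_m − x_i) is strictly larger than at any
post-peak point, so the maximum would always sit at the search start and
never at the repolarisation end. That start remains available
(`search_start = "post-spike-valley"`) for waveforms where the geometry
differs. The repolarisation-peak vertex itself is the largest post-valley
deflection *in the direction of the dominant depolarization lobe*; an
absolute-value criterion would land on the valley's own shoulder. A
brute-force evaluation of A over every candidate is the reference behaviour;
the implementation is asserted equal to it on every tested waveform.

**Measurement** (`measure_fpd()`): FPD = (offset − onset)/fs;
cFPD = FPD/sqrt(RR s) (Bazett; the identity at 60 bpm and strict monotonicity
in rate are tested); AUC is the trapezoidal integral of
|amplitude − baseline| between the landmarks, with the baseline taken as the
median of the pre-onset samples (the method needs a baseline convention; the
pre-onset median is robust to the spike and to slow drift). AUC is reported
as an absolute (unsigned) area. Either landmark can be fixed manually
(`manual_landmarks()`, or per-landmark in `analyze_waveform()`); mode flags
record the choice.

## The synthetic-data generator

`synth_recording()` is the test substrate: a deterministic, seeded generator
of MEA-like single- or multi-electrode recordings with exact per-beat ground
truth. Its default conditions are the study conditions everything else is
tested under: 20 kHz sampling, ~120 bpm with small interval jitter, a 200 µV
depolarization spike, a 50 µV repolarisation wave, FPD in the 300–430 ms
range, and additive white Gaussian noise (default 2 µV = 1 % of the spike).

The waveform primitives are chosen for *exact* landmarks rather than
biophysical realism:

* the spike is a Hann-windowed full sine period of 10 ms support — biphasic,
  with the trailing negative lobe scaled to 80 % so the positive deflection
  dominates, as in typical extracellular FPs; the onset is exactly the first
  sample of support;
* the repolarisation wave rises as a raised cosine (120 ms) and returns to
  baseline *linearly* (80 ms), reaching zero exactly at onset + FPD. The
  linear return makes the trapezium-area offset exactly the planted offset:
  at the corner the area derivative flips sign whenever the remaining
  post-corner width exceeds the descent duration, which holds for every
  configuration the package generates.

Premature beats occur with a configurable per-beat probability: a shortened
coupling interval (0.6 × RR, followed by a compensatory pause; never two in a
row) and a morphology compressed in amplitude and in repolarisation timing by
a shape factor (default 0.5). The spike keeps its 10 ms width — compressing
it would merely annihilate it under the 200 Hz low-pass instead of changing
its shape — which also matters for a Pearson-type classifier, since a pure
amplitude rescale would be invisible to it. Gradual morphology drift
(per-beat scaling of the repolarisation amplitude) emulates drug wash-in;
beats whose cumulative drift exceeds 10 % are labelled `"drifted"`.

What the generator does **not** emulate: ionic-current dynamics, electrode
field geometry, correlated or line-frequency noise, baseline wander, and the
diverse real FP morphologies (downward-only, inverted-repolarisation, ...).
Passing tests therefore demonstrate the correctness of the algorithmic chain
under controlled conditions, not field performance on arbitrary recordings.

## Validation framework

`confusion_counts()` / `ppv()` / `sensitivity()` / `specificity()` /
`summarize_validation()` score the classifier against resemblance labels:
TP = resembles and accepted, FP = accepted but does not resemble, TN =
rejected and does not resemble, FN = resembles but rejected. Metrics are
percentages at two decimals; a zero denominator is undefined and rendered as
an en dash. Cross-dataset summaries are macro-averages: per-dataset metrics
computed from the counts at full precision, then the unweighted mean, rounded
once at the end — recomputing the bundled eight-dataset benchmark
(`validation_benchmark("multi_dataset")`) reproduces its published summary
row (96.35 / 99.27 / 94.49 %) only under this convention, which is how the
convention was fixed. One printed sensitivity cell in that benchmark is
arithmetically inconsistent with its own printed counts (99.34 % vs
281/283 = 99.29 %); the counts are taken as authoritative and the cell is
flagged in the bundled table. A few further printed cells differ from their
counts by one unit in the last decimal (mixed rounding/truncation in the
source); comparisons are therefore made at one unit of the printed precision.

## Problem sizes and numerical choices

The packaged validation study (acceptance script and acceptance tests) runs
four 30-second recordings at 20 kHz — FPD/rate pairs (300, 128), (330, 130),
(360, 122), (430, 113) — with 1 % noise and 15 % premature beats, classifying
at CF 0.98 with the dominant-morphology template. Thirty seconds (55–65
beats) gives ensemble sizes of 40–55, where the averaged waveform's residual
noise is well below the landmark detectors' floors; the published studies
used 2-minute recordings, which would only grow the ensembles. Observed
behaviour under these conditions: beat-label agreement 95–98 %, and measured
FPD within 5 ms of the planted value (systematically ~+4 ms: the zero-phase
filter smears the onset a few ms ahead of the planted first sample, while the
trapezium corner moves ~1 ms the other way). The residual disagreement is
real, not noise: at FPD ≈ 0.8 × RR each correlation window contains the tail
of its *predecessor's* repolarisation, so a normal beat directly after a
premature one (whose tail is absent) decorrelates to c ≈ 0.92 and is
rejected — the same false-negative mechanism the published confusion tables
show.

Other conventions: correlations return the earliest/smallest-|lag| maximiser;
template midpoint ties go to the earlier complex; sampling-rate inference
uses the median time-column step and warns above 1 ppm jitter; the ASCII
time unit is auto-detected with a 0.02 threshold on the median step (an
ms-based export has steps ≥ 0.02 ms up to 50 kHz; a seconds-based export at
≥ 1 kHz has steps ≤ 0.001), overridable. Measurement CSVs and
JSON + CSV waveform archives round-trip exactly; the ASCII writer prints
amplitudes at three decimals (1e-3 µV round trip).

## Known limitations

* The onset/offset detectors assume one dominant depolarization deflection
  followed by a single repolarisation wave; multiphasic or
  inverted-repolarisation morphologies may need manual landmarks (supported,
  and flagged in the output).
* The correlation window derives from the smallest beat interval; recordings
  dominated by short-coupled ectopy shrink it, and with FPD close to the
  beat interval neighbouring complexes overlap the window (see above).
* No resampling: waveforms compared in an overlay must share one sampling
  rate.
* Bazett is the only rate correction offered; at rates far from 60 bpm it
  over-corrects, which is why cFPD values at 110–135 bpm sit well above the
  raw FPD.
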
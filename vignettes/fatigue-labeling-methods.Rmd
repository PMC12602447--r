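---
title: "Methods: EEG-driven fatigue labeling of driver physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG-driven fatigue labeling of driver physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Monotonous driving induces mental fatigue. The conventional way to study its
physiological correlates is time-on-task (ToT) labeling: for every driver,
the beginning of the task is called "low fatigue" and the end "high
fatigue". But fatigue does not progress identically across individuals; if a
driver's drowsiest period falls mid-task, ToT labeling dilutes the contrast
between conditions. `fatiguelab` implements the alternative: label each
subject's low- and high-fatigue periods from their own EEG, via a
drowsiness index, and quantify how much larger the low-vs-high contrasts in
independent physiological channels (eyeblinks, heart rate, heart rate
variability) become.

All analysis is restricted to the ~1-min repetitions of the longest straight
road of the driving course, so that every labeled window contains the same
motor activity. Those repetitions are the unit of labeling.

## The MDrow drowsiness index

Parietal alpha power rises as vigilance falls, and is maximal during
eyes-closed rest. The index normalizes task alpha activity to that
individual ceiling:

$$\mathrm{MDrow}(t) \;=\; \frac{\mathrm{GFP}_{\alpha}^{\text{task}}(t)}
 {\max_t \,\mathrm{GFP}_{\alpha}^{\text{rest}}(t)}$$

* **Strict alpha band.** The individual alpha frequency (IAF) is the peak of
  the parietal-averaged Welch spectrum of a 1-min eyes-closed recording,
  searched in 7–13 Hz; the band is IAF ± 1 Hz (narrower than the common
  IAF ± 2 Hz, to keep theta and beta variations out).
* **GFP.** For each retained 1-s epoch, each parietal channel (Pz, P3, P4)
  gets a Hanning-tapered periodogram at 1 Hz resolution; the channel alpha
  power sums the bins inside the strict band, and the epoch's scalar GFP is
  the mean over the three channels. The formula for collapsing channels is
  a design choice (the mean keeps the value interpretable as per-channel
  band power and makes the "identical channels" case collapse to
  single-channel power).
* **Windowing.** The 1-s series is stabilized over 60-s windows advancing by
  15 s, so the output resolution is 15 s. A 45-min task yields
  `floor((2700 - 60)/15) + 1 = 177` windows. Windows retaining fewer than 30
  of their 60 epochs are reported missing rather than estimated from
  artifact-dominated data.
* **Denominator.** The literal maximum over retained 1-s rest epochs. A
  single noisy rest epoch can deflate the entire series, so a robust
  95th-percentile option exists (`rest_stat = "q95"`, off by default).
* **Interpretation.** Values near or above 1 mean task alpha at the
  eyes-closed ceiling: drowsy. The identity `MDrow = 1` when task GFP equals
  the rest maximum is exact in the implementation and is tested as such.

MDrow is a within-subject ratio: it is invariant to any global amplitude
rescaling applied to both recordings, and it is never baseline-normalized
(unlike the other features).

## Preprocessing

EEG (8 channels at 125 Hz: AFz, AF3, AF4, AF7, AF8, Pz, P3, P4) is cleaned
with a 50 Hz notch and a 2–40 Hz band-pass. The cut-offs are given; the
realization is ours: zero-phase (forward–backward) IIR filters — a 2nd-order
notch with Q = 30 and a 4th-order Butterworth band-pass — so that no group
delay distorts blink or alpha timing. Because the two passes square the
magnitude response, the design edges are widened numerically until the
half-power points of the *combined* response sit at 2 and 40 Hz; without
this the effective band would be about 10% narrower than nominal.

The filtered signal is cut into non-overlapping 1-s epochs (a trailing
partial epoch is dropped, never padded) and an epoch is rejected when any
channel exceeds ±200 µV — which is why EEG units are mandatorily microvolts.
Epochs overlapping detected blinks are flagged separately and excluded from
the alpha/GFP computation. This flag-and-exclude policy replaces
template-based ocular-artifact correction: it is conservative and testable,
and the index uses parietal channels where blink contamination is smallest.
ICA is deliberately not used. Rejection is monotone in the threshold and, on
synthetic data, the rejected epochs coincide exactly with the generator's
injected supra-threshold bursts.

## Eyeblink features

Blinks are read from AFz (vertical ocular dipole) on the raw signal — the
2 Hz high-pass would distort blink morphology. The detector: low-pass at
8 Hz; subtract a sliding ±2 s median baseline; rectify after auto-detecting
polarity (the sign of the largest deviation, since montage polarity is not
guaranteed); mark local maxima above 3× a sliding MAD-based noise scale;
enforce 200 ms minimum peak separation; take onset/offset as the nearest
crossings of 10% of peak height (with sub-sample linear interpolation);
discard events outside 50–1000 ms. All five constants are configurable.

Two robustness elements deserve note. First, candidates must stay above the
adaptive threshold for at least the 50 ms duration floor: threshold-grazing
noise excursions exceed a 3-sigma level only briefly, while a genuine blink
at detectable amplitude stays above it for ~100 ms or more; without this
rule the false-event rate of a 3×MAD threshold on band-limited noise is
roughly one per minute regardless of the noise amplitude (the threshold is
scale-free). Second, the amplitude is measured on the raw
baseline-subtracted channel at the detected peak, not on the 8 Hz-smoothed
trace, avoiding the smoothing attenuation.

Blink duration is defined as the width at 10% of peak amplitude — the
detector's onset/offset rule. The synthetic generator uses the same
definition (its raised-cosine pulse is scaled so the 10% width equals the
configured duration), because the sub-10% tails of a smooth bump are not
measurable in noise and any other convention would impose a constant
definitional bias of about 20% on duration recovery.

Per analysis window: EBR = blinks/min (events assigned by peak time,
half-open, so a disjoint tiling conserves counts), EBD = mean duration (ms),
EBA = mean amplitude (µV); EBD/EBA are missing in blink-free windows.
Duration recovery degrades gracefully with noise: at blink SNR 10 the mean
duration error is ~10–15 ms, at SNR 5 the noise-extended crossings add
another ~15–20 ms.

## Cardiac features

Wrist PPG at 64 Hz is band-passed 0.4–4 Hz (zero-phase 5th-order
Butterworth), which removes DC and movement interference and emphasizes the
pulse waves. Beats are located with AMPD (automatic multiscale-based peak
detection): over each 30-s window (advanced by 25 s; a final window anchored
at the recording end covers the tail), local maxima are computed at every
window scale up to half the window, the scale with the most local maxima
sets the cut, and samples that are local maxima at every scale below it are
beats. Window merging deduplicates detections closer than 200 ms at seams —
the merging rule is ours, the windowing is given.

The inter-beat-interval series is corrected in one coherent pass: linear
detrend, flag intervals deviating more than 2 SD from the detrended mean,
replace each flagged interval by the mean of up to two clean neighbours per
side, then smooth with a 5-point centred moving average. The source text is
ambiguous about the detrend/flag/smooth order; one pass in this order is
internally consistent (the SD rule needs the detrended series first).
Correction touches only the IBI series, never the waveform. More than 50%
flagged intervals aborts with an "unusable" error rather than fabricating a
series.

One deliberate separation: the 5-point moving average is kept for
trend-level quantities (heart rate), but spectral HRV is computed from the
outlier-replaced, *unsmoothed* intervals. A moving average over beats is a
low-pass in beat-domain frequency; at ~70 bpm its gain at 0.25 Hz is ~0.07,
which would suppress the HF band almost entirely and inflate LF/HF by an
order of magnitude. Smoothing the spectral input would make the package's
own LF/HF recovery oracle (a 30 ms / 15 ms two-tone modulation must give
LF/HF ≈ 4) unattainable.

HR per 60-s window is `60000 / mean(IBI)` bpm (missing under 3 beats).
Frequency-domain HRV uses the Lomb–Scargle periodogram of the unevenly
sampled IBI values at their beat times — no resampling — on a 0.003–0.5 Hz
grid with 0.0025 Hz spacing; LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz) are
normalized by the total spectral power on the same grid, and HRV = LF/HF.
The grid and normalization are design choices; computing the total on the
same grid keeps the fractions consistent, and `lf + hf <= 1` always. On
evenly sampled input the implementation agrees with the classical
periodogram to machine precision (a tested equivalence). Windows with fewer
than 30 beats yield missing features rather than imputations.

## Labeling and comparison

* **ToT labels**: first *k* straight-road repetitions = Low, last *k* =
  High (default *k* = 2), identical for all subjects.
* **EEG labels**: each repetition is scored by the mean of MDrow windows
  whose centre falls inside it; the top-*k* scores are High and the
  bottom-*k* Low (default *k* = 1 — the wording "the two one-min segments
  … highest and the lowest" reads most naturally as one segment per
  condition; both counts are configurable and the asymmetry against ToT's
  *k* = 2 is recorded in results). Ties break toward the earlier segment
  for Low and the later for High, so a constant series labels the first
  segment Low and the last High. Segments without usable MDrow windows are
  excluded from the ranking with a warning.

Features (EBR, EBD, EBA, HR, LF, HF, HRV) are normalized by subtracting the
feature's value over the first 2 min of the task — a baseline that shares
the task's motor activity. MDrow is exempt (it is already rest-referenced
and comparable across subjects); attempting to normalize it is an error.

The comparison harness computes, per feature across subjects, the paired
High − Low difference; a Shapiro–Wilk check on the differences selects a
paired t-test or a Wilcoxon signed-rank test; the paired effect size is
Cohen's d = mean(diff)/SD(diff); Holm–Bonferroni adjusts the p-value family.
Degenerate inputs are handled explicitly: all-zero differences report d = 0,
p = 1; constant non-zero differences report an infinite-effect sentinel with
a note; features with under 3 pairs are reported as `insufficient_n`, not
tested. Mixed-effects modeling of environment/location factors is out of
scope; those tags ride along as metadata.

## The synthetic-data generator

The generator produces sessions with known ground truth against which every
recovery claim is tested. Defaults mirror the targeted study conditions:
a 45-min task (60 s lead-in, then 8 repetitions of 60 s spaced 270 s), 8
EEG channels at 125 Hz, a 1-min eyes-closed rest, PPG at 64 Hz.

* **EEG** = 1/f-power background noise (spectral shaping of white noise,
  exponent 1, scaled to 10 µV RMS by default) + an alpha tone at the
  subject's IAF whose parietal amplitude is `alpha_task_base_amp` (4 µV) ×
  a fatigue envelope, with frontal channels at 25% of parietal alpha so the
  parietal GFP dominates as the index assumes + raised-cosine blink
  transients (frontal-dominant, AFz largest) at Poisson times (15/min) with
  a 0.5 s refractory gap (a blink cannot begin during the previous one) +
  optional 300 µV artifact bursts placed strictly inside distinct 1-s
  epochs, so the injected supra-threshold epoch count is exact ground truth.
* **Rest** has parietal alpha at `alpha_rest_amp` (20 µV) and no blinks;
  with the default task peak (4 µV × envelope max 3.5 = 14 µV) the rest
  amplitude is the session ceiling by construction, keeping MDrow below 1.
* **Fatigue envelope**: bump (Gaussian, SD 90 s, centred on the surge
  repetition), ramp, or sigmoid; the envelope multiplies the task alpha
  amplitude, and the surge repetition is the ground truth the EEG labeling
  must recover.
* **PPG**: beat times integrate
  `IBI(t) = 60000/hr(t) + 30 sin(2π·0.10·t) + 15 sin(2π·0.25·t)` ms —
  deterministic tones rather than stochastic modulation, so band powers
  have exact expectations (LF/HF = (30/15)² = 4). `hr(t)` is the mean rate
  plus an optional surge (`hr_surge_bpm`) scaled by the normalized fatigue
  envelope, coupling heart rate to the EEG ground truth for the
  label-sensitivity analysis. The waveform is a train of symmetric Gaussian
  pulses (σ = 60 ms) at the beat times; a configurable fraction of beats is
  displaced by ±300 ms (ectopic), displacing the waveform pulse and both
  adjacent ground-truth intervals.
* **Cohorts** derive per-subject seeds deterministically from one master
  seed and draw IAF ~ U(8, 12) Hz, mean HR ~ U(60, 80) bpm, and the surge
  repetition uniformly over the 8 segments.

What the generator does *not* emulate: volume-conducted topographies beyond
fixed channel gains, non-stationary noise, saccades and slow eye movements,
respiration coupling, PPG morphology changes, or motion artifacts beyond
the gross-amplitude bursts and ectopic beats. Passing recovery tests on
this data therefore validates the pipeline's algorithmic correctness and
its behaviour under calibrated noise — not its performance on real road
recordings.

## Problem sizes and numerical choices

The validation suite uses 10-min two-segment sessions for single-module
recovery checks and a 20-subject cohort of full 45-min sessions for the
labeling analyses; IAF recovery uses ten 1-min rests spanning 8–12 Hz.
Spectral estimates use Hanning tapers; Welch segments for IAF are 8 s with
50% overlap (0.125 Hz resolution). Filter edge artifacts are irrelevant at
these durations because all filtering is zero-phase. Degenerate inputs
(flat signals, empty windows, zero rest power, monotone spectra) return
empty results, missing values, or explicit errors — never silent guesses.

## Reading the headline result

On a cohort whose alpha-surge segments are uniform over the task and whose
heart rate rises ~4 bpm with the surge, EEG-driven labeling recovers the
surge repetition for essentially every subject, while ToT labeling can only
agree when the surge happens to fall in the last repetitions (~25% of
subjects). Consequently the paired effect size for heart rate under
EEG-driven labeling exceeds the ToT one by an order of magnitude — the
quantitative form of the claim that individualized EEG labeling is the more
sensitive instrument for early fatigue. `scripts/acceptance.R` recomputes
all of these numbers from scratch.
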
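---
title: "Distress detection from paired wearable heart-rate recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distress detection from paired wearable heart-rate recordings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, assumptions and design decisions behind
`vrdistress`. The package analyses paired recordings from two wearables — a
chest ECG device sampled at 500 Hz and a wrist photoplethysmographic (BVP)
device sampled at 64 Hz — collected during three 4-minute virtual-reality
conditions: a seated baseline, a calm non-interactive scene (NIS), and an
interactive scene (IS) in which scripted startling events occur at 120, 180
and 240 s (the last event ends the trial).

## The detection model

Distress detection is deliberately simple and rule-based. Per device:

1. **Filtering.** ECG: zero-phase FIR bandpass 3–45 Hz, order
   `round(0.3 * fs)` forced even (so the filter is linear-phase by
   symmetry); BVP: zero-phase 4th-order Butterworth bandpass 1–8 Hz, which
   removes respiration-band drift (~0.2–0.33 Hz) while preserving pulse
   rates of 60–180 bpm. Zero phase matters because beat *timing* is the
   measurand; both filters run forward-backward, which doubles the
   effective magnitude order.
2. **Beat detection.** ECG beats via an adaptive-threshold QRS detector in
   the Hamilton tradition (differentiate, rectify, 80 ms envelope,
   detection threshold `noise_avg + 0.3125 * (qrs_avg - noise_avg)` over
   the last 8 classified peaks, 200 ms refractory, search-back at 1.5× the
   running mean RR), followed by template-matching correction: the mean
   ±100 ms beat template is built and each beat is shifted to the lag in
   ±50 ms maximizing the normalized cross-correlation. BVP beats via the
   two-moving-averages scheme of Elgendi (windows 111 ms and 667 ms on the
   clipped-squared waveform, offset coefficient 0.02), returning pulse
   onsets.
3. **Features.** `HR_i = 60 / RR_i` at beat times, 3-sample boxcar
   smoothing, linear resampling onto a shared 4 Hz grid anchored at scene
   start, and non-overlapping 10-s windows (40 samples each; a trailing
   partial window is discarded). Per window: mean HR, and RMSSD computed on
   the successive 4 Hz HR samples in bpm. This is the *literal* successive
   difference of heart-rate values, not the classical RMSSD over NN
   intervals in ms; the two differ, and the package intentionally
   implements the HR-domain variant because the whole chain (smoothing,
   resampling, windowing) operates on the HR signal. Ten-second windows are
   at the short end of ultra-short-term HRV practice; mean HR and RMSSD are
   the two features whose ultra-short-term estimates track longer
   recordings acceptably.
4. **Thresholds and levels.** From the baseline recording, per device:
   `HR_min` = minimum of all baseline 4 Hz samples, `RMSSD_med` = median of
   baseline per-window RMSSD. A window flags on HR when
   `mean HR > 1.3 * HR_min` (strict) and on RMSSD when
   `RMSSD < 0.5 * RMSSD_med` (strict); the distress level is the flag sum
   (0 low, 1 medium, 2 high). Boundary values do not flag. A constant
   baseline gives `RMSSD_med = 0`, a degenerate reference under which RMSSD
   can never flag; the package warns and proceeds.
5. **Event coincidence.** For each IS event at time *t*, the windows
   covering `[t-10, t)`, `[t, t+10)` and `[t+10, t+20)` are inspected. With
   a 240-s recording the event at 240 s retains only its "before" window;
   absent windows count as non-detecting and stay in the denominator of
   three, so the criteria keep their meaning across events. The per-subject
   outcome is the percentage of events detected under the 1/3 and 2/3
   criteria.

Agreement between devices is assessed on the shared 4 Hz grid over the full
scene with no outlier exclusion: per-device SNR
`10 log10(mean(HR^2) / popvar(HR))` (population variance, matching the
"average squared difference from the mean" definition), Pearson and
Spearman correlation, MAE and RMSE with the chest device as reference, and
Bland–Altman analysis of the differences wrist − chest with sample-SD
(n−1) limits `bias ± 1.96 SD`. Cohort-level device contrasts of
distress-level counts use the paired Wilcoxon signed-rank test — statistic
`min(W+, W-)`, zero differences dropped, exact two-sided p by full
enumeration of the signed-rank distribution (ties included) for up to 25
nonzero pairs, tie-corrected normal approximation with continuity
correction beyond — and Cliff's delta with the conventional magnitude
cutoffs 0.147 / 0.33 / 0.474.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| ECG band | 3–45 | Hz | QRS energy band; kills drift and mains |
| ECG FIR order | 0.3·fs (even) | taps−1 | standard order heuristic at 500 Hz |
| BVP band | 1–8 | Hz | pulse band; rejects respiration |
| BVP order | 4 (×2 passes) | — | Butterworth, flat passband |
| boxcar window | 3 | beats | mild smoothing; 6 ms at 500 Hz, 46.88 ms at 64 Hz nominal |
| resample rate | 4 | Hz | pairs devices 1:1 on one grid |
| window | 10 | s | ultra-short-term feature window |
| HR multiplier | 1.3 | — | +30 % over baseline minimum |
| RMSSD multiplier | 0.5 | — | −50 % below baseline median |
| events | 120, 180, 240 | s | IS schedule |
| Bland–Altman k | 1.96 | — | 95 % limits of agreement |

All of these sit in `default_run_config()` and can be overridden per run;
the defaults reproduce the standard settings exactly when untouched.

## The synthetic-data generator

Real paired recordings of this protocol are not publicly deposited, so the
package ships a generator that emulates them; it is first-class, tested
code and defines the study conditions under which the pipeline's
behavioural claims are asserted.

**Ground truth.** Beat-to-beat RR intervals derive from a target heart rate
plus mean-reverting AR(1) Gaussian jitter (`phi = 0.6`), whose amplitude
corresponds to an RR variability of `hrv_sd_ms` at rest (default 40 ms —
an unremarkable resting short-term variability for young adults). Arousal
enters through an envelope `a(t)` in [0, 1]: the target HR is
`resting_hr * (1 + distress_hr_gain * a)` and the jitter amplitude is
scaled by `(1 - distress_rmssd_drop * a)`. Suppressing the *absolute*
jitter models vagal withdrawal and makes the RMSSD ratio under full arousal
equal `1 - distress_rmssd_drop` regardless of the HR level, which keeps the
generator's two knobs aligned with the detector's two thresholds. Defaults
`distress_hr_gain = 0.4` and `distress_rmssd_drop = 0.7` place event
responses safely beyond the +30 %/−50 % detection boundaries; they are
design placeholders for a plausible strong startle response, not estimates
of any study's effect sizes.

**The arousal envelope.** For the interactive scene, `a(t)` is the
pointwise maximum of (a) phasic event-locked responses — linear 2-s ramps
into a 20-s hold after each event — and (b) a tonic task-engagement ramp
rising linearly from 0 at scene start to 1 at scene end. The phasic shape
is a deliberate simplification (a boxcar with ramps is detectable by 10-s
windows without pretending to model autonomic dynamics). The tonic ramp
reflects that the interactive scene is *designed* to escalate — a
problem-solving task under increasingly threatening staging — and it is
what makes distress detectable in the window just before the scene-ending
event at 240 s, whose post-event windows do not exist by construction.
Without a tonic component no post-event response could ever be visible for
that event and the 1/3 criterion could not reach 100 % even with perfect
signals; with it, full event coverage is attainable exactly when the
response parameters clear the detection thresholds.

**Waveforms.** The ECG places a fixed sum-of-Gaussians PQRST template
(R amplitude 1) at each ground-truth beat time — the R apex lands within
one sample of the beat — plus optional baseline wander (0.25 Hz), a 50 Hz
powerline tone, and white noise. The BVP places an asymmetric
systolic-plus-dicrotic pulse template at each beat time delayed by a 250 ms
pulse-transit time. Wrist artifacts are injected on top: transient
high-amplitude motion spikes at a Poisson rate (`artifact_rate_per_min`,
default 1/min) and contact-loss intervals (per-minute probability 0.05,
duration 3–8 s) during which the waveform is replaced by a low-amplitude
noise floor. Injected artifact locations are returned as metadata so tests
can assert detector behaviour inside and outside them. The artifact
defaults were fixed once, by calibrating the generator so that the
cohort-mean HR-domain SNR of the chest channel exceeds the wrist channel by
4–6 dB — the qualitative data-quality gap the pipeline is meant to
exhibit between a clean chest ECG and a motion-afflicted wrist PPG.

**What the generator does not emulate.** Respiratory sinus arrhythmia and
HR/respiration coupling, ectopic beats and arrhythmia, PQRST morphology
variation, amplitude drift from perfusion changes, device clock drift, and
any EDA/temperature/accelerometer channels. Passing tests therefore
demonstrate the pipeline's correctness under controlled cardiac dynamics
and artifact phenomenology, not its field performance on human data.

## Numerical choices and degenerate inputs

* **Zero-phase filtering** pads reflectively (mirror, edge sample not
  repeated) with three filter lengths before the forward and backward
  passes; output length equals input length.
* **DC leakage.** A windowed FIR bandpass of order 0.3·fs with a 3 Hz lower
  edge leaves a few percent of gain at 0 Hz; the taps are mean-subtracted
  to pin an exact spectral zero at DC.
* **Boxcar smoothing** uses the same mirror padding, so a 3-sample window
  leaves a constant series untouched and the interior is the exact centered
  mean.
* **Resampling** holds the nearest beat's HR outside the beat span, so the
  4 Hz grid is total even when the first beat falls after t = 0.
* **Winsorizing.** Instantaneous HR outside 20–250 bpm (possible only
  through artifact-driven false beats) is clipped before smoothing.
* **Windows** are `[k*10, (k+1)*10)` from scene start, restarting per
  scene; an even number of baseline windows takes the mean of the two
  central RMSSD values as the median.
* **Beat-series edge cases.** Flat signals yield empty beat series (not
  errors); fewer than three beats skip template correction with a warning;
  conflicting template shifts within the 200 ms refractory keep the
  higher-correlation beat.
* **Pulse-block amplitude floor.** Candidate Elgendi blocks whose waveform
  maximum is below a quarter of the signal's root-mean-square pulse scale
  are rejected; this suppresses filter edge transients and keeps the
  contact-loss noise floor from producing beats.
* **Event segments** beyond the recording end are marked absent and count
  as non-detecting while remaining in the denominator.
* **Wilcoxon** with all-zero differences raises a degenerate-data error;
  the cohort layer flags that comparison instead of failing the run.

## Design decisions that were genuinely open

* **Onsets versus systolic peaks as the PPG beat anchor.** Onsets are the
  default (`beat_anchor = "onset"`), peaks are available behind the same
  switch; onsets are the sharper fiducial on a clean pulse foot.
* **RMSSD domain.** HR-domain successive differences (bpm) rather than NN
  intervals (ms), for the reasons above; classical NN-interval RMSSD is out
  of scope.
* **Baseline minimum** is taken on the processed, smoothed 4 Hz series —
  making it exactly as artifact-sensitive as the rest of the pipeline. A
  lower-percentile floor could be substituted in a custom configuration by
  preprocessing the baseline series, but is intentionally not a default.
* **Event-window reading.** The three event segments are the before/onset/
  after windows `[t-10, t)`, `[t, t+10)`, `[t+10, t+20)`; an alternative
  reading with overlapping delayed windows exists, but the non-overlapping
  reading keeps segments aligned with the global 10-s grid.
* **Cliff's delta argument order** is `delta(E4, Faros)`, i.e. positive
  delta means the wrist device counts exceed the chest device counts.
* **EDF support** is a minimal 16-bit reader/writer (single-rate signals,
  1-s records) sufficient for round-tripping ECG recordings; it is not a
  general EDF(+) implementation.

## Problem sizes used by the test suite

The behavioural test suite asserts: exact worked examples and hand-derived
values per operation; oracle equivalence of every summary statistic against
brute-force loops on 1000 random vectors; beat recall/precision 1.0
(±25 ms) and window mean-HR recovery within 1.5 bpm (ECG) / 3 bpm (PPG) on
8 clean synthetic subjects; 100 % event coverage under the 1/3 criterion on
the chest channel and zero high-level windows in calm scenes for those
subjects; and, on a 16-subject cohort with default artifacts, strictly more
medium+high windows in IS than NIS on both devices plus the 4–6 dB SNR gap.
These sizes keep the full suite within a few minutes on one core while
leaving the stochastic assertions comfortable margins.

## Known limitations

* The detector inherits every weakness of its thresholds: a noisy baseline
  lowers `HR_min` and raises `RMSSD_med`, inflating false positives — by
  design, since the pipeline is meant to mirror the thresholding approach,
  not improve on it. Threshold fine-tuning is explicitly out of scope.
* RMSSD on 4 Hz-resampled HR mixes beat variability with interpolation
  structure; its absolute values are not comparable to NN-interval RMSSD.
* The synthetic artifact model is phenomenological; SNR, correlation and
  error magnitudes on synthetic cohorts should be read as qualitative, not
  as predictions of any device's field performance.
* Pulse-rate variability versus heart-rate variability differences between
  the two devices are not modelled or assessed.
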
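---
title: "Methods: the stridefiber photometry and locomotion pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the stridefiber photometry and locomotion pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridefiber)
```

# Scope

`stridefiber` analyzes fiber-photometry recordings made during locomotor
behavior and optogenetic stimulation in the mouse striatonigral system:
GCaMP calcium signals or red dopamine-sensor (rDA3m) signals recorded
through an implanted fiber, together with treadmill or open-field velocity
and TTL-timestamped stimulation schedules. It covers normalization of the
fluorescence channels, behavioral segmentation, event-aligned timing
metrics, and stimulation-locked response quantification, plus a synthetic
session generator with exact ground truth that makes every stage testable
without animal data.

# Signal model and normalization

A demodulated recording consists of a signal channel (465 nm excitation for
GCaMP, 560 nm for the red dopamine sensor) and a UV isosbestic reference
(405 nm) that is insensitive to sensor activation but shares motion and
bleaching artifacts with the signal. We model the signal channel as

$$S(t) = B(t)\,[1 + r(t)] + g_s A(t) + \varepsilon_s(t),$$

where $B$ is a slow photobleaching trend, $r$ the fractional sensor
response, $A$ a band-limited motion artifact coupled into both channels
with channel-specific gains, and $\varepsilon$ measurement noise. The
reference carries $B$ and $A$ but no $r$ — the isosbestic contract.

Two normalization dialects are implemented, matching the two recording
situations:

**Behavior mode** (`normalize_behavior_session()`), for locomotion
recordings. Both channels are pre-normalized to $\Delta F/F_0$ with
$F_0$ the running 10th percentile over a 5-s window
(`sliding_percentile_baseline()`), which tracks bleaching and other slow
correlated drifts. The reference $\Delta F/F_0$ is then low-pass filtered
(2nd-order Butterworth, 3 Hz corner, applied forward–backward so it is
zero-phase; the effective attenuation order is therefore doubled), a robust
RANSAC regression of the signal on the filtered reference absorbs the gain
and offset differences between channels, and the transformed reference is
subtracted to give the final $\Delta F/F$. Sessions are z-scored with the
mean and SD of the entire recording.

**Stimulation mode** (`reference_correct_stim()`), for optogenetic-
stimulation recordings where light delivery adds a large offset that a
percentile baseline would chase. Here the raw demodulated reference is
transformed onto the raw signal by the same RANSAC regression; the
transformed reference *is* the baseline $F$, and
$\Delta F/F = (S - F)/F$. There is no percentile baseline and no
pre-filtering in this dialect.

**Quality control** (`qc_session()`). A session is included only when the
maximum $\Delta F/F$ exceeds 1.5 % (enough sensor signal) *and* the
correlation between the final $\Delta F/F$ and the transformed reference
stays below 0.6 (not motion-dominated). The signal-strength threshold is
stated in percent; we interpret the printed value 1.5 as 1.5 % (a ratio of
1.5, i.e. 150 %, would be implausibly large for bulk photometry), and the
threshold is configurable. Zero-variance inputs make the correlation
undefined and exclude the session with an explicit reason.

## Numerical choices

* The $F_0$ window is centered on each sample and truncated at the trace
  edges; centering avoids phase bias in the baseline. Percentiles use
  linear interpolation between order statistics (R type-7), pinned so the
  C++ implementation and the per-sample `quantile()` oracle agree to
  machine precision.
* All analysis windows are half-open $[a, b)$ in seconds, so a boundary
  sample is never counted twice; the single exception is the peak-timing
  search, which includes both boundary seconds ("1 s before and 1 s
  after"). Bout boundaries are reported at the first sample of the new
  state; at 1 kHz sub-sample interpolation would be noise.
* `ransac_lm()` draws candidate lines through random point pairs, scores
  them by inlier count within a residual band, re-fits the consensus set by
  OLS and then re-selects inliers under the refined line until stable.
  Without that local refinement the final fit inherits ~5–10 % slope noise
  from whichever random pair happened to win. The inlier band is 2.5 times
  the consistency-scaled MAD of a preliminary OLS fit's residuals: a 1-MAD
  band leaves the fit underdetermined whenever the residual spread is
  dominated by the signal itself (any nearby line reproduces its own inlier
  set), while 2.5 MAD keeps essentially all clean points — near-OLS
  behavior in the null case — yet still excludes calcium transients and
  stimulation responses, which sit tens of standard deviations out. For
  exactly affine data the MAD is zero, so the band is floored at a tiny
  multiple of the response scale. If no candidate reaches a 25 % inlier
  fraction the function falls back to plain OLS with a warning.
* Zero-phase filtering has edge transients; the referencing regression is
  unaffected in practice, but tests of exact identities exclude roughly one
  corner-period at each trace end.

## Known limitations of the referencing model

* *Errors-in-variables attenuation.* Stimulation-mode referencing regresses
  the signal on a noisy reference. When reference noise is not small
  relative to the spread of the bleaching trend, the fitted slope is
  attenuated by the classical factor
  $\sigma^2_B / (\sigma^2_B + \sigma^2_\varepsilon)$, which bends the
  recovered $\Delta F/F$ by a slowly drifting offset across the session.
  With realistic reference noise (fractions of a percent of $F$) the effect
  is negligible; it matters only for very dim reference channels.
* *Percentile-baseline asymmetry.* In the signal channel the bottom decile
  of an $F_0$ window is drawn from rest samples only (transients elevate
  the in-bout samples), while in the reference channel it is drawn from all
  samples. With a large, slowly varying artifact the two baselines can
  diverge by a fraction of the artifact SD near long bouts. This bounds how
  precisely transient amplitudes survive referencing when the artifact is
  comparable to the transients — one reason the pipeline's own QC rejects
  motion-dominated sessions.

# Behavioral segmentation

Three rule sets, all with strict threshold comparisons (a sample exactly at
threshold belongs to neither class and breaks runs):

* **Treadmill movement bouts** (`detect_treadmill_bouts()`): binarize at
  0.25 cm/s; sub-threshold runs are rest only if longer than 0.8 s, shorter
  ones are absorbed into the surrounding movement; movement periods shorter
  than 0.5 s or with mean velocity below 0.5 cm/s are excluded; a bout's
  onset is the crossing that ends a valid rest period and its offset the
  crossing followed by one, so bouts touching the session edges are not
  scored. The rules do not dictate whether absorption happens before the
  movement filters; we absorb first, because onset/offset are defined
  relative to valid rest periods, and expose the other order as
  `treadmill_rule_order = "filter_first"`.
* **Open-field ambulation bouts** (`detect_ambulation_bouts()`): runs above
  2 cm/s, merged across gaps of at most 0.5 s, kept if longer than 0.5 s.
  Merging precedes the duration filter — otherwise "separated by more than
  0.5 s" would have no effect.
* **Immobility bouts** (`detect_immobility_bouts()`): the same machinery on
  runs of a normalized motion index below 0.02 (the video pixel-change
  proxy; any index normalized to $[0,1]$ is accepted).

Trial state around stimulation (`classify_trial_state()`) requires *every*
sample in the 0.5 s before the anchor to exceed 2 cm/s (ambulatory) or to
stay below 1.5 cm/s (quiescent; small movements allowed); the gap between
the thresholds guarantees the labels cannot overlap. Velocity effects of
stimulation use 1-s means before/after the anchor
(`stim_velocity_change()`), and the 3-min ON/OFF open-field design is
summarized per epoch with velocity ratios normalized to each subject's
prior epoch (`epoch_velocity_summary()`); bouts straddling an epoch
boundary are clipped and counted in the epoch containing their onset so
frequencies stay additive.

# Event-aligned timing metrics

Activity is aligned to locomotion onsets/offsets on the session grid with
no interpolation (`align_to_events()`); events without a full window are
dropped and counted. Three metrics follow:

* **Peak time** (`peak_time()`): argmax of the trial-mean trace within
  ±1 s; ties resolve to the earliest lag.
* **Pre-offset slope** (`offset_slope()`): OLS slope of the trial-mean
  activity against lag over $[-0.5, 0)$ s.
* **Rise time** (`rise_time()`): per trial, baseline is the mean over
  $[-1, -0.5)$ s; a 20-ms window slides from $-0.5$ s in 2-ms steps, and at
  each step the per-trial window means are compared with the baselines by a
  right-tailed paired t-test across trials. A rise is a run of at least 5
  consecutive steps with $p < 0.05$, and the reported time is the center of
  the first window of that run. The search continues past the event to
  +0.5 s: activity that rises only after movement onset (as one of the
  studied striatonigral populations does) would otherwise be undetectable.

**A caution on the rise detector.** Adjacent 20-ms windows stepped by 2 ms
share 90 % of their samples, so the 5 % per-step false-positive rate of the
t-test persists across neighboring steps and short spurious runs are
common: on transient-free sessions the detector reports *some* rise about
three quarters of the time (the calibration test measures this rate and
bounds it at 0.85), independent of signal-to-noise because the t statistic
is pivotal. The run rule alone is therefore not a multiplicity control.
Since a genuine step-like rise produces a run that persists essentially to
the end of the search while noise runs are short, the package selects the
*dominant (longest) sustained run* as the rise by default
(`rise_run_select = "longest"`); with this reading the detector recovers
step onsets within ±10 ms. `rise_run_select = "first"` reproduces the
earliest-run reading instead. Users who need a calibrated null should
raise `rise_consecutive` well above the window/step ratio.

Per-animal aggregation follows the study design: metrics are computed on
each session's trial-mean trace, then summarized across animals; pooling
trials across sessions is available but not the default
(`locomotion_event_metrics()` works per session).

# Stimulation-locked responses

Each trial is cut to $[-5, \mathrm{dur} + 9]$ s around light onset and its
own 5-s pre-onset mean is subtracted (`extract_stim_trials()`), making all
metrics invariant to constant offsets. Three offset-anchored quantities
follow, with suppression negative by convention:

* **Initial elevation**: mean $\Delta F/F$ over 0.5–1 s post-onset — the
  transient dopamine surge seen when movement-promoting striatonigral
  neurons are stimulated.
* **Maximal reduction**: minimum over the 1 s before light offset — peak
  suppression. On noisy trials the windowed minimum is biased low (an order
  statistic); `stim_response_summary(mean_trace = TRUE)` computes the
  metrics on the per-duration mean trace instead, trading that bias for
  fewer observations. Both modes are reported in tests against a
  brute-force Monte-Carlo oracle of the same order statistic.
* **Post-stimulation change**: mean over 4–9 s after offset — the rebound
  phase that follows release from inhibition.

Trials of different durations (2/5/15 s) are summarized separately, since
all windows are offset-anchored.

# The synthetic generator

`synth_config()` fixes the study conditions; the generator's defaults *are*
those conditions and the tests run at them:

* 1 kHz sampling (analyses in the test suite mostly run at 100–500 Hz to
  keep the suite fast; every algorithm is rate-agnostic and the unit tests
  pin the sample-exact behavior);
* bleaching from $F = 1$ toward 0.7 a.u. with a 600-s e-fold, shared by
  both channels (reference scaled to 0.8);
* double-exponential transient kernel (rise 50 ms, decay 500 ms) as a
  GCaMP8s stand-in, amplitude 0.06 a.u. (~7.5 % $\Delta F/F$ at peak,
  realistic for locomotion transients), placed at bout onset plus a signed
  lag (default −150 ms: activity leads movement);
* a pre-offset activity trend of either sign: a ramp rising to 0.02 a.u. at
  offset (+1) or an elevated level decaying to zero at offset (−1). The
  trend never dips below baseline — fluorescence reports spiking activity,
  and a sub-baseline dip would also collide with the percentile baseline's
  lower decile;
* a shared motion artifact: Gaussian noise band-passed to 0.8–2.2 Hz,
  SD 0.014 a.u., coupled with gains 1.0 (signal) and 0.9 (reference).
  Motion artifacts are band-limited jerks: power near DC is
  indistinguishable from bleaching (and is absorbed inconsistently by the
  percentile baselines of a transient-bearing vs a transient-free channel),
  while power near or above the 3-Hz reference filter corner cannot be
  cancelled by construction. The band is the regime the referencing method
  is designed for;
* bout-structured velocity: rest jitter capped at 0.12 cm/s (below half
  the movement threshold, so segmentation ground truth is unambiguous),
  raised-cosine on/off ramps, in-bout velocity floored at 0.3 cm/s,
  Poisson onsets at 1 bout/min (head-fixed mice walk in sparse, slow
  bouts; the habituation criterion of the treadmill assay implies at least
  one bout per minute) with gamma-distributed durations (mean 2 s,
  floor 0.8 s) and plateau velocity around 3 cm/s;
* stimulation responses: elevation boxcar over 0.3–1.2 s post-onset, a
  linear suppression ramp starting at 1.5 s reaching $-$`suppression_amp`
  exactly at offset, and an exponential rebound strictly after offset. The
  ground truth includes the noiseless expectation of each analysis window
  computed directly from this shape on the sampling grid, so recovery tests
  compare against closed forms (the sampled exponential's window mean is a
  geometric series, exact to machine precision);
* per-channel Gaussian noise (default 0.003 a.u.); the reference channel's
  noise can be set independently (`ref_noise_sd`) because rig noise does
  not scale with biological effect size.

Determinism: every generator draws a fixed number of variates in a fixed
order, so two runs with the same seed that differ only in a gain (for
example `motion_amp = 0`) share their noise and transients exactly —
matched-pair comparisons with and without artifact are therefore possible.
`simulate_photometry()` and `simulate_stim_session()` offset the seed by +1
and +2 relative to `simulate_locomotion()` to keep the streams independent.

What the generator does *not* emulate: sensor saturation and
nonlinearities, hemodynamic contamination, spiking statistics, video
tracking noise, or lock-in demodulation artifacts. Passing tests show the
pipeline recovers what this generative model encodes — they do not certify
performance on pathologies the model omits.

# Test and verification design

Every detector is checked boundary-exactly against an independent
exhaustive-scan implementation on random square-wave traces that avoid
exact-threshold samples (200 traces of up to 60 s at 100 Hz), and against
the generator's ground truth on noiseless sessions. The sliding-percentile
baseline is compared per sample with `stats::quantile()`. The sliding
t-test is cross-checked against `stats::t.test()` at every step. Timing
metrics are validated by parameter recovery: step onsets at −150 ms and
+80 ms (40 trials, 1 z-unit step, 0.3 z-unit noise, 100 replicates each)
must be recovered within ±30 ms in at least 90 % of replicates, slope signs
(±0.53/−0.35 z/s) in at least 95 % of 200 replicates. Artifact removal is
verified on 50 matched session pairs (240 s at 100 Hz): the pre-correction
signal must correlate with the artifact above 0.8, the corrected trace
below 0.1, and session-mean transient peaks must agree with the
artifact-free run within 10 %. Stimulation amplitudes are recovered over a
3×3 suppression × rebound grid, noiselessly within 10 % and, with 10 noisy
trials per cell, within sampling error assessed jointly across the grid
(a per-cell two-standard-error gate would fail about one cell in twenty by
construction). The 1000-replicate null calibration of the rise detector
reports its false-detection rate against the documented 0.85 ceiling.
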
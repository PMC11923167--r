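# stridefiber

Analysis of fiber-photometry recordings made during locomotion and
optogenetic stimulation — the recording setting used to dissect how
striatonigral (direct-pathway) neuron subtypes start and stop movement and
shape dopamine release. The package takes demodulated sensor fluorescence
(GCaMP calcium or red dopamine-sensor signals with a 405-nm isosbestic
reference), treadmill or open-field velocity, and TTL stimulation schedules,
and produces normalized traces, behavioral bouts, event-aligned timing
metrics and stimulation-locked response amplitudes. A synthetic session
generator with exact ground truth makes the whole pipeline testable without
any animal data.

## What it computes

**Normalization.** Two isosbestic-referencing dialects. For locomotion
recordings: ΔF/F₀ with F₀ the running 10th percentile over a 5-s window on
both channels, zero-phase Butterworth filtering (3 Hz) of the reference,
RANSAC regression of signal on reference, and subtraction of the
transformed reference, i.e.

  ΔF/F = S/F₀ˢ − 1 − (a·LP[R/F₀ʳ − 1] + b),

followed by whole-session z-scoring and quality control (include only
max ΔF/F > 1.5 % and signal–reference r < 0.6). For stimulation
recordings: F = a·R + b fit by RANSAC on the raw demodulated traces,
ΔF/F = (S − F)/F.

**Behavioral segmentation.** Treadmill movement bouts (0.25 cm/s threshold,
0.8-s rest rule, 0.5-s / 0.5-cm/s movement filters), open-field ambulation
bouts (>2 cm/s, >0.5 s, merged across gaps ≤0.5 s), immobility bouts
(motion index <2 %), ambulatory/quiescent trial states (all samples >2 or
<1.5 cm/s in the 0.5 s before a stimulation anchor) and 1-s pre/post
velocity changes; 3-min ON/OFF epoch summaries with velocity ratios
normalized to each subject's baseline epoch.

**Event-aligned metrics.** Peri-event matrices, peak time (argmax of the
trial-mean trace in ±1 s), pre-offset slope (OLS over −0.5..0 s), and
rise-time detection by a 20-ms sliding window stepped 2 ms, tested against
the −1..−0.5 s baseline with a right-tailed paired t-test across trials
(rise = 5 consecutive steps at p < 0.05).

**Stimulation responses.** Per-trial baseline subtraction (5 s pre-onset),
initial elevation (0.5–1 s post-onset mean), maximal reduction (minimum in
the 1 s before offset) and post-stimulation change (4–9 s post-offset
mean), summarized per stimulation duration.

## Worked example

Simulate a 5-minute head-fixed treadmill session in which neural activity
leads locomotion onset by 150 ms and decays into locomotion offset, then
run the full pipeline:

```r
library(stridefiber)

cfg <- synth_config(duration = 300, rate = 100, event_lag = -0.15, seed = 42)
sim <- simulate_treadmill_session(cfg)

nt <- normalize_behavior_session(sim$bundle$photometry, seed = 42)
nt
#> <normalized_trace> behavior_mode, 30000 samples, max dF/F 8.8%
#>   QC: included (max dF/F 8.80%, r = 0.024)

bouts <- detect_treadmill_bouts(sim$bundle$behavior)
bouts
#> # A tibble: 6 × 5
#>   onset offset duration mean_velocity kind
#>   <dbl>  <dbl>    <dbl>         <dbl> <chr>
#> 1  32.2   33.6    1.32           2.41 movement
#> 2 102.   103.     0.970          1.25 movement
#> 3 147.   149.     1.59           3.05 movement
#> 4 154.   155.     1.85           1.92 movement
#> 5 178.   179.     1.52           3.88 movement
#> 6 208.   211.     2.57           3.28 movement

locomotion_event_metrics(nt$zscore, nt$t, bouts)
#>   n_bouts onset_peak_time onset_rise_time offset_peak_time offset_slope
#> 1       6            0.03           -0.14            -0.92       -2.627
```

The session passes quality control (strong signal, low residual
correlation with the reference). Six walking bouts are segmented; their
boundaries match the generator's ground truth sample-for-sample. Activity
rises 140 ms *before* locomotion onset (ground truth −150 ms, recovered
within one detector step), peaks right at onset, and the negative
pre-offset slope (−2.6 z/s) reflects the simulated decay of activity into
movement offset.

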
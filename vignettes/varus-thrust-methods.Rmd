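---
title: "Quantifying varus thrust from IMU gait data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying varus thrust from IMU gait data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varusthrust)
```

## The measurement problem

Varus thrust is a transient lateral excursion of the knee in the frontal
plane during early weight acceptance, common in medial knee
osteoarthritis and associated with knee adduction moments, radiographic
progression and pain. Observational rating by a therapist is binary and
subjective; optical motion capture is accurate but expensive and slow to
set up. A shank- or thigh-mounted IMU senses the impact that the thrust
transmits to the skeleton directly, as mediolateral (ML) acceleration in
early stance.

The catch is that impact acceleration also grows with how fast the limb
is moving: a brisk walker without thrust can show the same raw ML
acceleration RMS as a slow walker with marked thrust. The index computed
here therefore divides the stance measurement by a swing-speed
surrogate:

* **stRMS** — RMS of the raw ML acceleration over the *first half of the
  stance phase* (heel contact to mid-stance), the window in which the
  thrust occurs. No mean removal: the index is defined on the extracted
  signal as measured, so a quasi-static gravity projection on the ML axis
  is retained. A `demean` flag exists for sensitivity analyses and is off
  by default.
* **v-swRMS** — RMS of the 20 Hz low-passed angular velocity over the
  swing phase, per plane (sagittal, frontal, horizontal).
* **A-RMS = stRMS / mean(v-swRMS of the 3 planes)**, in m/s/deg. Degrees
  are never converted to radians; the unit follows the index's
  definition.

`varus_thrust()` runs the whole chain and returns a classed object;
`compute_subject_result()` exposes the index layer given externally
derived events. Events always come from the tibial sensor — femoral
indices reuse the tibia-derived stride windows, with the femoral
recording indexed by the same timestamps (the two sensors are assumed
pre-synchronized; per-file clocks are not re-aligned).

## Event detection

The source description of the index names the channels (heel contact
from vertical tibial acceleration, toe-off from anteroposterior tibial
acceleration) but delegates the algorithms to prior literature without
equations. The committed interpretation here, validated against the
synthetic generator's ground truth rather than against any one prior
paper, is:

1. **Stride period** `T`: lag of the highest autocorrelation peak of the
   mean-removed VT signal within 0.6–2.5 s. A normalized autocorrelation
   below 0.2 in that whole range is treated as "no periodic gait".
2. **Heel contacts**: peaks of a 10 Hz zero-phase low-passed copy of VT,
   kept if their topographic prominence is at least 0.5 times a robust
   stride-scale amplitude (median per-window peak-to-trough over windows
   of length `T`) and separated by at least `0.7 T`. The threshold is
   data-relative, which makes detection invariant to rescaling the
   signal.
3. **Toe-offs**: within each heel-contact interval, the
   largest-magnitude extremum of the 10 Hz-filtered AP signal in the
   40–80 % sub-window. Any plausible stance fraction (the gate accepts
   0.35–0.85) places the push-off feature inside this window.
4. **Stable strides**: the first two and last two complete strides are
   discarded; among the rest, the first run of `n_strides` (default 10)
   consecutive strides whose durations are within ±15 % of the median
   and whose stance fractions lie in (0.35, 0.85) is retained, and every
   candidate's accept/reject reason is logged. Whether the original
   protocol pooled ten consecutive or ten hand-picked strides is
   unknowable from its description; the consecutive-run rule was chosen
   for determinism, not inferred.

All thresholds live in `thrust_control()` with these defaults.

Numerical conventions: an event time is the timestamp of the extremal
*sample* — at 200 Hz, sub-sample interpolation would add precision below
the method's noise floor. Phase windows are half-open
(`start <= t < end`), so the first half of stance and the swing phase
partition cleanly without double-counting; a stride whose window would
contain fewer than 4 samples is rejected. Acceleration is **never**
low-pass filtered before the RMS (the filter applies to angular velocity
only, and to the separate detection copies of VT/AP); the impact content
of ML acceleration is the very quantity of interest.

## Filtering

All filtering is a 4th-order Butterworth applied forward–backward
(`lowpass_filter()`), so the phase response is zero and event timing is
not shifted. Because a forward–backward pass has no initial-state
conditioning, the signal is extended at both ends by odd (point-symmetric)
reflection before filtering; the pad length scales as `9 * rate/cutoff`
samples, long enough for the start-up transient to decay below 1e-9 at
the default cutoffs. Signals shorter than the minimum pad raise an error
that names the minimum length.

## Aggregation across strides

How the ten per-stride values become one subject value is genuinely open
in the index's description. The default, `mean_of_strides`, computes
A-RMS per stride and averages the ten values, preserving stride-level
variance for diagnostics (visible in `summary()`); `pooled_samples`
concatenates all stance-half samples and all swing samples first and
computes a single ratio. Both are implemented; tests pin their exact
semantics and their near-agreement on clean gait.

## The synthetic generator

No recording of the original cohort is available, so
`generate_recording()` emulates treadmill walking with known ground
truth. Shapes are stylized, not biomechanically fitted — the acceptance
surface is event-timing recovery, homogeneity and monotonicity of the
index, and statistical-layer recovery, not waveform realism:

* VT: a Gaussian impact transient (σ = 18 ms) centred exactly at each
  heel contact, over a 9.81 m/s² gravity offset;
* AP: a biphasic push-off feature whose dominant lobe is centred exactly
  at toe-off;
* ML: a half-sine thrust pulse spanning the first half of stance with
  peak `thrust_amplitude_ms2`, over a 0.5 m/s² gravity projection;
* angular velocity: half-sine swing envelopes, sagittal dominant with
  frontal/horizontal at 25 % amplitude, scaled by `swing_speed_scale`;
* noise: white Gaussian per channel, low-passed at 30 Hz (approximating
  sensor plus soft-tissue noise while keeping events detectable);
* femur: the tibial gait shapes at 70 % amplitude with independent
  noise.

Because the speed–impact coupling is the entire reason the adjusted
index exists, the acceleration amplitudes are multiplied by
`swing_speed_scale^speed_coupling` (default exponent 1):
`thrust_amplitude_ms2` is therefore a *speed-normalized* thrust, the
quantity A-RMS is designed to recover.

These shapes give closed forms used as oracles in the tests: noise-free,
`stRMS = sqrt(g0^2 + A_eff^2/2 + (4/pi) g0 A_eff)` for pulse peak
`A_eff` on offset `g0`, and `mean v-swRMS = 0.5 V s / sqrt(2)` for
sagittal peak `V` and scale `s`.

**Calibration.** Defaults were solved analytically from the published
two-group summary statistics (16 knee-OA, 16 healthy) before any
pipeline test was run, and are treated as fixed study conditions:
healthy-like normalized thrust 2.2 m/s² and sagittal peak 246 deg/s put
stRMS near 2.0 m/s² and A-RMS near 0.023 m/s/deg at scale 1; the OA
group of `cohort_config()` combines a larger normalized thrust (mean
2.92) with a slower swing (scale 0.61, consistent with the groups'
reported walking speeds), reproducing the published pattern in which raw
stRMS is slightly *lower* in OA while A-RMS is clearly higher. Group SDs
(1.00 / 0.65 on thrust, 0.09 / 0.13 on swing scale) were set from the
sensitivity of log stRMS to the thrust amplitude so that the relative
spread of A-RMS matches the published ~20–30 %.

What the generator does **not** emulate: soft-tissue wobble and sensor
mounting artefacts, asymmetric or turning gait, the femur's empirically
*higher* A-RMS (the 70 % femur scaling cancels in the ratio), stride-time
drift, and any severity gradation of thrust. Passing tests therefore
demonstrate correctness of the algorithms under controlled conditions,
not clinical validity on real patients.

## Statistics layer

* **ICC(1,1)**: one-way random-effects, single-measurement form,
  `(BMS - WMS) / (BMS + (k-1) WMS)` with k = 2, computed from the n×2
  mean squares; negative estimates are reported as-is with a printed
  note, never truncated.
* **Cohen's d**: pooled SD with the `n1+n2-2` denominator, reported
  unsigned. Recomputing the published comparison table with this variant
  reproduces all four printed effect sizes within rounding of the
  printed inputs (`reproduce_reference_stats()`), which supports — but
  cannot prove — that this was the variant used.
* **t-tests**: pooled-variance Student form, two-sided, available from
  raw samples or from printed mean/SD/n summaries; no multiple-testing
  correction, matching the original analysis.
* **ROC**: thresholds at midpoints between consecutive distinct pooled
  values plus ±Inf sentinels; trapezoid AUC, which equals the
  Mann–Whitney U/(n1·n2) with ties counted 0.5 (asserted to 1e-12 in the
  tests). Youden-maximal ties break toward larger specificity, then the
  smaller threshold — deterministic, and conservative about false
  positives for a screening index. All-identical inputs yield AUC 0.5
  with a `degenerate` flag rather than an error.
* **Binormal AUC**: `pnorm(|m1-m2|/sqrt(s1^2+s2^2))`, the closed-form
  consistency check connecting printed group summaries with printed
  empirical AUCs.
* **Standardized-β OLS**: z-scored outcome and predictors via
  `stats::lm`, binary groups coded 0/1 before scaling.

## Problem sizes in the test suite

The suite generates everything at run time: single trials of 14–20
strides (~16–24 s at 200 Hz), a 50-seed sweep for event-recovery rates,
40 single-session subjects for the adjustment-efficacy property, and
20-seed sweeps of 16- or 32-subject single-session cohorts for the null
and separation calibrations; ICC recovery uses n = 500 simulated
subjects and the AUC identity 1,000 random small instances. These sizes
keep the full suite under two minutes on one core while leaving the
statistical margins comfortable.

## Known limitations

* The event-detection thresholds are validated against the generator,
  not against the prior papers the original description cites; on real
  pathological gait (shuffling, festination, severe asymmetry) the
  prominence and stance-fraction gates may need retuning via
  `thrust_control()`.
* Recordings from the two sensors are assumed time-synchronized; no
  cross-sensor alignment is attempted.
* A-RMS is validated as a discriminator of thrust presence; nothing here
  establishes it as a severity scale.
* The CSV dialect stores explicit timestamps so dropped samples are
  detectable, but the pipeline itself assumes regular sampling between
  events; heavily gapped recordings should be repaired upstream.
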
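---
title: "Models and methods behind atriosync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind atriosync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

atriosync analyses paired sinus-rhythm recordings — surface lead II and one
bipolar coronary-sinus (CS) channel — around the three stages of a
pulmonary-vein ablation procedure (before ablation, after isolation of the
left veins, after the full procedure). This vignette explains the generative
model of the synthetic cohort, the feature definitions, the statistical
machinery, and the numerical decisions, in enough detail that a maintainer
can judge what a passing test suite does and does not establish.

## The generative model

Each patient × phase pair of recordings is built from one **master beat
schedule**: inter-beat intervals follow a stationary AR(1) process
(default mean 800 ms, marginal SD 50 ms, lag-1 coefficient 0.6, floored at
200 ms), capturing the autocorrelated heart-rate fluctuation of sinus
rhythm. Both channels see the same heartbeats: each channel's activation
peak is the master time plus a fixed conduction delay (40 ms for the CS
channel) plus independent Gaussian **fiducial jitter** per beat.

Durations are coupled on the **cycle-fraction scale**. For beat *i* the
channels draw a bivariate-normal pair of *normalized durations*
(n~p,i~, n~l,i~), expressed in ms at a reference cycle of 1000 ms
(defaults: 150 ± 15 ms for the P-wave, 100 ± 10 ms for the CS wave,
cross-correlation `rho_duration` = 0.7). The *measured* duration is

> D~ch,i~ = n~ch,i~ × IBI~ch,i~ / 1000,

with the channel's **own** measured inter-beat interval. Heart-rate
adjustment (multiplication by sf~i~ = 1000/IBI~i~) is therefore the exact
inverse of the generative distortion: it recovers the normalized duration
up to sample quantization. This is the minimal model in which heart-rate
fluctuation masks a morphology coupling and rate adjustment unmasks it —
the mechanism the package exists to analyse.

Two regimes of the jitter parameter matter:

* **default 10 ms** — ordinary delineation noise on curated recordings.
  Here the *shared* heart-rate fluctuation dominates, so raw durations of
  the two channels correlate *above* the latent coupling; adjustment strips
  the shared rate component and reports the intrinsic morphology coupling.
* **30–40 ms** — strongly fluctuating fiducials, as on intracardiac
  channels during radiofrequency delivery. Each channel's interval noise is
  private, the raw product n × IBI decorrelates, and the adjusted values
  recover the latent coupling. This is the regime of the unmasking
  property checks (latent ρ = 0.7, recovered median within ±0.07).

**Ectopic beats** are premature: a beat is made ectopic (probability
`ectopic_rate`, hard-capped at 4 % of beats) by shortening its preceding
interval by `ectopic_shortening` (default 30 %) and shifting the rest of
the schedule earlier — there is no compensatory pause, so exactly one
interval deviates per event. Ectopic morphology is attenuated (duration
× 0.8, amplitude × 0.7) in both channels, since ectopy is a property of the
heartbeat, not of one sensor.

**Phase effects** are multiplicative: during energy delivery the mean
interval rises 8 % and interval variability 60 %, durations stretch 5 %;
after the procedure variability falls to 60 % of baseline and durations and
amplitudes shrink ~8–10 %. The per-patient *random* component
(`phase_effect_sd`, log-normal, default 0.08) applies to the duration
effect and is shared between channels; it is the across-patient variance
that the ablation-transition correlation detects. The rate effects are
deterministic per phase: a per-patient random heart-rate response would be
shared between the two channels and would therefore inflate the raw
transition correlations with variance that adjustment removes — keeping
them deterministic lets the transition tables isolate the duration effect.

**Waveforms** are rendered at 1 kHz: P-waves as nonnegative raised-cosine
humps (maximum amplitude equals peak-to-peak, slope rates positive), CS
waves as biphasic derivative-of-Gaussian wavelets (sign-alternating,
peak-to-peak twice the positive lobe), plus a power-line sinusoid, baseline
wander (0.2 Hz sinusoid and a scaled random walk), and white noise. The
generator emits exact onset/peak/offset annotations alongside.

What the generator does **not** emulate: ventricular activity (QRS/T) and
its cancellation, f-waves or any non-sinus rhythm, multi-lead surface
geometry, torso volume conduction, catheter motion, or the CS-channel
selection problem of real multi-electrode recordings. Passing tests
demonstrate correctness of the analysis pipeline under the stated model,
not clinical performance on hospital recordings.

## Preprocessing

* **Power-line removal**: second-order IIR notch (unity gain at DC and
  Nyquist, 2 Hz bandwidth) applied forward–backward, giving ≥ 40 dB
  rejection at the line frequency with no phase distortion of fiducials.
* **Baseline wander**: second-order Butterworth high-pass, 0.5 Hz default,
  forward–backward.
* **Ectopic detection** operates on intervals: beat *i* is flagged when its
  preceding interval deviates more than 20 % from the median of the 11
  surrounding intervals. Sinus fluctuation stays well under that threshold
  (≈ 5 SD away at the default configuration) while a 30 % premature beat
  exceeds it, giving sensitivity ≳ 0.98 at false-positive rates ≲ 10⁻³.
* **Interpolation** of flagged beats happens at the *feature-sequence*
  level (linear between unflagged neighbours), never on raw samples; the
  adjusted features are recomputed from the interpolated raw features so
  the HRA identity survives interpolation. When the two channels carry the
  same beats the pipeline interpolates the union of their flags.
* **Delineation** (stand-in for curated annotations): local isoelectric
  line estimated as the straight line through the medians of the outer
  thirds of a ±150 ms window; peak refined to the rectified extremum; onset
  and offset at the outermost crossings of 5 % of the peak-to-baseline
  range on a 16 ms moving average, bridging sub-threshold gaps up to 15 ms
  (so the centre zero crossing of a biphasic wave does not truncate it);
  the edge is then walked down the remaining tail — on the raw samples
  (with a minimum per-step decrement of 0.1 % of range, which stops the
  walk on residual drift) when the noise floor is negligible, or on the
  smoothed envelope down to its estimated noise floor otherwise. The noise
  floor comes from the median absolute successive difference, which smooth
  waves barely contribute to. On noise-free signals the recovered duration
  is exact to 1–2 samples; at 20 dB recording SNR the median absolute
  duration error is ≈ 6 ms.

## Features and rate variability

Definitions follow the field's conventions: duration = offset − onset;
`ampmax` is the maximum *signed* sample (equal to peak-to-peak only for
positive monophasic waves — deliberately not rectified, so biphasic CS
waves report their positive lobe); RMS over the annotation window;
positive area by the trapezoidal rule after clipping negatives; slope
rates between onset and the round-half-up sample at 5/10/20 % of the
duration or the peak, in mV/ms (a degenerate zero-width point advances one
sample). SDNN uses the sample (n − 1) standard deviation, the HRV
convention; VARNN is stored as SDNN² so the identity is exact by
construction. The first activation of a recording has no interval, carries
undefined adjusted features, and is excluded from pairwise statistics
rather than borrowing a neighbouring interval.

## Statistics

* **Per-recording Pearson correlation** between matched beat series
  (one-to-one nearest-peak matching within ±200 ms after subtracting the
  median inter-channel delay). Cohort cells are aggregated by the
  **median**; the mean is used only when the cohort has at least 8
  recordings *and* the values pass the Shapiro–Wilk gate at α = 0.05.
  p-values are combined with the same centring rule — the combination rule
  for per-recording p-values is genuinely underdetermined, and the median
  was chosen for symmetry with the correlation rule (Fisher combination
  was considered and rejected as it answers a different question).
* **Cross-validated regression**: folds by seeded random permutation with
  near-equal sizes; R² computed once on pooled out-of-fold predictions
  (lower variance than averaging per-fold R² at ~300 beats), adjusted for
  the single predictor, floored at zero before conversion to percent
  (cross-validated R² is negative for anti-predictive fits; the tables are
  nonnegative percentages). The reported p-value is the full-data slope
  t-test, which for simple regression is algebraically the Pearson test —
  the package computes it through the same routine so the equality is
  exact.
* **Ablation-induced variation**: per patient and feature,
  CV = (median~after~/median~before~ − 1) × 100 over a phase transition;
  rate-variability features contribute their single per-recording value.
  Patients with a zero before-median are excluded with a warning. CV pairs
  are correlated across patients per feature and transition.
* **Significance**: α = 0.05 everywhere, no multiple-testing correction
  (flagged in the report metadata); per-recording vs pooled-activation
  phase correlations are both available (`pooled = TRUE`), per-recording
  being the default.

## Cross-quadratic sample entropy

Both series are z-scored (n − 1 SD); the tolerance r applies on the
normalized scale and is **not** rescaled again. Template distance is
Chebyshev (the sample-entropy standard), a distance exactly equal to r
counts as a match, and the match probabilities deliberately average over
the first N − m (and N − m − 1) templates so the m and m + 1 counts share
index ranges. The value −ln(A^{m+1}/A^m) + ln 2r is undefined (returned as
`NA`, never ±∞) when either probability is zero; undefined values are
excluded from medians and counted. Defaults m = 1, r = 0.35 are fixed
configuration, not fitted. The + ln 2r correction makes the value stable
in r: on independent noise, recomputing at r = 0.2 vs r = 0.35 moves the
value by < 0.1, and the independent-Gaussian limit −ln erf(r/2) + ln 2r
(≈ 1.276 at r = 0.35) serves as the external reference point: entropy of
coupled series falls below it. The O(N·M) counting loop is compiled (Rcpp);
the test suite checks it against a literal R double-loop enumeration to
10⁻¹².

## Seeds and reproducibility

One master seed spawns per-patient, per-phase child seeds through a fixed
affine map (`child_seed()`), so any recording can be regenerated in
isolation; fold assignment seeds derive from the same map. All simulation
entry points restore the caller's RNG state. Two runs of
`run_study()` + `render_report()` with the same configuration and seed
produce byte-identical CSVs (no timestamps enter any output).

## Problem sizes used in validation

The test suite exercises the full rendered pipeline on small cohorts (2–3
patients × 40 beats), statistical properties on annotation-only cohorts of
8–40 patients × 100–300 beats, and the entropy oracle on series of length
60–100; the cohort-scale validation script uses 40 patients × 300 beats ×
20 seed replicates for the unmasking and null-calibration checks and
series of length 5000 for the Gaussian entropy limit. The null-calibration
cohort switches off every shared component (duration coupling, interval
variability, patient-level phase effects, ectopy) because each of them
couples the two channels by construction; with them removed the observed
significant fraction sits at the nominal 5 %. One residual caveat: the
adjusted-duration series are i.i.d. under this null, but the raw duration
series inherit a small negative lag-1 autocorrelation from the fiducial
jitter (an MA(1) component in each channel's intervals), and the Pearson
test is exact only for serially independent pairs — so raw-duration cells
run a few tenths of a percent liberal. This is a property of the test
under autocorrelated physiology, not an implementation defect.

## Known limitations

* The delineator is a stand-in for curated expert annotations; its error
  model (and the 20 dB figure above) refers to the synthetic morphologies.
* Aggregated p-values (median across recordings) describe the typical
  recording, not cohort-level evidence; no correction for the number of
  feature × phase cells is applied.
* CQSE on ~300-beat series carries noticeable small-sample bias; values
  are comparable within this package's settings (m, r fixed), not across
  different r without the ln 2r convention.
* The ablation-transition correlations hinge on the per-patient shared
  duration effect in the generator; with only 40 patients their sampling
  error is large, which mirrors the practical situation.
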
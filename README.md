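# atriosync

Tools for the paired analysis of surface P-waves (ECG lead II) and coronary
sinus (CS) local activation waves (LAWs) recorded in sinus rhythm before,
during, and after catheter ablation of paroxysmal atrial fibrillation.

## The problem

During pulmonary-vein ablation, a multi-electrode catheter parked in the
coronary sinus records local atrial electrograms while the surface ECG
records global atrial depolarization (the P-wave). Whether CS activity
tracks the global substrate — and whether the effect of ablation on the CS
mirrors its effect on the atria as a whole — is assessed by correlating
per-activation features of the two channels. The catch is heart rate:
interval-dependent features (duration, area, slope rate) of both channels
ride on a fluctuating cycle length, and measurement jitter on intracardiac
fiducials decorrelates the raw values. atriosync implements the analysis
around that problem, including the heart-rate adjustment (HRA) that exposes
the masked coupling, and a synthetic cohort generator that makes every
stage testable without clinical data.

## What it computes

For every annotated activation: duration, maximum and peak-to-peak
amplitude, RMS amplitude, positive area (trapezoidal), and slope rates at
5/10/20 % of the duration and at the peak,

    S_i = (Amp(i) − Amp(onset)) / (t_i − t_onset)   [mV/ms].

Interval-dependent features are heart-rate adjusted with the scaling factor

    sf_i = 1000 / IBI_i,

where `IBI_i` is the channel's own inter-beat interval (ms): durations and
areas are multiplied by `sf_i`, slope rates divided by it. Per recording,
atrial rate variability is summarized as SDNN, VARNN = SDNN², and RMSSD.

Associations are quantified three ways:

* **Pearson correlation** per recording between matched surface/CS beat
  series, aggregated across the cohort by the median (mean only if the
  values pass a Shapiro–Wilk normality gate);
* **simple linear regression with 10-fold cross-validation**, reporting the
  adjusted coefficient of determination on pooled out-of-fold predictions
  (its p-value is the full-data slope t-test, identical to the Pearson
  test);
* **cross-quadratic sample entropy (CQSE)** between z-scored series,

      CQSE(m, r) = −ln( A^{m+1}(r) / A^m(r) ) + ln(2r),

  with Chebyshev template matching, defaults m = 1, r = 0.35. Independent
  Gaussian series give −ln erf(r/2) + ln 2r ≈ 1.28; shared dynamics push
  the value down.

The effect of ablation is measured per patient and feature as the percent
change of the per-recording median across a transition,
`CV = (median_after / median_before − 1) × 100`, and the surface and
invasive CV values are correlated across patients.

## Worked example

Simulate a small cohort in the high-fiducial-jitter regime (40 ms) where
heart-rate fluctuation masks the raw duration coupling, and run the whole
pipeline on annotations only:

```r
library(atriosync)
cfg <- cohort_config(n_patients = 6, n_beats = 120,
                     channel_ibi_jitter_sd = 40, seed = 2024)
res <- run_study(cfg, render = FALSE)
subset(res$table1, feature %in% c("duration", "hra_duration"))
```

```
      feature phase      rho            p n_recordings center significant
     duration   pre 54.47314 1.347912e-10            6 median        TRUE
 hra_duration   pre 66.44186 8.934789e-16            6 median        TRUE
     duration  lpvi 63.83738 4.392798e-15            6 median        TRUE
 hra_duration  lpvi 67.98083 2.462844e-17            6 median        TRUE
     duration  post 45.03650 3.057157e-07            6 median        TRUE
 hra_duration  post 68.41995 1.246539e-17            6 median        TRUE
```

The cohort was generated with a latent duration coupling of ρ = 0.7.
Raw duration correlations (45–64 %) are attenuated by the fiducial jitter
each channel adds to its own inter-beat intervals; after heart-rate
adjustment the correlation returns to the latent level (≈ 66–68 %) in
every phase. The entropy summary for the same run sits near the
independent-noise reference for all feature pairs:

```r
res$cqse$by_phase
```

```
 phase median_cqse       q1       q3 n_defined n_undefined
  lpvi    1.146247 1.124505 1.205809        12           0
  post    1.243282 1.215484 1.268178        12           0
   pre    1.221664 1.191300 1.247645        12           0
```

`run_study()` with the default `render = TRUE` synthesizes full 1 kHz
waveforms (raised-cosine P-waves, biphasic CS wavelets, power-line,
baseline-wander and broadband noise), pushes them through the zero-phase
notch and high-pass filters, optionally re-delineates them, and computes
the amplitude, area and slope features as well. `render_report()` writes
all tables as CSV, byte-reproducibly for a fixed seed.

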
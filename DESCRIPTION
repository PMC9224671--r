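Package: atriosync
Title: Paired Analysis of Surface P-Waves and Coronary Sinus Activation Waves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of paired surface-ECG (lead II) and bipolar
    coronary-sinus recordings acquired in sinus rhythm around catheter ablation
    of paroxysmal atrial fibrillation. Provides a synthetic cohort generator
    with ground-truth annotations, standard denoising filters and ectopic-beat
    handling, per-activation morphological features (duration, amplitudes,
    positive area, slope rates) with heart-rate adjustment, atrial-rate
    variability summaries (SDNN, VARNN, RMSSD), Pearson and 10-fold
    cross-validated linear-regression association analyses, ablation-induced
    variation statistics, and cross-quadratic sample entropy between paired
    feature series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
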
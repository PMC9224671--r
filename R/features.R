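# Per-activation morphological features, atrial-rate-variability summaries,
# and heart-rate-adjusted (HRA) variants. The HRA scaling factor for beat i is
# sf_i = 1000 / IBI_i; durations and areas are multiplied by sf_i, slope
# rates divided by it, so interval-dependent features are referred to a
# common 1000 ms cycle length.

#' Activation duration from one annotation
#'
#' @param onset,offset Sample indices (1-based, inclusive), onset < offset.
#' @param fs Sampling rate (Hz).
#' @return Duration in ms.
#' @export
activation_duration <- function(onset, offset, fs) {
  if (any(onset >= offset)) stop("onset must precede offset", call. = FALSE)
  (offset - onset) / fs * 1000
}

#' Amplitude features of one activation window
#'
#' `ampmax` is the maximum signed sample (not the rectified maximum: for
#' positive monophasic P-waves it coincides with the peak-to-peak amplitude,
#' for biphasic waves it is the positive lobe only), `pp` the peak-to-peak
#' amplitude, and `rms` the quadratic mean over the window.
#'
#' @param samples Numeric signal (mV).
#' @param onset,offset Window bounds (1-based, inclusive).
#' @return Named list with `ampmax`, `pp`, `rms` (mV).
#' @export
amplitude_features <- function(samples, onset, offset) {
  if (onset > offset) stop("empty annotation window", call. = FALSE)
  w <- samples[onset:offset]
  if (length(w) == 0 || anyNA(w)) stop("empty annotation window", call. = FALSE)
  list(ampmax = max(w), pp = max(w) - min(w), rms = sqrt(mean(w^2)))
}

#' Positive area of one activation window
#'
#' Negative samples are clipped to zero and the remainder integrated by the
#' trapezoidal rule with sample spacing `1000 / fs` ms.
#'
#' @inheritParams amplitude_features
#' @param fs Sampling rate (Hz).
#' @return Area in mV.ms.
#' @export
positive_area <- function(samples, onset, offset, fs) {
  w <- pmax(samples[onset:offset], 0)
  if (length(w) < 2) return(0)
  dt <- 1000 / fs
  sum((w[-1] + w[-length(w)]) / 2) * dt
}

#' Slope rate of one activation
#'
#' Signed amplitude change per ms between the onset and the sample at a given
#' fraction of the activation duration (or its peak):
#' `S = (Amp(i) - Amp(onset)) / (t_i - t_onset)`. Fractional sample points
#' are placed by round-half-up; a degenerate zero-width point is advanced by
#' one sample. Slope rates are positive for positive monophasic P-waves and
#' may be negative for biphasic waves.
#'
#' @param samples Numeric signal (mV).
#' @param onset,peak,offset Annotation indices (1-based).
#' @param fs Sampling rate (Hz).
#' @param at One of `"5%"`, `"10%"`, `"20%"`, `"max"`.
#' @return Slope in mV/ms.
#' @export
slope_rate <- function(samples, onset, peak, offset, fs,
                       at = c("5%", "10%", "20%", "max")) {
  at <- match.arg(at)
  if (onset >= offset) stop("onset must precede offset", call. = FALSE)
  ti <- if (at == "max") {
    peak
  } else {
    frac <- as.numeric(sub("%", "", at)) / 100
    as.integer(onset + rhu(frac * (offset - onset)))
  }
  if (ti == onset) ti <- ti + 1L
  (samples[ti] - samples[onset]) / ((ti - onset) * 1000 / fs)
}

#' Inter-beat intervals from annotations
#'
#' Peak-to-peak differences in ms; element i is the interval between
#' activations i and i-1, so the first element is `NA`.
#'
#' @param annotations Annotation data frame or [annotated_recording()].
#' @param fs Sampling rate (Hz); ignored when a recording is supplied.
#' @return Numeric vector of ms, first element `NA`.
#' @export
compute_ibi <- function(annotations, fs = 1000) {
  if (inherits(annotations, "annotated_recording")) {
    fs <- annotations$fs
    annotations <- annotations$annotations
  }
  if (nrow(annotations) < 2) stop("need at least 2 annotations", call. = FALSE)
  d <- diff(annotations$peak)
  if (any(d <= 0)) stop("annotation peaks must be strictly increasing", call. = FALSE)
  c(NA_real_, d * 1000 / fs)
}

#' Add heart-rate-adjusted feature columns
#'
#' Given a per-beat feature table with `ibi` (ms), computes `sf = 1000 / ibi`
#' and scales `duration` and `posar` by `sf` and the slope rates `s5`, `s10`,
#' `s20`, `smax` by `1 / sf`. Beats without a defined interval (the first
#' activation) get `NA` adjusted values and are excluded from pairwise
#' statistics downstream.
#'
#' @param features Data frame with at least an `ibi` column.
#' @return The data frame with `sf` and `hra_*` columns appended.
#' @export
hra_adjust <- function(features) {
  if (!"ibi" %in% names(features)) stop("`features` must contain `ibi`", call. = FALSE)
  sf <- ifelse(is.na(features$ibi) | features$ibi <= 0, NA_real_,
               1000 / features$ibi)
  features$sf <- sf
  for (col in intersect(c("duration", "posar"), names(features))) {
    features[[paste0("hra_", col)]] <- features[[col]] * sf
  }
  for (col in intersect(c("s5", "s10", "s20", "smax"), names(features))) {
    features[[paste0("hra_", col)]] <- features[[col]] / sf
  }
  features
}

#' Atrial-rate-variability summary of an interval series
#'
#' Time-domain variability of normal-to-normal activation intervals:
#' `sdnn` is the sample standard deviation (n - 1 denominator), `varnn` its
#' square, and `rmssd` the root mean square of successive interval
#' differences. Intervals should be ectopic-interpolated first.
#'
#' @param ibi Numeric interval series in ms (`NA` entries dropped).
#' @return List with `sdnn` (ms), `varnn` (ms^2), `rmssd` (ms),
#'   `n_intervals`.
#' @export
arv_summary <- function(ibi) {
  x <- ibi[!is.na(ibi)]
  if (length(x) < 3) stop("need at least 3 defined intervals", call. = FALSE)
  sdnn <- sd(x)
  list(sdnn = sdnn, varnn = sdnn^2, rmssd = sqrt(mean(diff(x)^2)),
       n_intervals = length(x))
}

#' Per-beat feature table of one recording
#'
#' Computes duration, inter-beat interval and heart-rate-adjusted duration
#' for every annotated activation; when the recording carries samples, also
#' the amplitude features, positive area and slope rates with their adjusted
#' variants.
#'
#' @param rec An [annotated_recording()].
#' @return Data frame with one row per activation.
#' @export
extract_features <- function(rec) {
  ann <- rec$annotations
  fs <- rec$fs
  n <- nrow(ann)
  feats <- data.frame(
    beat = seq_len(n),
    onset = ann$onset, peak = ann$peak, offset = ann$offset,
    duration = activation_duration(ann$onset, ann$offset, fs),
    ibi = if (n >= 2) compute_ibi(ann, fs) else rep(NA_real_, n)
  )
  if (!is.null(rec$samples)) {
    s <- rec$samples
    amp <- lapply(seq_len(n), function(i) {
      amplitude_features(s, ann$onset[i], ann$offset[i])
    })
    feats$ampmax <- vapply(amp, `[[`, numeric(1), "ampmax")
    feats$pp <- vapply(amp, `[[`, numeric(1), "pp")
    feats$rms <- vapply(amp, `[[`, numeric(1), "rms")
    feats$posar <- vapply(seq_len(n), function(i) {
      positive_area(s, ann$onset[i], ann$offset[i], fs)
    }, numeric(1))
    for (at in c("5%", "10%", "20%", "max")) {
      col <- paste0("s", sub("%", "", at))
      feats[[col]] <- vapply(seq_len(n), function(i) {
        slope_rate(s, ann$onset[i], ann$peak[i], ann$offset[i], fs, at)
      }, numeric(1))
    }
  }
  hra_adjust(feats)
}
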
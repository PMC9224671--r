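# Denoising, ectopic handling, and a threshold delineator. All filters are
# applied forward-backward (zero phase) so fiducial points are not shifted.

#' Remove power-line interference with a zero-phase notch filter
#'
#' Second-order IIR notch at `line_freq` (unity gain at DC and Nyquist),
#' applied forward-backward. The -3 dB notch width is `bandwidth` Hz per
#' pass; the passband is left within 1 dB outside a few Hz of the notch.
#'
#' @param samples Numeric signal (mV).
#' @param fs Sampling rate (Hz), must exceed `2 * line_freq`.
#' @param line_freq Interference frequency (Hz), default 50.
#' @param bandwidth Notch -3 dB bandwidth (Hz).
#' @return Filtered signal, same length.
#' @export
remove_powerline <- function(samples, fs, line_freq = 50, bandwidth = 2) {
  if (fs <= 2 * line_freq) {
    stop("`fs` must exceed twice the line frequency", call. = FALSE)
  }
  w0 <- 2 * pi * line_freq / fs
  g <- 1 / (1 + tan(pi * bandwidth / fs))
  b <- g * c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * g * cos(w0), 2 * g - 1)
  as.numeric(signal::filtfilt(b, a, samples))
}

#' Remove baseline wander with a zero-phase high-pass filter
#'
#' Second-order Butterworth high-pass applied forward-backward. At the 0.5 Hz
#' default a 0.1 Hz drift is attenuated far beyond 20 dB while components at
#' 5 Hz and above pass within 1 dB.
#'
#' @param samples Numeric signal (mV).
#' @param fs Sampling rate (Hz).
#' @param cutoff High-pass cutoff (Hz); values below 2 Hz are recommended so
#'   activation morphology is preserved.
#' @return Filtered signal, same length.
#' @export
remove_baseline_wander <- function(samples, fs, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop("`cutoff` must lie in (0, fs/2)", call. = FALSE)
  }
  bt <- signal::butter(2, cutoff / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bt, samples))
}

# Median of up to `k` intervals surrounding (and excluding) interval i.
surrounding_median <- function(x, i, k = 11) {
  n <- length(x)
  half <- k %/% 2
  lo <- i - half
  hi <- i + half + (k %% 2 == 0)
  if (lo < 1) {
    hi <- min(n, hi + (1 - lo))
    lo <- 1
  }
  if (hi > n) {
    lo <- max(1, lo - (hi - n))
    hi <- n
  }
  idx <- setdiff(lo:hi, i)
  median(x[idx])
}

#' Detect ectopic activations from interval deviation
#'
#' A beat is flagged as ectopic when its preceding inter-beat interval
#' deviates by more than `threshold` (default 20 percent) from the median of
#' the 11 surrounding intervals. Premature (ectopic) beats shorten their
#' preceding interval well beyond normal sinus fluctuation, so the running
#' median separates them cleanly.
#'
#' @param annotations Annotation data frame (onset/peak/offset indices) or an
#'   [annotated_recording()].
#' @param fs Sampling rate (Hz); ignored when a recording is supplied.
#' @param threshold Fractional deviation that triggers a flag.
#' @param window Number of surrounding intervals in the running median.
#' @return Logical vector, one flag per annotation (the first beat, which has
#'   no preceding interval, is never flagged).
#' @export
detect_ectopics <- function(annotations, fs = 1000, threshold = 0.2, window = 11) {
  if (inherits(annotations, "annotated_recording")) {
    fs <- annotations$fs
    annotations <- annotations$annotations
  }
  n <- nrow(annotations)
  if (n < 12) stop("need at least 12 annotations to detect ectopics", call. = FALSE)
  ibi <- diff(annotations$peak) * 1000 / fs
  flags <- rep(FALSE, n)
  for (i in seq_along(ibi)) {
    m <- surrounding_median(ibi, i, window)
    if (m > 0 && abs(ibi[i] - m) / m > threshold) flags[i + 1] <- TRUE
  }
  flags
}

#' Replace flagged entries of a feature sequence by linear interpolation
#'
#' Flagged entries are replaced by linear interpolation between the nearest
#' unflagged neighbours; flagged runs at either end take the nearest unflagged
#' value. Unflagged entries are never modified and length is preserved.
#'
#' @param x Numeric feature sequence (may contain `NA` at unflagged positions,
#'   which are preserved).
#' @param flags Logical vector of the same length.
#' @return Numeric vector of the same length.
#' @export
interpolate_ectopics <- function(x, flags) {
  if (length(x) != length(flags)) {
    stop("`flags` must match the length of `x`", call. = FALSE)
  }
  if (all(flags)) stop("cannot interpolate: all entries flagged", call. = FALSE)
  if (!any(flags)) return(x)
  keep <- which(!flags & !is.na(x))
  if (length(keep) == 0) stop("no defined unflagged entries", call. = FALSE)
  out <- x
  fill <- which(flags)
  out[fill] <- approx(keep, x[keep], xout = fill, rule = 2)$y
  out
}

#' Delineate activations around approximate peaks
#'
#' Stand-in threshold delineator for use when curated annotations are not
#' available. For each approximate peak the local isoelectric line is the
#' straight line through the medians of the outer thirds of a +/- 150 ms
#' window; the peak is refined to the extremum of the rectified signal near
#' the approximate location; onset and offset are the outermost samples
#' (within the window) at which a lightly smoothed rectified amplitude stays
#' above 5 percent of the peak-to-baseline range, allowing brief
#' sub-threshold gaps (so the zero crossing at the centre of a biphasic wave
#' does not truncate it). The edge is then walked down the remaining wave
#' tail: along the strict monotone descent of the raw samples when the local
#' noise floor (estimated from successive differences) is negligible, or
#' along the smoothed envelope down to that noise floor otherwise.
#'
#' @param samples Numeric signal (mV).
#' @param fs Sampling rate (Hz).
#' @param approximate_peaks Approximate peak sample indices (1-based),
#'   separated by at least 200 ms.
#' @param window_ms Half-width of the delineation window.
#' @param search_ms Half-width of the peak refinement window.
#' @param threshold Fraction of the peak-to-baseline range defining onset and
#'   offset.
#' @param smooth_ms Moving-average length used for threshold crossings and,
#'   on noisy signals, the descent tracking.
#' @param gap_ms Longest sub-threshold gap bridged when scanning away from
#'   the peak.
#' @return Annotation data frame (onset, peak, offset). Activations whose
#'   window has zero range are skipped with a warning.
#' @export
delineate <- function(samples, fs, approximate_peaks, window_ms = 150,
                      search_ms = 30, threshold = 0.05, smooth_ms = 16,
                      gap_ms = 15) {
  pk_in <- sort(as.integer(approximate_peaks))
  if (any(pk_in < 1 | pk_in > length(samples))) {
    stop("approximate peaks must lie within the signal", call. = FALSE)
  }
  if (length(pk_in) > 1 && any(diff(pk_in) < 0.2 * fs)) {
    stop("approximate peaks must be separated by at least 200 ms", call. = FALSE)
  }
  w <- as.integer(rhu(window_ms * fs / 1000))
  srch <- as.integer(rhu(search_ms * fs / 1000))
  k <- max(1L, as.integer(rhu(smooth_ms * fs / 1000)))
  gap <- max(1L, as.integer(rhu(gap_ms * fs / 1000)))
  sm <- as.numeric(stats::filter(samples, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- samples[is.na(sm)]
  out <- vector("list", length(pk_in))
  for (b in seq_along(pk_in)) {
    p0 <- pk_in[b]
    lo <- max(1L, p0 - w)
    hi <- min(length(samples), p0 + w)
    # isoelectric line: straight line through the medians of the outer thirds
    # of the window, so residual slow drift does not bias the thresholds
    third <- max(1L, (hi - lo + 1L) %/% 3L)
    lx <- lo + (third - 1L) / 2
    rx <- hi - (third - 1L) / 2
    lmed <- median(samples[lo:(lo + third - 1L)])
    rmed <- median(samples[(hi - third + 1L):hi])
    basev <- lmed + (rmed - lmed) * ((lo:hi) - lx) / max(rx - lx, 1)
    base_at <- function(i) basev[i - lo + 1L]
    sl <- max(lo, p0 - srch):min(hi, p0 + srch)
    pk <- sl[which.max(abs(samples[sl] - base_at(sl)))]
    rng <- abs(samples[pk] - base_at(pk))
    if (rng <= .Machine$double.eps) {
      warning(sprintf("flat window around peak %d: annotation skipped", p0))
      next
    }
    thr <- threshold * rng
    # robust noise estimate from successive differences (waves are smooth on
    # the sample scale, so they contribute little); the descent below the
    # threshold is followed until it stalls against this noise floor
    sigma_hat <- stats::mad(diff(samples[lo:hi])) / sqrt(2)
    scan_edge <- function(dir) {
      i <- pk
      last_above <- pk
      below <- 0L
      while (below <= gap) {
        nxt <- i + dir
        if (nxt < lo || nxt > hi) break
        i <- nxt
        if (abs(sm[i] - base_at(i)) >= thr) {
          last_above <- i
          below <- 0L
        } else {
          below <- below + 1L
        }
      }
      edge <- last_above
      if (sigma_hat < 0.01 * rng) {
        # clean signal: follow the monotone descent of the raw samples, but
        # demand a minimum decrement per step so residual drift (which falls
        # orders of magnitude more slowly than a wave tail) does not carry
        # the walk past the activation boundary
        step_eps <- 0.001 * rng
        repeat {
          nxt <- edge + dir
          if (nxt < lo || nxt > hi) break
          if (abs(samples[nxt] - base_at(nxt)) <
              abs(samples[edge] - base_at(edge)) - step_eps) {
            edge <- nxt
          } else {
            break
          }
        }
        edge
      } else {
        # noisy signal: follow the descent of the smoothed envelope and stop
        # where it reaches the noise floor of the smoothed signal (or turns
        # decisively upward again)
        floor_level <- sigma_hat / sqrt(k)
        run_min <- abs(sm[edge] - base_at(edge))
        i <- edge
        repeat {
          nxt <- i + dir
          if (nxt < lo || nxt > hi) break
          v <- abs(sm[nxt] - base_at(nxt))
          if (v < run_min) {
            run_min <- v
            edge <- nxt
          }
          if (v <= floor_level) {
            edge <- nxt
            break
          }
          if (v > run_min + 4 * floor_level) break
          i <- nxt
        }
        edge
      }
    }
    onset <- scan_edge(-1L)
    offset <- scan_edge(1L)
    if (onset >= pk) onset <- pk - 1L
    if (offset <= pk) offset <- pk + 1L
    out[[b]] <- data.frame(onset = onset, peak = pk, offset = offset)
  }
  ann <- do.call(rbind, out)
  if (is.null(ann)) {
    return(data.frame(onset = integer(), peak = integer(), offset = integer()))
  }
  ann
}
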
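# Cross-quadratic sample entropy (CQSE) between paired normalized feature
# series. CQSE is cross-sample entropy with a + ln(2r) tolerance correction
# that makes values comparable across choices of r. Low values indicate
# shared dynamics between the two series; independent Gaussian noise gives
# -ln(erf(r/2)) + ln(2r), about 1.28 at r = 0.35.

#' Z-score a series
#'
#' Removes level and scale differences before entropy computation:
#' `(x - mean(x)) / sd(x)` with the sample (n - 1) standard deviation.
#'
#' @param x Numeric vector of length >= 2 with nonzero variance.
#' @return Vector with mean 0 and sample standard deviation 1.
#' @export
normalize_series <- function(x) {
  if (length(x) < 2) stop("series too short to normalize", call. = FALSE)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("degenerate series: zero standard deviation", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Cross match probability of length-m templates
#'
#' Probability that a length-`m` template of `x` lies within Chebyshev
#' distance `r` of a length-`m` template of `y`, averaging over the first
#' `N - m` and `M - m` templates of each series (a distance exactly equal to
#' `r` counts as a match). Series are expected to be normalized already.
#'
#' @param x,y Numeric series (lengths N, M > m).
#' @param m Template length.
#' @param r Tolerance on the normalized scale.
#' @return Match probability in \[0, 1\].
#' @export
match_probability <- function(x, y, m, r) {
  cross_match_probability_cpp(as.numeric(x), as.numeric(y), as.integer(m), r)
}

#' Cross-quadratic sample entropy of two series
#'
#' `CQSE(m, r, N, M) = -ln(A^(m+1)(r) / A^m(r)) + ln(2r)` where `A^m(r)` is
#' the cross match probability of length-m templates. Both series are
#' z-scored first (unless `normalize = FALSE`), and `r` applies on the
#' normalized scale. When either match probability is zero the value is
#' undefined and returned as `NA` rather than infinite.
#'
#' @param x,y Numeric series of length >= m + 2.
#' @param m Template length (default 1).
#' @param r Tolerance (default 0.35).
#' @param normalize Z-score the inputs first (default `TRUE`).
#' @return List of class `cqse_result` with `value` (nats; `NA` when
#'   undefined), `m`, `r`, `N`, `M`, and match probabilities `a_m`, `a_m1`.
#' @export
cqse <- function(x, y, m = 1, r = 0.35, normalize = TRUE) {
  if (length(x) < m + 2 || length(y) < m + 2) {
    stop("series must have length >= m + 2", call. = FALSE)
  }
  if (r <= 0) stop("`r` must be positive", call. = FALSE)
  if (normalize) {
    x <- normalize_series(x)
    y <- normalize_series(y)
  }
  a_m <- match_probability(x, y, m, r)
  a_m1 <- match_probability(x, y, m + 1, r)
  value <- if (a_m > 0 && a_m1 > 0) -log(a_m1 / a_m) + log(2 * r) else NA_real_
  structure(list(value = value, m = m, r = r, N = length(x), M = length(y),
                 a_m = a_m, a_m1 = a_m1),
            class = "cqse_result")
}

#' @export
print.cqse_result <- function(x, ...) {
  cat(sprintf("CQSE(m = %d, r = %.2f, N = %d, M = %d) = %s  [A^m = %.4g, A^(m+1) = %.4g]\n",
              x$m, x$r, x$N, x$M,
              if (is.na(x$value)) "undefined" else sprintf("%.4f", x$value),
              x$a_m, x$a_m1))
  invisible(x)
}

#' CQSE across a table of paired feature series
#'
#' Computes one CQSE value per (patient, phase, feature) from a long table of
#' paired surface/invasive beat series, plus per-phase medians pooled over
#' features and per-phase, per-feature medians. Degenerate series (zero
#' variance) and undefined entropies are excluded from the medians and
#' counted.
#'
#' @param paired Data frame with columns `patient`, `phase`, `feature`,
#'   `surface`, `invasive` (one row per matched beat).
#' @param m,r Entropy parameters.
#' @return List with `per_recording` (data frame incl. `defined` flag),
#'   `by_phase` and `by_phase_feature` median summaries.
#' @export
cohort_cqse <- function(paired, m = 1, r = 0.35) {
  cells <- unique(paired[, c("patient", "phase", "feature")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- paired$patient == cells$patient[i] &
      paired$phase == cells$phase[i] & paired$feature == cells$feature[i]
    xs <- paired$surface[sel]
    ys <- paired$invasive[sel]
    ok <- is.finite(xs) & is.finite(ys)
    xs <- xs[ok]
    ys <- ys[ok]
    val <- NA_real_
    if (length(xs) >= m + 2 && sd(xs) > 0 && sd(ys) > 0) {
      val <- cqse(xs, ys, m = m, r = r)$value
    }
    data.frame(patient = cells$patient[i], phase = cells$phase[i],
               feature = cells$feature[i], cqse = val, defined = is.finite(val))
  })
  per <- do.call(rbind, res)
  agg <- function(df, by) {
    parts <- split(df, df[by], drop = TRUE)
    out <- lapply(parts, function(p) {
      v <- p$cqse[p$defined]
      cbind(p[1, by, drop = FALSE],
            data.frame(median_cqse = if (length(v)) median(v) else NA_real_,
                       q1 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
                       q3 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_,
                       n_defined = length(v), n_undefined = sum(!p$defined)))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  }
  list(per_recording = per,
       by_phase = agg(per, "phase"),
       by_phase_feature = agg(per, c("phase", "feature")))
}
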
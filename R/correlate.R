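# Linear association machinery: per-recording Pearson correlation,
# cross-validated simple linear regression, normality-gated cohort
# aggregation, and ablation-induced variation statistics.

#' Pearson correlation with correlation expressed in percent
#'
#' Product-moment correlation with a two-sided p-value from the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (pairs with `NA` dropped);
#'   at least 3 complete pairs with nonzero variance.
#' @return List of class `correlation_result` with `rho` (percent), `p_value`
#'   and `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  structure(list(rho = unname(ct$estimate) * 100, p_value = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("rho = %+.2f%%, p = %.4g, n = %d\n", x$rho, x$p_value, x$n))
  invisible(x)
}

#' Simple linear regression with k-fold cross-validated R-squared
#'
#' Folds are assigned by a seeded random permutation with near-equal sizes.
#' Each training fold yields a least-squares line; the coefficient of
#' determination is computed once on the pooled out-of-fold predictions and
#' adjusted for the single predictor as `1 - (1 - R2)(n - 1)/(n - 2)`.
#' Negative cross-validated values are floored at zero before conversion to
#' percent. The p-value is the full-data slope t-test, which for simple
#' regression is identical to the Pearson correlation test, so statistical
#' power matches the correlation analysis by construction.
#'
#' @param x,y Numeric vectors (predictor, response); complete pairs only,
#'   `n >= 2k`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return List of class `regression_cv_result` with `r2_adjusted` and `r2`
#'   (percent), `p_value`, `beta0`, `beta1`, `sigma2` (residual variance of
#'   the full fit), `k_folds`, `seed`, `n`.
#' @export
regression_cv <- function(x, y, k = 10, seed = 1L) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 2 * k) {
    stop(sprintf("n = %d is too small for %d folds; reduce `k`", n, k),
         call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance", call. = FALSE)
  folds <- local_seed(seed, sample(rep(seq_len(k), length.out = n)))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    tr <- folds != f
    mx <- mean(x[tr])
    my <- mean(y[tr])
    b1 <- sum((x[tr] - mx) * (y[tr] - my)) / sum((x[tr] - mx)^2)
    pred[!tr] <- my + b1 * (x[!tr] - mx)
  }
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum((y - pred)^2) / sst
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  mx <- mean(x)
  my <- mean(y)
  beta1 <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  beta0 <- my - beta1 * mx
  resid <- y - beta0 - beta1 * x
  structure(list(
    r2_adjusted = 100 * max(0, r2_adj), r2 = 100 * max(0, r2),
    p_value = cor.test(x, y)$p.value,
    beta0 = beta0, beta1 = beta1, sigma2 = sum(resid^2) / (n - 2),
    k_folds = k, seed = as.integer(seed), n = n
  ), class = "regression_cv_result")
}

#' Shapiro-Wilk normality gate
#'
#' Downstream aggregation reports medians when normality is rejected at
#' `alpha` and means otherwise.
#'
#' @param values Numeric vector, 3 <= n <= 5000, nonzero variance.
#' @param alpha Significance level of the gate.
#' @return List with `W`, `p_value`, `is_normal`.
#' @export
shapiro_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (sd(values) == 0) stop("zero variance", call. = FALSE)
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value,
       is_normal = sw$p.value >= alpha)
}

#' Aggregate per-recording correlation results across a cohort
#'
#' Normality of the correlation values is assessed with the Shapiro-Wilk
#' gate; the central value is the mean when normality holds and the median
#' otherwise (correlation statistics of physiological cohorts typically fail
#' the gate, so medians are the norm). The p-values are combined with the
#' same centring rule, symmetric with the correlation rule.
#'
#' @param rho Per-recording correlation values (percent).
#' @param p Per-recording p-values.
#' @return List with `rho`, `p_value`, `n_recordings`, `center`
#'   (`"mean"` or `"median"`).
#' @export
cohort_correlation <- function(rho, p) {
  ok <- is.finite(rho) & is.finite(p)
  rho <- rho[ok]
  p <- p[ok]
  if (length(rho) == 0) stop("no recording results to aggregate", call. = FALSE)
  # median unless the cohort is large enough to assess normality and passes
  center <- "median"
  if (length(rho) >= 8 && length(rho) <= 5000 && sd(rho) > 0) {
    if (shapiro_gate(rho)$is_normal) center <- "mean"
  }
  fun <- if (center == "mean") mean else median
  list(rho = fun(rho), p_value = fun(p), n_recordings = length(rho),
       center = center)
}

#' Ablation-induced variation of a feature
#'
#' Percent change of the per-recording median across an ablation transition:
#' `(median(after) / median(before) - 1) * 100`. Recording-level scalar
#' features (the rate-variability summaries) are passed as length-one
#' vectors and used directly.
#'
#' @param before,after Numeric feature values from the two recordings.
#' @return Percent change, or `NA` with a warning when the before-median is
#'   zero.
#' @export
ca_variation <- function(before, after) {
  mb <- median(before, na.rm = TRUE)
  ma <- median(after, na.rm = TRUE)
  if (!is.finite(mb) || mb == 0) {
    warning("undefined variation: zero or missing before-median")
    return(NA_real_)
  }
  (ma / mb - 1) * 100
}

#' Correlate ablation-induced variation across patients
#'
#' For one feature and one ablation transition, the Pearson correlation
#' across patients between the surface and invasive variation percentages.
#'
#' @param cv_table Data frame with columns `feature`, `transition`,
#'   `cv_surface`, `cv_invasive` (one row per patient per feature per
#'   transition).
#' @param feature,transition Cell selectors.
#' @return A `correlation_result` (see [pearson_correlation()]).
#' @export
transition_correlation <- function(cv_table, feature, transition) {
  rows <- cv_table$feature == feature & cv_table$transition == transition
  x <- cv_table$cv_surface[rows]
  y <- cv_table$cv_invasive[rows]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) {
    stop("fewer than 3 patients with defined variation pairs", call. = FALSE)
  }
  pearson_correlation(x[ok], y[ok])
}

#' Match activations one-to-one across two channels
#'
#' Greedy nearest-peak matching within a tolerance after subtracting the
#' median inter-channel delay; unmatched activations are dropped from
#' pairwise analyses.
#'
#' @param peaks_a,peaks_b Peak times (ms) of the two channels, increasing.
#' @param tol_ms Matching tolerance after delay removal.
#' @return Data frame with columns `a`, `b` of matched indices.
#' @export
match_activations <- function(peaks_a, peaks_b, tol_ms = 200) {
  if (length(peaks_a) == 0 || length(peaks_b) == 0) {
    return(data.frame(a = integer(), b = integer()))
  }
  # robust delay estimate from nearest-neighbour differences
  near <- vapply(peaks_a, function(t) peaks_b[which.min(abs(peaks_b - t))] - t,
                 numeric(1))
  delay <- median(near)
  b_adj <- peaks_b - delay
  used <- rep(FALSE, length(peaks_b))
  a_idx <- integer(0)
  b_idx <- integer(0)
  for (i in seq_along(peaks_a)) {
    d <- abs(b_adj - peaks_a[i])
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tol_ms) {
      used[j] <- TRUE
      a_idx <- c(a_idx, i)
      b_idx <- c(b_idx, j)
    }
  }
  data.frame(a = a_idx, b = b_idx)
}
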
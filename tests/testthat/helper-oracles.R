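# Independent oracles used by the tests. These deliberately re-implement the
# quantities under test in the most literal, least optimized way.

# Cross match probability by direct double-loop enumeration of the defining
# sums: mean over i = 1..N-m of the fraction of j = 1..M-m whose length-m
# templates lie within Chebyshev distance r (a distance equal to r counts).
bf_match_probability <- function(x, y, m, r) {
  N <- length(x)
  M <- length(y)
  total <- 0
  for (i in 1:(N - m)) {
    cnt <- 0
    for (j in 1:(M - m)) {
      d <- max(abs(x[i:(i + m - 1)] - y[j:(j + m - 1)]))
      if (r - d >= 0) cnt <- cnt + 1
    }
    total <- total + cnt / (M - m)
  }
  total / (N - m)
}

bf_cqse <- function(x, y, m, r) {
  xn <- (x - mean(x)) / sd(x)
  yn <- (y - mean(y)) / sd(y)
  am <- bf_match_probability(xn, yn, m, r)
  am1 <- bf_match_probability(xn, yn, m + 1, r)
  if (am == 0 || am1 == 0) return(NA_real_)
  -log(am1 / am) + log(2 * r)
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# Entropy of independent standard normal pairs: templates match when the
# difference of two independent N(0,1) draws, which is N(0, 2), lies within
# r, so A^m = erf(r/2)^m and the ratio leaves -ln erf(r/2) + ln 2r.
cqse_gaussian_limit <- function(r) -log(erf(r / 2)) + log(2 * r)

# Small quiet cohort for fast rendered tests.
quiet_config <- function(...) {
  args <- list(n_patients = 2, n_beats = 40, noise_sd = 0.004,
               wander_amp = 0.04, powerline_amp = 0.02)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}
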
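test_that("duration is the onset-offset interval in ms", {
  expect_equal(activation_duration(1000, 1120, 1000), 120)
  expect_equal(activation_duration(0, 1, 1000), 1)
  expect_equal(activation_duration(100, 160, 500), 120)
  expect_error(activation_duration(10, 10, 1000), "precede")
})

test_that("amplitude features follow their closed forms", {
  a <- amplitude_features(c(0, 0.2, 0), 1, 3)
  expect_equal(a$ampmax, 0.2)
  expect_equal(a$pp, 0.2)
  expect_equal(a$rms, sqrt(0.04 / 3))
  b <- amplitude_features(c(-0.1, 0.2), 1, 2)
  expect_equal(b$pp, 0.3)
  expect_equal(b$ampmax, 0.2)
  expect_error(amplitude_features(c(1, 2), 2, 1), "empty")
})

test_that("positive area clips negatives and integrates trapezoidally", {
  fs <- 1000
  rect <- rep(0.1, 101)  # 0.1 mV for 100 ms
  expect_equal(positive_area(rect, 1, 101, fs), 10, tolerance = 0.11)
  expect_equal(positive_area(rep(-0.5, 50), 1, 50, fs), 0)
  tri <- c(seq(0, 0.2, length.out = 61), seq(0.2, 0, length.out = 61)[-1])
  expect_equal(positive_area(tri, 1, 121, fs), 12, tolerance = 0.1)
})

test_that("slope rates are signed amplitude change per ms", {
  ramp <- seq(0, 0.2, length.out = 101)  # 0 to 0.2 mV over 100 ms
  expect_equal(slope_rate(ramp, 1, 101, 101, 1000, "max"), 0.002)
  expect_equal(slope_rate(ramp, 1, 101, 101, 1000, "20%"), 0.002)
  # positive monophasic wave: maximal slope rate positive
  peaks <- seq(1000, 5000, by = 800)
  rw <- render_waveforms(peaks, rep(120, length(peaks)), rep(0.2, length(peaks)),
                         "pwave", 1000)
  ann <- rw$annotations
  s <- vapply(seq_len(nrow(ann)), function(i) {
    slope_rate(rw$samples, ann$onset[i], ann$peak[i], ann$offset[i], 1000, "max")
  }, numeric(1))
  expect_true(all(s > 0))
  # downward-first biphasic wave: early slope rate negative
  rl <- render_waveforms(peaks, rep(90, length(peaks)), rep(0.5, length(peaks)),
                         "law", 1000)
  downward <- -rl$samples
  annl <- rl$annotations
  s5 <- slope_rate(downward, annl$onset[1], annl$peak[1], annl$offset[1],
                   1000, "5%")
  expect_lt(s5, 0)
  # degenerate zero-width point advances by one sample instead of dividing by 0
  expect_true(is.finite(slope_rate(ramp, 1, 3, 5, 1000, "5%")))
})

test_that("inter-beat intervals are peak differences with an undefined first", {
  ann <- data.frame(onset = c(1, 801, 1651) - 60 + 60,
                    peak = c(1, 801, 1651), offset = c(61, 861, 1711))
  ann$onset <- ann$peak - 30
  ibi <- compute_ibi(ann, fs = 1000)
  expect_true(is.na(ibi[1]))
  expect_equal(ibi[-1], c(800, 850))
  even <- data.frame(onset = c(1, 501, 1001), peak = c(31, 531, 1031),
                     offset = c(61, 561, 1061))
  expect_equal(compute_ibi(even, 1000)[-1], c(500, 500))
  bad <- data.frame(onset = c(1, 2), peak = c(10, 10), offset = c(20, 21))
  expect_error(compute_ibi(bad, 1000), "increasing")
})

test_that("heart-rate adjustment follows the scaling factor arithmetic", {
  f <- data.frame(duration = 120, posar = 10, s5 = 0.001, s10 = 0.0015,
                  s20 = 0.002, smax = 0.002, ibi = 800)
  h <- hra_adjust(f)
  expect_equal(h$sf, 1.25)
  expect_equal(h$hra_duration, 150)
  expect_equal(h$hra_posar, 12.5)
  expect_equal(h$hra_smax, 0.0016)
  # identity point: a 1000 ms interval changes nothing
  f2 <- data.frame(duration = 120, posar = 10, smax = 0.002, ibi = 1000)
  h2 <- hra_adjust(f2)
  expect_equal(h2$hra_duration, f2$duration)
  expect_equal(h2$hra_smax, f2$smax)
  # undefined interval propagates NA
  f3 <- data.frame(duration = c(120, 120), ibi = c(NA, 800))
  expect_true(is.na(hra_adjust(f3)$hra_duration[1]))
})

test_that("adjusted duration is invariant to a global time rescaling", {
  set.seed(5)
  ibi <- 800 + rnorm(50, 0, 40)
  nd <- 150 + rnorm(50, 0, 15)
  dur <- nd * ibi / 1000
  h1 <- hra_adjust(data.frame(duration = dur, ibi = ibi))
  h2 <- hra_adjust(data.frame(duration = dur * 1.3, ibi = ibi * 1.3))
  expect_equal(h1$hra_duration, h2$hra_duration, tolerance = 1e-12)
})

test_that("rate-variability summaries obey their algebra", {
  z <- arv_summary(c(800, 800, 800))
  expect_equal(z$sdnn, 0)
  expect_equal(z$varnn, 0)
  expect_equal(z$rmssd, 0)
  a <- arv_summary(c(790, 800, 810))
  expect_equal(a$sdnn, 10)
  expect_equal(a$varnn, 100)
  expect_equal(a$rmssd, 10)
  # varnn = sdnn^2 exactly, rmssd invariant to level shifts
  set.seed(6)
  x <- 800 + rnorm(100, 0, 50)
  s <- arv_summary(x)
  expect_identical(s$varnn, s$sdnn^2)
  expect_equal(arv_summary(x + 250)$rmssd, s$rmssd, tolerance = 1e-12)
  expect_error(arv_summary(c(800, 810)), "3")
})

test_that("interval variability of the generator matches its configuration", {
  x <- generate_ibi_series(300, 800, 50, 0.6, 12)
  expect_lt(abs(arv_summary(x)$sdnn - 50), 5)
})

test_that("feature extraction recovers generator ground truth", {
  cfg <- quiet_config(noise_sd = 0, wander_amp = 0, powerline_amp = 0, seed = 9)
  gp <- generate_patient(cfg, "pre", 31, render = TRUE)
  f <- extract_features(gp$surface)
  tr <- gp$truth
  # durations within a sample of scheduled, amplitudes within per-beat noise
  expect_lt(max(abs(f$duration - tr$duration_surface)), 1.5)
  expect_lt(max(abs(f$ampmax - tr$amp_surface)), 0.005)
  expect_equal(f$ampmax, f$pp, tolerance = 1e-4)  # positive monophasic
  expect_lt(max(abs(f$ibi[-1] - tr$ibi_surface[-1])), 1.5)
})
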
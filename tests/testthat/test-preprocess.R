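test_that("notch filter rejects the line frequency and spares the passband", {
  fs <- 1000
  t <- seq_len(6000) / fs
  line <- 0.1 * sin(2 * pi * 50 * t)
  out <- remove_powerline(line, fs)
  interior <- out[500:5500]
  residual_amp <- sqrt(2) * sqrt(mean(interior^2))
  expect_lte(residual_amp, 0.01)  # >= 20 dB rejection
  # broadband energy essentially untouched
  set.seed(1)
  wn <- rnorm(6000, 0, 0.05)
  expect_lt(abs(sqrt(mean(remove_powerline(wn, fs)^2)) / sqrt(mean(wn^2)) - 1),
            0.1)
  expect_equal(remove_powerline(numeric(100) , fs), numeric(100))
  expect_error(remove_powerline(line, fs = 90, line_freq = 50), "twice")
})

test_that("high-pass filter removes drift and DC but preserves 5 Hz", {
  fs <- 1000
  t <- seq_len(20000) / fs
  drift <- 0.5 * sin(2 * pi * 0.1 * t)
  out <- remove_baseline_wander(drift, fs)
  expect_lte(max(abs(out[2000:18000])), 0.05)
  offs <- remove_baseline_wander(rep(1, 5000), fs)
  expect_lt(abs(mean(offs[1000:4000])), 0.01)
  keep <- 0.2 * sin(2 * pi * 5 * t)
  kept <- remove_baseline_wander(keep, fs)
  amp <- sqrt(2) * sqrt(mean(kept[2000:18000]^2))
  expect_gt(amp / 0.2, 10^(-1 / 20))  # within 1 dB
  expect_error(remove_baseline_wander(drift, fs, cutoff = 600), "cutoff")
})

test_that("both filters are linear in their input", {
  fs <- 1000
  set.seed(2)
  x <- rnorm(3000, 0, 0.1)
  expect_equal(remove_powerline(3 * x, fs), 3 * remove_powerline(x, fs),
               tolerance = 1e-10)
  expect_equal(remove_baseline_wander(3 * x, fs),
               3 * remove_baseline_wander(x, fs), tolerance = 1e-10)
})

test_that("interval-deviation flags mark premature beats", {
  ann <- function(peaks) data.frame(onset = peaks - 60, peak = peaks,
                                    offset = peaks + 60)
  even <- ann(seq(1000, by = 800, length.out = 20))
  expect_false(any(detect_ectopics(even, fs = 1000)))
  peaks <- seq(1000, by = 800, length.out = 20)
  peaks[10:20] <- peaks[10:20] - 300  # beat 10 arrives 300 ms early
  flags <- detect_ectopics(ann(peaks), fs = 1000)
  expect_true(flags[10])
  expect_equal(sum(flags), 1)
  expect_error(detect_ectopics(even[1:5, ], fs = 1000), "12")
})

test_that("ectopic detector is sensitive and specific on generated cohorts", {
  sens <- numeric(0)
  fp <- numeric(0)
  for (s in 1:10) {
    cfg <- cohort_config(n_patients = 1, n_beats = 300, ectopic_rate = 0.04,
                         ectopic_shortening = 0.30, seed = s)
    gp <- generate_patient(cfg, "pre", s * 17, render = FALSE)
    truth <- gp$truth$ectopic_flags
    flags <- detect_ectopics(gp$surface)
    if (sum(truth) > 0) sens <- c(sens, sum(flags & truth) / sum(truth))
    fp <- c(fp, sum(flags & !truth) / sum(!truth))
  }
  expect_gte(mean(sens), 0.95)
  expect_lte(mean(fp), 0.01)
})

test_that("flag interpolation is linear between unflagged neighbours", {
  expect_equal(interpolate_ectopics(c(100, 999, 120), c(FALSE, TRUE, FALSE)),
               c(100, 110, 120))
  x <- c(5, 7, 2, 9)
  expect_identical(interpolate_ectopics(x, rep(FALSE, 4)), x)
  expect_equal(interpolate_ectopics(c(100, 0, 0, 130),
                                    c(FALSE, TRUE, TRUE, FALSE)),
               c(100, 110, 120, 130))
  # unflagged entries never change
  set.seed(3)
  y <- rnorm(50)
  fl <- runif(50) < 0.3
  fl[c(1, 50)] <- FALSE
  out <- interpolate_ectopics(y, fl)
  expect_identical(out[!fl], y[!fl])
  expect_length(out, 50)
  # flagged runs at the edges take the nearest unflagged value
  expect_equal(interpolate_ectopics(c(9, 5, 5), c(TRUE, FALSE, FALSE)),
               c(5, 5, 5))
  expect_error(interpolate_ectopics(c(1, 2), c(TRUE, TRUE)), "all entries")
})

test_that("delineation recovers noise-free durations almost exactly", {
  peaks <- seq(1000, 20000, by = 800)
  rw <- render_waveforms(peaks, rep(120, length(peaks)), rep(0.2, length(peaks)),
                         "pwave", 1000)
  ann <- delineate(rw$samples, 1000, rw$annotations$peak)
  durs <- (ann$offset - ann$onset)
  expect_true(all(abs(durs - 120) <= 4))
  # translation invariance: identical humps get identical durations
  expect_equal(length(unique(durs)), 1)
  # biphasic waves delineated across the zero crossing
  rl <- render_waveforms(peaks, rep(90, length(peaks)), rep(0.5, length(peaks)),
                         "law", 1000)
  annl <- delineate(rl$samples, 1000, rl$annotations$peak)
  true_dur <- rl$annotations$offset - rl$annotations$onset
  expect_true(all(abs((annl$offset - annl$onset) - true_dur) <= 4))
})

test_that("delineation stays accurate at 20 dB recording SNR", {
  peaks <- seq(1000, 40000, by = 800)
  clean <- render_waveforms(peaks, rep(120, length(peaks)),
                            rep(0.2, length(peaks)), "pwave", 1000)
  rec_rms <- sqrt(mean(clean$samples^2))
  errs <- numeric(0)
  for (s in 1:3) {
    noisy <- render_waveforms(peaks, rep(120, length(peaks)),
                              rep(0.2, length(peaks)), "pwave", 1000,
                              noise = list(noise_sd = rec_rms / 10), seed = s)
    ann <- delineate(noisy$samples, 1000, clean$annotations$peak)
    errs <- c(errs, abs((ann$offset - ann$onset) - 120))
  }
  expect_lte(median(errs), 8)
})

test_that("baseline wander removal preserves delineated durations", {
  peaks <- seq(1000, 20000, by = 800)
  clean <- render_waveforms(peaks, rep(120, length(peaks)),
                            rep(0.2, length(peaks)), "pwave", 1000)
  t <- seq_along(clean$samples) / 1000
  wander <- 0.3 * sin(2 * pi * 0.25 * t) + 0.15 * sin(2 * pi * 0.1 * t + 1)
  filtered <- remove_baseline_wander(clean$samples + wander, 1000)
  ann_c <- delineate(clean$samples, 1000, clean$annotations$peak)
  ann_f <- delineate(filtered, 1000, clean$annotations$peak)
  d_c <- ann_c$offset - ann_c$onset
  d_f <- ann_f$offset - ann_f$onset
  expect_lte(median(abs(d_f - d_c)), 2)
})

test_that("flat windows are skipped with a warning", {
  s <- numeric(2000)
  expect_warning(ann <- delineate(s, 1000, 500), "flat")
  expect_equal(nrow(ann), 0)
})
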
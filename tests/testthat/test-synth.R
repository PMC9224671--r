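test_that("inter-beat interval series has the requested AR(1) structure", {
  # zero variance degenerates to the mean
  expect_equal(generate_ibi_series(3, 800, 0, 0.5, 1), c(800, 800, 800))
  # determinism
  expect_identical(generate_ibi_series(100, 800, 50, 0.6, 7),
                   generate_ibi_series(100, 800, 50, 0.6, 7))
  # stationary moments at large n
  x <- generate_ibi_series(5000, 800, 50, 0.6, 7)
  expect_lt(abs(mean(x) - 800), 5)
  expect_lt(abs(sd(x) - 50), 5)
  # lag-1 autocorrelation near the configured coefficient
  expect_lt(abs(cor(x[-1], x[-length(x)]) - 0.6), 0.1)
  # floor: intervals never drop below 200 ms
  y <- generate_ibi_series(2000, 300, 200, 0, 11)
  expect_gte(min(y), 200)
  expect_error(generate_ibi_series(10, -5, 10, 0.5, 1), "positive")
})

test_that("patient generation is deterministic and respects its invariants", {
  cfg <- cohort_config(n_patients = 1, n_beats = 60, seed = 5)
  a <- generate_patient(cfg, "pre", 99, render = FALSE)
  b <- generate_patient(cfg, "pre", 99, render = FALSE)
  expect_identical(a, b)
  # annotation ordering invariants
  for (rec in list(a$surface, a$invasive)) {
    ann <- rec$annotations
    expect_true(all(ann$onset < ann$peak & ann$peak < ann$offset))
    expect_true(all(diff(ann$peak) > 0))
    expect_true(all(ann$onset[-1] > ann$offset[-nrow(ann)]))
  }
  expect_error(generate_patient(cfg, "during", 99), "arg")
})

test_that("perfect coupling makes normalized durations proportional beat-by-beat", {
  cfg <- cohort_config(n_patients = 1, n_beats = 50, rho_duration = 1,
                       channel_ibi_jitter_sd = 0, ectopic_rate = 0, seed = 2)
  gp <- generate_patient(cfg, "pre", 7, render = FALSE)
  nd_s <- gp$truth$normalized_surface / cfg$surface_duration_mean
  nd_c <- gp$truth$normalized_cs / cfg$cs_duration_mean
  expect_equal(nd_s, nd_c, tolerance = 1e-12)
  expect_equal(gp$truth$latent_rho, 1, tolerance = 1e-9)
})

test_that("realized duration coupling tracks the configured correlation", {
  cfg <- cohort_config(n_patients = 1, n_beats = 300, rho_duration = 0.7,
                       seed = 3)
  rhos <- vapply(1:10, function(s) {
    generate_patient(cfg, "pre", s, render = FALSE)$truth$latent_rho
  }, numeric(1))
  expect_true(all(abs(rhos - 0.7) < 0.15))
})

test_that("ectopic beats appear at the configured prevalence and never above 4%", {
  cfg <- cohort_config(n_patients = 1, n_beats = 300, ectopic_rate = 0.04,
                       seed = 4)
  counts <- vapply(1:30, function(s) {
    sum(generate_patient(cfg, "pre", s, render = FALSE)$truth$ectopic_flags)
  }, numeric(1))
  expect_true(all(counts <= floor(0.04 * 300)))
  # binomial mean 12 before capping; capping pulls it slightly below
  expect_gt(mean(counts), 8)
  expect_lte(mean(counts), 12)
})

test_that("heart-rate adjustment exactly inverts the generative distortion", {
  cfg <- cohort_config(n_patients = 1, n_beats = 80, seed = 6)
  gp <- generate_patient(cfg, "lpvi", 21, render = FALSE)
  tr <- gp$truth
  # exact identity on the latent quantities
  expect_equal(tr$duration_surface[-1] * 1000 / tr$ibi_surface[-1],
               tr$normalized_surface[-1], tolerance = 1e-12)
  expect_equal(tr$duration_cs[-1] * 1000 / tr$ibi_cs[-1],
               tr$normalized_cs[-1], tolerance = 1e-12)
  # via sample-quantized annotations the identity holds to quantization error
  f <- extract_features(gp$surface)
  err <- abs(f$hra_duration[-1] - tr$normalized_surface[-1])
  expect_lt(max(err), 2.5)
})

test_that("fiducial jitter attenuates raw duration coupling but not normalized", {
  cfg <- cohort_config(n_patients = 1, n_beats = 300, rho_duration = 0.7,
                       channel_ibi_jitter_sd = 40, ectopic_rate = 0, seed = 8)
  wins <- vapply(1:100, function(s) {
    tr <- generate_patient(cfg, "pre", s, render = FALSE)$truth
    raw <- cor(tr$duration_surface, tr$duration_cs)
    nrm <- cor(tr$normalized_surface, tr$normalized_cs)
    raw < nrm
  }, logical(1))
  expect_gte(sum(wins), 95)
})

test_that("rendered waveforms round-trip their scheduled morphology", {
  peaks <- seq(1000, 8000, by = 800)
  rw <- render_waveforms(peaks, rep(120, length(peaks)), rep(0.2, length(peaks)),
                         "pwave", fs = 1000)
  ann <- rw$annotations
  # nonnegative raised cosine: ampmax equals peak-to-peak, duration exact
  for (i in seq_len(nrow(ann))) {
    amp <- amplitude_features(rw$samples, ann$onset[i], ann$offset[i])
    expect_equal(amp$ampmax, 0.2, tolerance = 1e-3)
    expect_equal(amp$pp, amp$ampmax)
    expect_equal(activation_duration(ann$onset[i], ann$offset[i], 1000), 120,
                 tolerance = 1)
  }
  # biphasic wave: peak-to-peak exceeds the signed maximum
  rl <- render_waveforms(peaks, rep(90, length(peaks)), rep(0.5, length(peaks)),
                         "law", fs = 1000)
  annl <- rl$annotations
  ampl <- amplitude_features(rl$samples, annl$onset[1], annl$offset[1])
  expect_gt(ampl$pp, ampl$ampmax)
  expect_equal(ampl$ampmax, 0.5, tolerance = 0.01)
  expect_equal(ampl$pp, 1.0, tolerance = 0.02)
})

test_that("power-line noise dominates the spectrum at its line frequency", {
  peaks <- seq(1000, 30000, by = 800)
  rw <- render_waveforms(peaks, rep(120, length(peaks)), rep(0.15, length(peaks)),
                         "pwave", fs = 1000,
                         noise = list(powerline_amp = 0.05, powerline_freq = 50),
                         seed = 1)
  s <- rw$samples - mean(rw$samples)
  spec <- Mod(fft(s))[seq_len(length(s) %/% 2)]
  freq <- (seq_along(spec) - 1) * 1000 / length(s)
  # strongest component above 10 Hz sits at 50 Hz
  hi <- freq > 10
  expect_equal(freq[hi][which.max(spec[hi])], 50, tolerance = 0.2)
})

test_that("overlapping activations are rejected", {
  expect_error(render_waveforms(c(1000, 1100), c(300, 300), c(0.2, 0.2),
                                "pwave", 1000),
               "overlap")
  expect_error(render_waveforms(c(1000, 900), c(100, 100), c(0.2, 0.2),
                                "pwave", 1000),
               "increasing")
})

test_that("cohort configuration validates its bounds", {
  expect_error(cohort_config(ectopic_rate = 0.05), "0.04")
  expect_error(cohort_config(ibi_mean = 0), "positive")
  expect_error(cohort_config(n_beats = 5), "n_beats")
  expect_error(cohort_config(ibi_ar1 = 1), "ar1")
})
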
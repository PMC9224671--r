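#' Default per-phase effect multipliers
#'
#' Multiplicative shifts applied per ablation phase. `ibi` scales the mean
#' inter-beat interval (heart rate drops while radiofrequency energy is
#' applied, so the lpvi phase lengthens it), `arv` scales the inter-beat
#' variability (raised during energy delivery, depressed after the procedure
#' by transient autonomic impairment), `duration` and `amplitude` scale the
#' activation morphology (mild prolongation during ablation, shortening and
#' amplitude loss after substrate modification).
#'
#' @return Named list with elements `pre`, `lpvi`, `post`.
#' @export
default_phase_effects <- function() {
  list(
    pre  = list(duration = 1.00, amplitude = 1.00, ibi = 1.00, arv = 1.0),
    lpvi = list(duration = 1.05, amplitude = 0.95, ibi = 1.08, arv = 1.6),
    post = list(duration = 0.92, amplitude = 0.90, ibi = 1.00, arv = 0.6)
  )
}

#' Configuration of a synthetic ablation cohort
#'
#' Defines the statistical structure of a simulated cohort of paired surface
#' lead-II / bipolar coronary-sinus recordings in sinus rhythm. Defaults
#' emulate the study conditions the analysis is designed for: 40 patients,
#' 5-minute recordings at 1 kHz (roughly 300 sinus beats at 800 ms cycle
#' length), autocorrelated inter-beat intervals, cross-channel coupling of
#' cycle-normalized activation durations, per-channel fiducial jitter, and
#' ectopic beats at up to 4 percent prevalence.
#'
#' Normalized durations (`surface_duration_mean`, `cs_duration_mean`) are
#' expressed in ms at a reference cycle length of 1000 ms; the measured
#' duration of beat i is the normalized duration times `IBI_i / 1000`, so
#' heart-rate adjustment with the channel's own inter-beat interval recovers
#' the normalized value exactly.
#'
#' @param n_patients Number of patients.
#' @param n_beats Beats per recording (>= 10).
#' @param fs Sampling rate in Hz.
#' @param ibi_mean,ibi_sd Mean and stationary standard deviation of the
#'   inter-beat interval (ms).
#' @param ibi_ar1 Lag-1 autoregressive coefficient of the interval series,
#'   in (-1, 1).
#' @param rho_duration Target cross-channel correlation of normalized
#'   durations, in \[-1, 1\].
#' @param channel_ibi_jitter_sd Per-channel fiducial jitter sd (ms). The
#'   default (10 ms) reflects ordinary delineation noise; raising it to
#'   30-40 ms emulates strongly fluctuating fiducials and visibly attenuates
#'   raw (non-adjusted) duration correlations.
#' @param ectopic_rate Ectopic-beat prevalence, in \[0, 0.04\].
#' @param ectopic_shortening Fractional shortening of the interval preceding
#'   an ectopic beat (>= 0.3).
#' @param powerline_amp,powerline_freq Power-line interference amplitude (mV)
#'   and frequency (Hz).
#' @param wander_amp Baseline-wander amplitude (mV).
#' @param noise_sd Broadband noise sd (mV).
#' @param surface_duration_mean,surface_duration_cv Normalized P-wave duration
#'   mean (ms at 1000 ms cycle) and coefficient of variation.
#' @param cs_duration_mean,cs_duration_cv Same for the coronary-sinus local
#'   activation wave.
#' @param surface_amp,cs_amp Nominal activation amplitudes (mV).
#' @param cs_delay Conduction delay of the coronary-sinus channel relative to
#'   the surface channel (ms).
#' @param phase_effects Per-phase multiplier list, see
#'   [default_phase_effects()].
#' @param phase_effect_sd Log-normal sd of the per-patient random component of
#'   the phase duration effect (shared between channels; this is what makes
#'   ablation-induced variation correlated across channels).
#' @param seed Master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 40, n_beats = 300, fs = 1000,
                          ibi_mean = 800, ibi_sd = 50, ibi_ar1 = 0.6,
                          rho_duration = 0.7, channel_ibi_jitter_sd = 10,
                          ectopic_rate = 0.04, ectopic_shortening = 0.30,
                          powerline_amp = 0.05, powerline_freq = 50,
                          wander_amp = 0.10, noise_sd = 0.01,
                          surface_duration_mean = 150, surface_duration_cv = 0.10,
                          cs_duration_mean = 100, cs_duration_cv = 0.10,
                          surface_amp = 0.15, cs_amp = 0.50,
                          cs_delay = 40,
                          phase_effects = default_phase_effects(),
                          phase_effect_sd = 0.08,
                          seed = 1L) {
  if (!is.numeric(ibi_mean) || ibi_mean <= 0) {
    stop("`ibi_mean` must be positive", call. = FALSE)
  }
  if (n_beats < 10) stop("`n_beats` must be >= 10", call. = FALSE)
  if (ectopic_rate < 0 || ectopic_rate > 0.04) {
    stop("`ectopic_rate` must lie in [0, 0.04]", call. = FALSE)
  }
  if (abs(ibi_ar1) >= 1) stop("`ibi_ar1` must satisfy |ar1| < 1", call. = FALSE)
  if (abs(rho_duration) > 1) {
    stop("`rho_duration` must lie in [-1, 1]", call. = FALSE)
  }
  if (ibi_sd < 0 || channel_ibi_jitter_sd < 0 || noise_sd < 0) {
    stop("dispersion parameters must be nonnegative", call. = FALSE)
  }
  if (!all(c("pre", "lpvi", "post") %in% names(phase_effects))) {
    stop("`phase_effects` must name pre, lpvi and post", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0("<cohort_config> %d patients x %d beats, fs = %g Hz\n",
                     "  IBI %g +/- %g ms (ar1 = %g), duration coupling rho = %g,\n",
                     "  fiducial jitter %g ms, ectopics %.1f%%, seed %d\n"),
              x$n_patients, x$n_beats, x$fs, x$ibi_mean, x$ibi_sd, x$ibi_ar1,
              x$rho_duration, x$channel_ibi_jitter_sd, 100 * x$ectopic_rate,
              as.integer(x$seed)))
  invisible(x)
}

# Stationary AR(1) sequence around `mean` with marginal sd `sd`, no seeding.
ar1_sequence <- function(n, mean, sd, ar1) {
  if (sd == 0) return(rep(mean, n))
  dev <- numeric(n)
  dev[1] <- rnorm(1, 0, sd)
  if (n > 1) {
    innov <- rnorm(n - 1, 0, sd * sqrt(1 - ar1^2))
    for (i in 2:n) dev[i] <- ar1 * dev[i - 1] + innov[i - 1]
  }
  mean + dev
}

#' Generate an autocorrelated inter-beat interval series
#'
#' Stationary AR(1) process around `mean` with marginal standard deviation
#' `sd`, floored at 200 ms. This emulates the sinus-rhythm heart-rate
#' fluctuation that downstream heart-rate adjustment compensates for.
#'
#' @param n_beats Number of intervals (>= 2).
#' @param mean Mean interval (ms, > 0).
#' @param sd Marginal standard deviation (ms, >= 0).
#' @param ar1 Lag-1 autoregressive coefficient, |ar1| < 1.
#' @param seed Integer seed.
#' @return Numeric vector of intervals in ms.
#' @export
generate_ibi_series <- function(n_beats, mean, sd, ar1, seed) {
  if (!is.numeric(mean) || mean <= 0) {
    stop("invalid config: `mean` must be positive", call. = FALSE)
  }
  if (n_beats < 2) stop("`n_beats` must be >= 2", call. = FALSE)
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (abs(ar1) >= 1) stop("|ar1| must be < 1", call. = FALSE)
  local_seed(seed, pmax(ar1_sequence(n_beats, mean, sd, ar1), 200))
}

# Annotation sample indices for a train of activations. P-waves are symmetric
# about their peak; biphasic CS waves put the (positive) peak a third of the
# way into the wave.
annotate_beats <- function(peak_ms, duration_ms, kind, fs) {
  if (kind == "pwave") {
    onset_ms <- peak_ms - duration_ms / 2
    offset_ms <- peak_ms + duration_ms / 2
  } else {
    onset_ms <- peak_ms - duration_ms / 3
    offset_ms <- peak_ms + 2 * duration_ms / 3
  }
  ann <- data.frame(onset = as.integer(rhu(onset_ms * fs / 1000)),
                    peak = as.integer(rhu(peak_ms * fs / 1000)),
                    offset = as.integer(rhu(offset_ms * fs / 1000)))
  ann$onset <- pmax(ann$onset, 1L)
  ann$onset <- pmin(ann$onset, ann$peak - 1L)
  ann$offset <- pmax(ann$offset, ann$peak + 1L)
  ann
}

#' Render activation waveforms with additive noise
#'
#' Renders a beat schedule to a sampled signal. P-waves are nonnegative
#' raised-cosine humps (so the maximum and peak-to-peak amplitudes coincide);
#' coronary-sinus local activation waves are biphasic derivative-of-Gaussian
#' wavelets whose positive lobe reaches `amplitude` and whose negative lobe
#' mirrors it (peak-to-peak twice the maximum). Additive disturbances are a
#' power-line sinusoid, slow baseline wander (sinusoid plus a scaled random
#' walk), and white noise.
#'
#' @param peak_times Strictly increasing activation peak times (ms). For
#'   biphasic waves this is the time of the positive lobe.
#' @param durations Activation durations (ms), each shorter than the gap to
#'   the neighbouring activations.
#' @param amplitudes Peak amplitudes (mV).
#' @param kind `"pwave"` or `"law"`.
#' @param fs Sampling rate (Hz).
#' @param noise List with `powerline_amp`, `powerline_freq`, `wander_amp`,
#'   `noise_sd` (any subset; missing entries are 0 / 50 Hz).
#' @param n_samples Output length; defaults to half a second past the last
#'   offset.
#' @param seed Optional seed for the noise draws; `NULL` uses the current RNG
#'   stream.
#' @return List with `samples` (numeric, mV) and `annotations` (data frame of
#'   1-based onset/peak/offset indices).
#' @export
render_waveforms <- function(peak_times, durations, amplitudes,
                             kind = c("pwave", "law"), fs = 1000,
                             noise = list(), n_samples = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (any(diff(peak_times) <= 0)) {
    stop("`peak_times` must be strictly increasing", call. = FALSE)
  }
  if (any(durations <= 0)) stop("durations must be positive", call. = FALSE)
  ann <- annotate_beats(peak_times, durations, kind, fs)
  n <- length(peak_times)
  if (n > 1 && any(ann$onset[-1] <= ann$offset[-n])) {
    stop("overlapping activations", call. = FALSE)
  }
  if (is.null(n_samples)) n_samples <- max(ann$offset) + as.integer(fs / 2)
  render <- function() {
    s <- numeric(n_samples)
    for (i in seq_len(n)) {
      if (kind == "pwave") {
        on_ms <- peak_times[i] - durations[i] / 2
        idx <- ann$onset[i]:ann$offset[i]
        t_ms <- idx * 1000 / fs
        s[idx] <- s[idx] + amplitudes[i] / 2 *
          (1 - cos(2 * pi * pmin(pmax(t_ms - on_ms, 0), durations[i]) / durations[i]))
      } else {
        sigma <- durations[i] / 6
        ctr <- peak_times[i] + sigma
        idx <- ann$onset[i]:ann$offset[i]
        t_ms <- idx * 1000 / fs
        u <- (t_ms - ctr) / sigma
        s[idx] <- s[idx] + amplitudes[i] * (-u) * exp(-u^2 / 2 + 0.5)
      }
    }
    pl_amp <- noise$powerline_amp %||% 0
    pl_freq <- noise$powerline_freq %||% 50
    w_amp <- noise$wander_amp %||% 0
    n_sd <- noise$noise_sd %||% 0
    t_sec <- seq_len(n_samples) / fs
    if (pl_amp > 0) s <- s + pl_amp * sin(2 * pi * pl_freq * t_sec + runif(1, 0, 2 * pi))
    if (w_amp > 0) {
      s <- s + w_amp * sin(2 * pi * 0.2 * t_sec + runif(1, 0, 2 * pi))
      rw <- cumsum(rnorm(n_samples))
      if (sd(rw) > 0) s <- s + rw * (0.5 * w_amp / sd(rw))
    }
    if (n_sd > 0) s <- s + rnorm(n_samples, 0, n_sd)
    s
  }
  samples <- if (is.null(seed)) render() else local_seed(seed, render())
  list(samples = samples, annotations = ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate one patient's paired recordings for one phase
#'
#' Draws a master beat schedule (AR(1) inter-beat intervals), applies the
#' phase effects, inserts ectopic beats by shortening one interval and
#' shifting the remainder of the schedule, jitters each channel's fiducials,
#' draws cross-correlated normalized durations, and converts them to measured
#' durations through each channel's own inter-beat interval, so heart-rate
#' adjustment inverts the generative distortion exactly. The per-patient
#' random component of the phase duration effect is shared between channels.
#'
#' @param config A [cohort_config()].
#' @param phase `"pre"`, `"lpvi"` or `"post"`.
#' @param patient_seed Integer seed for this patient/phase (see
#'   [child_seed()]).
#' @param render If `TRUE`, render sampled waveforms (needed for amplitude,
#'   area and slope features); if `FALSE`, return annotation-only recordings
#'   (duration and rate features only), which is orders of magnitude faster.
#' @return List with `surface` and `invasive` ([annotated_recording()]) and
#'   `truth`, a list of latent quantities: exact peak times, channel
#'   inter-beat intervals, normalized and measured durations, ectopic flags,
#'   and `latent_rho`, the realized correlation of the normalized durations.
#' @export
generate_patient <- function(config, phase = c("pre", "lpvi", "post"),
                             patient_seed, render = TRUE) {
  phase <- match.arg(phase)
  pe <- config$phase_effects[[phase]]
  fs <- config$fs
  local_seed(patient_seed, {
    n <- config$n_beats
    dur_mul <- pe$duration * exp(rnorm(1, 0, config$phase_effect_sd))
    amp_mul_s <- pe$amplitude * exp(rnorm(1, 0, config$phase_effect_sd / 2))
    amp_mul_c <- pe$amplitude * exp(rnorm(1, 0, config$phase_effect_sd / 2))

    ibi <- pmax(ar1_sequence(n - 1, config$ibi_mean * pe$ibi,
                             config$ibi_sd * pe$arv, config$ibi_ar1), 200)
    t_master <- 1000 + c(0, cumsum(ibi))

    ect <- rep(FALSE, n)
    if (config$ectopic_rate > 0 && n > 4) {
      cand <- 3:(n - 2)
      ect[cand] <- runif(length(cand)) < config$ectopic_rate
      cap <- floor(0.04 * n)  # prevalence never exceeds 4 percent of beats
      if (sum(ect) > cap) {
        drop <- sample(which(ect), sum(ect) - cap)
        ect[drop] <- FALSE
      }
    }
    for (k in which(ect)) {
      delta <- config$ectopic_shortening * (t_master[k] - t_master[k - 1])
      t_master[k:n] <- t_master[k:n] - delta
    }

    jit <- config$channel_ibi_jitter_sd
    t_s <- t_master + rnorm(n, 0, jit)
    t_c <- t_master + config$cs_delay + rnorm(n, 0, jit)
    # jitter never realistically reorders beats >= 200 ms apart, but guard
    t_s <- cummax(t_s + seq_len(n) * 1e-9)
    t_c <- cummax(t_c + seq_len(n) * 1e-9)

    rho <- config$rho_duration
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    nd_s <- config$surface_duration_mean * dur_mul * (1 + config$surface_duration_cv * z1)
    nd_c <- config$cs_duration_mean * dur_mul * (1 + config$cs_duration_cv * z2)
    nd_s <- pmax(nd_s, 0.3 * config$surface_duration_mean)
    nd_c <- pmax(nd_c, 0.3 * config$cs_duration_mean)
    nd_s[ect] <- 0.8 * nd_s[ect]
    nd_c[ect] <- 0.8 * nd_c[ect]

    amp_s <- config$surface_amp * amp_mul_s * (1 + 0.05 * rnorm(n))
    amp_c <- config$cs_amp * amp_mul_c * (1 + 0.05 * rnorm(n))
    amp_s[ect] <- 0.7 * amp_s[ect]
    amp_c[ect] <- 0.7 * amp_c[ect]

    ibi_s <- c(NA_real_, diff(t_s))
    ibi_c <- c(NA_real_, diff(t_c))
    ref <- config$ibi_mean * pe$ibi
    dur_s <- nd_s * ifelse(is.na(ibi_s), ref, ibi_s) / 1000
    dur_c <- nd_c * ifelse(is.na(ibi_c), ref, ibi_c) / 1000

    noise <- list(powerline_amp = config$powerline_amp,
                  powerline_freq = config$powerline_freq,
                  wander_amp = config$wander_amp, noise_sd = config$noise_sd)
    if (render) {
      rs <- render_waveforms(t_s, dur_s, amp_s, "pwave", fs, noise)
      rc <- render_waveforms(t_c, dur_c, amp_c, "law", fs, noise)
      ann_s <- rs$annotations
      ann_c <- rc$annotations
      samp_s <- rs$samples
      samp_c <- rc$samples
    } else {
      ann_s <- annotate_beats(t_s, dur_s, "pwave", fs)
      ann_c <- annotate_beats(t_c, dur_c, "law", fs)
      samp_s <- NULL
      samp_c <- NULL
    }

    truth <- list(
      master_ibi = ibi, master_times = t_master,
      peak_ms_surface = t_s, peak_ms_cs = t_c,
      ibi_surface = ibi_s, ibi_cs = ibi_c,
      normalized_surface = nd_s, normalized_cs = nd_c,
      duration_surface = dur_s, duration_cs = dur_c,
      amp_surface = amp_s, amp_cs = amp_c,
      ectopic_flags = ect,
      latent_rho = if (sd(nd_s) > 0 && sd(nd_c) > 0) cor(nd_s, nd_c) else NA_real_
    )
    list(
      surface = annotated_recording(samp_s, fs, "surface-lead-II", ann_s, ect),
      invasive = annotated_recording(samp_c, fs, "cs-bipolar", ann_c, ect),
      truth = truth
    )
  })
}

#' Write a synthetic cohort to disk
#'
#' Generates every patient x phase pair of recordings and writes samples as
#' CSV, annotations as JSON lines, and a JSON manifest binding them together
#' with the generating configuration.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @param render Render waveforms (see [generate_patient()]).
#' @return The manifest path, invisibly.
#' @export
simulate_cohort <- function(config, dir, render = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  phases <- c("pre", "lpvi", "post")
  entries <- list()
  for (p in seq_len(config$n_patients)) {
    for (q in seq_along(phases)) {
      ph <- phases[q]
      gp <- generate_patient(config, ph, child_seed(config$seed, p, q), render)
      rel <- file.path(sprintf("patient_%02d", p), ph)
      dir.create(file.path(dir, rel), recursive = TRUE, showWarnings = FALSE)
      paths <- list(surface_csv = file.path(rel, "surface.csv"),
                    surface_ann = file.path(rel, "surface.jsonl"),
                    invasive_csv = file.path(rel, "cs.csv"),
                    invasive_ann = file.path(rel, "cs.jsonl"))
      if (render) {
        write_recording_csv(gp$surface, file.path(dir, paths$surface_csv))
        write_recording_csv(gp$invasive, file.path(dir, paths$invasive_csv))
      }
      write_annotations_jsonl(gp$surface, file.path(dir, paths$surface_ann))
      write_annotations_jsonl(gp$invasive, file.path(dir, paths$invasive_ann))
      entries[[length(entries) + 1]] <- c(
        list(patient = p, phase = ph, seed = child_seed(config$seed, p, q)),
        paths
      )
    }
  }
  manifest <- list(
    config = unclass(config)[setdiff(names(config), "phase_effects")],
    phase_effects = config$phase_effects,
    fs = config$fs, seed = as.integer(config$seed), rendered = render,
    recordings = entries
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
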
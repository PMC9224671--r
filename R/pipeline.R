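# Orchestration: synth -> preprocess -> features -> correlation / entropy
# across patients, phases (pre, lpvi, post) and ablation transitions.

PHASES <- c("pre", "lpvi", "post")
TRANSITIONS <- list(pre_lpvi = c("pre", "lpvi"),
                    pre_post = c("pre", "post"),
                    lpvi_post = c("lpvi", "post"))
ACTIVATION_FEATURES <- c("duration", "ampmax", "pp", "rms", "posar",
                         "s5", "s10", "s20", "smax",
                         "hra_duration", "hra_posar",
                         "hra_s5", "hra_s10", "hra_s20", "hra_smax")
ARV_FEATURES <- c("sdnn", "varnn", "rmssd")

# Ectopic-interpolate the raw feature columns of a per-beat table, then
# recompute the heart-rate-adjusted columns from the interpolated values.
interpolate_feature_table <- function(feats, flags) {
  raw_cols <- intersect(c("duration", "ibi", "ampmax", "pp", "rms", "posar",
                          "s5", "s10", "s20", "smax"), names(feats))
  if (any(flags) && !all(flags)) {
    for (col in raw_cols) {
      feats[[col]] <- interpolate_ectopics(feats[[col]], flags)
    }
  }
  feats$sf <- NULL
  feats[grepl("^hra_", names(feats))] <- NULL
  hra_adjust(feats)
}

# Analysis of one patient's paired recordings for one phase.
analyze_pair <- function(surface, invasive, patient, phase, k_folds, cv_seed,
                         m, r, filter_signals = TRUE, run_delineation = FALSE) {
  fs <- surface$fs
  prep <- function(rec) {
    if (!is.null(rec$samples) && filter_signals) {
      s <- remove_powerline(rec$samples, fs)
      s <- remove_baseline_wander(s, fs)
      rec$samples <- s
    }
    if (!is.null(rec$samples) && run_delineation) {
      ann <- delineate(rec$samples, fs, rec$annotations$peak)
      rec <- annotated_recording(rec$samples, fs, rec$channel_kind, ann)
    }
    rec
  }
  surface <- prep(surface)
  invasive <- prep(invasive)

  feats_s <- extract_features(surface)
  feats_c <- extract_features(invasive)
  flag_s <- if (nrow(feats_s) >= 12) detect_ectopics(surface) else rep(FALSE, nrow(feats_s))
  flag_c <- if (nrow(feats_c) >= 12) detect_ectopics(invasive) else rep(FALSE, nrow(feats_c))
  # an ectopic beat belongs to the heartbeat, not to one channel: when both
  # channels carry the same beats, interpolate the union of the flags in both
  if (nrow(feats_s) == nrow(feats_c)) {
    flag_s <- flag_c <- flag_s | flag_c
  }
  feats_s <- interpolate_feature_table(feats_s, flag_s)
  feats_c <- interpolate_feature_table(feats_c, flag_c)

  arv_s <- arv_summary(feats_s$ibi)
  arv_c <- arv_summary(feats_c$ibi)

  mt <- match_activations(feats_s$peak * 1000 / fs, feats_c$peak * 1000 / fs)
  feat_cols <- intersect(ACTIVATION_FEATURES, intersect(names(feats_s), names(feats_c)))

  paired <- do.call(rbind, lapply(feat_cols, function(f) {
    data.frame(patient = patient, phase = phase, feature = f,
               beat = seq_len(nrow(mt)),
               surface = feats_s[[f]][mt$a], invasive = feats_c[[f]][mt$b])
  }))

  stats <- do.call(rbind, lapply(feat_cols, function(f) {
    xs <- feats_s[[f]][mt$a]
    ys <- feats_c[[f]][mt$b]
    ok <- is.finite(xs) & is.finite(ys)
    rho <- p <- r2 <- r2p <- cq <- NA_real_
    if (sum(ok) >= 3 && sd(xs[ok]) > 0 && sd(ys[ok]) > 0) {
      pc <- pearson_correlation(xs[ok], ys[ok])
      rho <- pc$rho
      p <- pc$p_value
      if (sum(ok) >= 2 * k_folds) {
        lr <- regression_cv(xs[ok], ys[ok], k = k_folds, seed = cv_seed)
        r2 <- lr$r2_adjusted
        r2p <- lr$p_value
      }
      if (sum(ok) >= m + 2) cq <- cqse(xs[ok], ys[ok], m = m, r = r)$value
    }
    data.frame(patient = patient, phase = phase, feature = f,
               rho = rho, p = p, r2_adjusted = r2, r2_p = r2p, cqse = cq,
               n_pairs = sum(ok))
  }))

  med_rows <- lapply(feat_cols, function(f) {
    data.frame(patient = patient, phase = phase, feature = f,
               median_surface = median(feats_s[[f]], na.rm = TRUE),
               median_invasive = median(feats_c[[f]], na.rm = TRUE))
  })
  med_rows <- c(med_rows, lapply(ARV_FEATURES, function(f) {
    data.frame(patient = patient, phase = phase, feature = f,
               median_surface = arv_s[[f]], median_invasive = arv_c[[f]])
  }))

  n_ann <- nrow(feats_s)
  excl <- data.frame(
    patient = patient, phase = phase,
    annotations_surface = nrow(feats_s), annotations_invasive = nrow(feats_c),
    matched_pairs = nrow(mt),
    unmatched_surface = nrow(feats_s) - nrow(mt),
    unmatched_invasive = nrow(feats_c) - nrow(mt),
    ectopic_surface = sum(flag_s), ectopic_invasive = sum(flag_c),
    first_beat_excluded = 1L
  )

  list(paired = paired, stats = stats, medians = do.call(rbind, med_rows),
       exclusions = excl)
}

#' Run the full paired surface/invasive analysis over a cohort
#'
#' Generates (or loads) every patient x phase pair of recordings, applies
#' standard preprocessing, extracts per-activation features with heart-rate
#' adjustment, interpolates detected ectopics at the feature level, matches
#' activations one-to-one across channels, and produces: per-recording paired
#' feature tables; the per-phase Pearson correlation summary; the per-phase
#' cross-validated regression summary; ablation-transition variation
#' correlations (including the rate-variability features SDNN, VARNN and
#' RMSSD); and the cross-quadratic sample entropy summary.
#'
#' @param x A [cohort_config()] (the cohort is simulated) or the path of a
#'   manifest written by [simulate_cohort()].
#' @param seed Master seed; defaults to the config's seed.
#' @param render Render waveforms when simulating. With `render = FALSE` only
#'   duration and rate features are available, which is much faster and
#'   sufficient for duration-focused analyses.
#' @param delineate Re-delineate from the samples instead of using the
#'   carried annotations (stand-in delineator; requires rendered waveforms).
#' @param filter_signals Apply power-line and baseline-wander removal to
#'   rendered waveforms before feature extraction.
#' @param k_folds Folds of the cross-validated regression.
#' @param m,r Entropy template length and tolerance.
#' @param alpha Significance level used for report flags.
#' @param pooled If `TRUE`, phase-level correlations pool matched activations
#'   across patients instead of aggregating per-recording statistics.
#' @return Object of class `study_result`: list with `per_recording`,
#'   `paired`, `table1` (Pearson), `table2` (regression), `cv_transitions`,
#'   `table3` (transition correlations), `cqse`, `medians`, `exclusions`,
#'   `meta`.
#' @export
run_study <- function(x, seed = NULL, render = TRUE, delineate = FALSE,
                      filter_signals = TRUE, k_folds = 10, m = 1, r = 0.35,
                      alpha = 0.05, pooled = FALSE) {
  if (inherits(x, "cohort_config")) {
    seed <- if (is.null(seed)) x$seed else seed
    loader <- function(p, q) {
      generate_patient(x, PHASES[q], child_seed(seed, p, q), render = render)
    }
    n_patients <- x$n_patients
    meta_src <- list(source = "synthetic", config = unclass(x))
  } else if (is.character(x)) {
    cohort <- load_cohort(x)
    seed <- if (is.null(seed)) cohort$seed else seed
    loader <- function(p, q) cohort$recordings[[p]][[PHASES[q]]]
    n_patients <- cohort$n_patients
    meta_src <- list(source = "manifest", manifest = x)
  } else {
    stop("`x` must be a cohort_config or a manifest path", call. = FALSE)
  }

  parts <- list()
  for (p in seq_len(n_patients)) {
    for (q in seq_along(PHASES)) {
      gp <- loader(p, q)
      if (is.null(gp)) {
        stop(sprintf("patient %d is missing phase %s", p, PHASES[q]), call. = FALSE)
      }
      parts[[length(parts) + 1]] <- analyze_pair(
        gp$surface, gp$invasive, p, PHASES[q], k_folds,
        cv_seed = child_seed(seed, p, q) + 31L, m = m, r = r,
        filter_signals = filter_signals, run_delineation = delineate
      )
    }
  }

  per_recording <- do.call(rbind, lapply(parts, `[[`, "stats"))
  paired <- do.call(rbind, lapply(parts, `[[`, "paired"))
  medians <- do.call(rbind, lapply(parts, `[[`, "medians"))
  exclusions <- do.call(rbind, lapply(parts, `[[`, "exclusions"))

  feat_set <- unique(per_recording$feature)
  cells <- expand.grid(feature = feat_set, phase = PHASES,
                       stringsAsFactors = FALSE)
  summarize_cell <- function(f, ph, value_col, p_col) {
    sel <- per_recording$feature == f & per_recording$phase == ph
    v <- per_recording[[value_col]][sel]
    pv <- per_recording[[p_col]][sel]
    if (!any(is.finite(v))) {
      return(data.frame(feature = f, phase = ph, value = NA_real_,
                        p = NA_real_, n_recordings = 0L, center = NA_character_))
    }
    agg <- cohort_correlation(v, pv)
    data.frame(feature = f, phase = ph, value = agg$rho, p = agg$p_value,
               n_recordings = agg$n_recordings, center = agg$center)
  }
  pooled_cell <- function(f, ph) {
    sel <- paired$feature == f & paired$phase == ph
    xs <- paired$surface[sel]
    ys <- paired$invasive[sel]
    ok <- is.finite(xs) & is.finite(ys)
    pc <- pearson_correlation(xs[ok], ys[ok])
    data.frame(feature = f, phase = ph, value = pc$rho, p = pc$p_value,
               n_recordings = pc$n, center = "pooled")
  }
  table1 <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    if (pooled) pooled_cell(cells$feature[i], cells$phase[i])
    else summarize_cell(cells$feature[i], cells$phase[i], "rho", "p")
  }))
  names(table1)[names(table1) == "value"] <- "rho"
  table1$significant <- is.finite(table1$p) & table1$p < alpha

  table2 <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    summarize_cell(cells$feature[i], cells$phase[i], "r2_adjusted", "r2_p")
  }))
  names(table2)[names(table2) == "value"] <- "r2_adjusted"
  table2$significant <- is.finite(table2$p) & table2$p < alpha

  cv_rows <- list()
  for (tr in names(TRANSITIONS)) {
    ph <- TRANSITIONS[[tr]]
    for (p in unique(medians$patient)) {
      before <- medians[medians$patient == p & medians$phase == ph[1], ]
      after <- medians[medians$patient == p & medians$phase == ph[2], ]
      for (f in unique(medians$feature)) {
        b_s <- before$median_surface[before$feature == f]
        a_s <- after$median_surface[after$feature == f]
        b_c <- before$median_invasive[before$feature == f]
        a_c <- after$median_invasive[after$feature == f]
        if (!length(b_s) || !length(a_s)) next
        cv_rows[[length(cv_rows) + 1]] <- data.frame(
          patient = p, feature = f, transition = tr,
          cv_surface = suppressWarnings(ca_variation(b_s, a_s)),
          cv_invasive = suppressWarnings(ca_variation(b_c, a_c))
        )
      }
    }
  }
  cv_transitions <- do.call(rbind, cv_rows)

  table3 <- do.call(rbind, lapply(names(TRANSITIONS), function(tr) {
    do.call(rbind, lapply(unique(cv_transitions$feature), function(f) {
      res <- tryCatch(transition_correlation(cv_transitions, f, tr),
                      error = function(e) NULL)
      data.frame(feature = f, transition = tr,
                 rho = if (is.null(res)) NA_real_ else res$rho,
                 p = if (is.null(res)) NA_real_ else res$p_value,
                 n_patients = if (is.null(res)) 0L else res$n)
    }))
  }))
  table3$significant <- is.finite(table3$p) & table3$p < alpha

  cqse_summary <- cohort_cqse(paired, m = m, r = r)

  meta <- c(meta_src, list(
    seed = as.integer(seed), k_folds = k_folds, m = m, r = r, alpha = alpha,
    pooled = pooled, render = render, delineate = delineate,
    filter_signals = filter_signals,
    n_patients = n_patients, phases = PHASES
  ))
  structure(list(per_recording = per_recording, paired = paired,
                 table1 = table1, table2 = table2,
                 cv_transitions = cv_transitions, table3 = table3,
                 cqse = cqse_summary, medians = medians,
                 exclusions = exclusions, meta = meta),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d patients, seed %d, %s cohort\n",
              x$meta$n_patients, x$meta$seed, x$meta$source))
  cat(sprintf("  features: %s\n", paste(unique(x$table1$feature), collapse = ", ")))
  top <- x$table1[x$table1$significant, ]
  cat(sprintf("  significant phase correlations: %d of %d cells\n",
              nrow(top), nrow(x$table1)))
  invisible(x)
}

# Reload a cohort written by simulate_cohort().
load_cohort <- function(manifest_path) {
  man <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  base <- dirname(manifest_path)
  fix_path <- function(p) file.path(base, p)
  recs <- list()
  n_patients <- 0L
  for (e in man$recordings) {
    p <- e$patient
    ph <- e$phase
    n_patients <- max(n_patients, p)
    ann_s <- read_annotations_jsonl(fix_path(e$surface_ann))
    ann_c <- read_annotations_jsonl(fix_path(e$invasive_ann))
    fs <- man$fs
    surf <- if (isTRUE(man$rendered)) {
      read_recording_csv(fix_path(e$surface_csv), fs, "surface-lead-II",
                         ann_s$annotations, ann_s$ectopic_flags)
    } else {
      annotated_recording(NULL, fs, "surface-lead-II", ann_s$annotations,
                          ann_s$ectopic_flags)
    }
    inv <- if (isTRUE(man$rendered)) {
      read_recording_csv(fix_path(e$invasive_csv), fs, "cs-bipolar",
                         ann_c$annotations, ann_c$ectopic_flags)
    } else {
      annotated_recording(NULL, fs, "cs-bipolar", ann_c$annotations,
                          ann_c$ectopic_flags)
    }
    if (length(recs) < p) recs[[p]] <- list()
    recs[[p]][[ph]] <- list(surface = surf, invasive = inv)
  }
  list(recordings = recs, n_patients = n_patients, seed = man$seed)
}

#' Write a study result bundle to CSV files
#'
#' Emits the phase-correlation, regression, transition and entropy tables as
#' CSV together with per-recording statistics, exclusion accounting and a
#' JSON run log. Output is deterministic: re-running the same configuration
#' and seed reproduces every file byte for byte.
#'
#' @param result A `study_result` from [run_study()].
#' @param dir Output directory (created if needed).
#' @param plots If `TRUE` and ggplot2 is installed, also saves summary
#'   figures (correlation bars per phase, variation bars per transition, and
#'   an entropy box plot).
#' @return Character vector of file paths, invisibly.
#' @export
render_report <- function(result, dir, plots = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    table1 = "table1_pearson.csv", table2 = "table2_regression.csv",
    table3 = "table3_transition_cv.csv", per_recording = "per_recording.csv",
    cv_transitions = "cv_transitions.csv", medians = "medians.csv",
    exclusions = "exclusions.csv"
  )
  written <- character(0)
  for (nm in names(files)) {
    path <- file.path(dir, files[[nm]])
    write.csv(result[[nm]], path, row.names = FALSE)
    written <- c(written, path)
  }
  for (nm in c("per_recording", "by_phase", "by_phase_feature")) {
    path <- file.path(dir, sprintf("cqse_%s.csv", nm))
    write.csv(result$cqse[[nm]], path, row.names = FALSE)
    written <- c(written, path)
  }
  log_path <- file.path(dir, "run_info.json")
  jsonlite::write_json(result$meta, log_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, log_path)
  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    written <- c(written, save_report_plots(result, dir))
  }
  invisible(written)
}

save_report_plots <- function(result, dir) {
  g <- ggplot2::ggplot(result$table1,
                       ggplot2::aes(x = feature, y = rho, fill = phase)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "Pearson correlation (%)", x = NULL)
  p1 <- file.path(dir, "correlations_by_phase.pdf")
  ggplot2::ggsave(p1, g, width = 7, height = 6)
  per <- result$cqse$per_recording
  g2 <- ggplot2::ggplot(per[per$defined, ],
                        ggplot2::aes(x = phase, y = cqse)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.6) +
    ggplot2::labs(y = "CQSE (nats)", x = NULL)
  p2 <- file.path(dir, "cqse_by_phase.pdf")
  ggplot2::ggsave(p2, g2, width = 5, height = 4)
  c(p1, p2)
}
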
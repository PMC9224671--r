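#' Construct an annotated single-channel recording
#'
#' Container for one channel's samples together with its activation
#' annotations. Annotations are stored as 1-based, inclusive sample indices
#' (`onset`, `peak`, `offset`); serialized JSON-lines use 0-based indices.
#'
#' @param samples Numeric vector of amplitudes in mV, or `NULL` for an
#'   annotation-only recording (duration and rate features remain computable).
#' @param fs Sampling rate in Hz.
#' @param channel_kind `"surface-lead-II"` or `"cs-bipolar"`.
#' @param annotations Data frame with integer columns `onset`, `peak`,
#'   `offset`, strictly ordered within and between rows.
#' @param ectopic_flags Logical vector, one flag per annotation (defaults to
#'   all `FALSE`).
#' @return An object of class `annotated_recording`.
#' @export
annotated_recording <- function(samples, fs, channel_kind = c("surface-lead-II", "cs-bipolar"),
                                annotations, ectopic_flags = NULL) {
  channel_kind <- match.arg(channel_kind)
  stop_if_not_scalar_number(fs, "fs")
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (!is.data.frame(annotations) ||
      !all(c("onset", "peak", "offset") %in% names(annotations))) {
    stop("`annotations` must be a data frame with onset, peak, offset columns",
         call. = FALSE)
  }
  ann <- annotations[, c("onset", "peak", "offset")]
  n <- nrow(ann)
  if (n > 0) {
    if (any(ann$onset >= ann$peak) || any(ann$peak >= ann$offset)) {
      stop("each annotation must satisfy onset < peak < offset", call. = FALSE)
    }
    if (n > 1 && any(ann$onset[-1] <= ann$offset[-n])) {
      stop("annotations must be non-overlapping and ordered", call. = FALSE)
    }
    if (any(ann$onset < 1)) stop("annotation indices must be >= 1", call. = FALSE)
    if (!is.null(samples) && any(ann$offset > length(samples))) {
      stop("annotation indices exceed signal length", call. = FALSE)
    }
  }
  if (is.null(ectopic_flags)) ectopic_flags <- rep(FALSE, n)
  if (length(ectopic_flags) != n) {
    stop("`ectopic_flags` must have one entry per annotation", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = fs, channel_kind = channel_kind,
         annotations = ann, ectopic_flags = as.logical(ectopic_flags)),
    class = "annotated_recording"
  )
}

#' @export
print.annotated_recording <- function(x, ...) {
  cat(sprintf("<annotated_recording> %s, fs = %g Hz, %d activations%s\n",
              x$channel_kind, x$fs, nrow(x$annotations),
              if (is.null(x$samples)) " (annotation-only)"
              else sprintf(", %d samples", length(x$samples))))
  invisible(x)
}

#' Write / read a recording's samples as CSV
#'
#' Two-column CSV (`sample_index` 0-based, `amplitude_mV`), the plain-text
#' interchange format used for cohort export.
#'
#' @param rec An [annotated_recording()] with samples.
#' @param path Output file path.
#' @export
write_recording_csv <- function(rec, path) {
  if (is.null(rec$samples)) stop("recording has no samples to write", call. = FALSE)
  df <- data.frame(sample_index = seq_along(rec$samples) - 1L,
                   amplitude_mV = rec$samples)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param fs,channel_kind Passed to [annotated_recording()] when reading.
#' @param annotations,ectopic_flags Annotations to attach on read.
#' @export
read_recording_csv <- function(path, fs, channel_kind, annotations,
                               ectopic_flags = NULL) {
  df <- read.csv(path)
  annotated_recording(df$amplitude_mV, fs, channel_kind, annotations,
                      ectopic_flags)
}

#' Write / read activation annotations as JSON lines
#'
#' One JSON object per activation with 0-based `onset`, `peak`, `offset`
#' sample indices and an `is_ectopic` flag.
#'
#' @param rec An [annotated_recording()].
#' @param path Output file path.
#' @export
write_annotations_jsonl <- function(rec, path) {
  ann <- rec$annotations
  lines <- vapply(seq_len(nrow(ann)), function(i) {
    jsonlite::toJSON(list(onset = ann$onset[i] - 1L, peak = ann$peak[i] - 1L,
                          offset = ann$offset[i] - 1L,
                          is_ectopic = rec$ectopic_flags[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_annotations_jsonl
#' @return For the reader, a list with elements `annotations` (1-based data
#'   frame) and `ectopic_flags`.
#' @export
read_annotations_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, jsonlite::fromJSON)
  data.frame(
    onset = vapply(rows, function(r) as.integer(r$onset), integer(1)) + 1L,
    peak = vapply(rows, function(r) as.integer(r$peak), integer(1)) + 1L,
    offset = vapply(rows, function(r) as.integer(r$offset), integer(1)) + 1L
  ) -> ann
  list(annotations = ann,
       ectopic_flags = vapply(rows, function(r) isTRUE(r$is_ectopic), logical(1)))
}
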
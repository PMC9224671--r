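# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Round half away from zero (for nonnegative inputs: round-half-up). Base R
# round() rounds half to even, which would make fiducial placement depend on
# parity of the sample grid.
rhu <- function(x) floor(x + 0.5)

#' Derive a reproducible child seed for one patient and phase
#'
#' One master seed spawns independent, reproducible per-patient, per-phase
#' seeds so that any single recording of a cohort can be regenerated in
#' isolation. The derivation is a fixed affine map kept within the 32-bit
#' integer range.
#'
#' @param seed Master integer seed.
#' @param patient Patient index (1-based).
#' @param phase_idx Phase index: 1 = pre, 2 = lpvi, 3 = post.
#' @return An integer seed.
#' @export
child_seed <- function(seed, patient, phase_idx) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + patient * 613 + phase_idx * 7919) %% 2147483629L
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
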
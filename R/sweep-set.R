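#' Aligned sweep ensemble
#'
#' A `sweep_set` holds one shared time base and M aligned current sweeps
#' (pA), with the protocol metadata the analysis needs: sampling interval,
#' agonist onset and pulse duration, holding potential, and the baseline /
#' analysis windows (half-open `[start, end)` intervals in ms).
#'
#' @param time_ms numeric vector of sample times (ms), strictly increasing
#'   and evenly spaced.
#' @param sweeps numeric matrix, `length(time_ms)` rows x M columns, in pA.
#' @param v_hold holding potential in mV.
#' @param t0_agonist agonist application onset (ms).
#' @param pulse_dur agonist pulse duration (ms).
#' @param baseline_window,analysis_window half-open `[start, end)` intervals
#'   in ms; the baseline window must precede `t0_agonist` and not overlap
#'   the analysis window.
#' @param labels named list of free-form condition metadata.
#' @param seed integer seed the sweeps were generated with (NA if recorded).
#' @return an object of class `sweep_set`.
#' @export
sweep_set <- function(time_ms, sweeps, v_hold,
                      t0_agonist, pulse_dur,
                      baseline_window, analysis_window,
                      labels = list(), seed = NA_integer_) {
  sweeps <- as.matrix(sweeps)
  if (nrow(sweeps) != length(time_ms))
    stop("sweeps must have one row per time point")
  dtv <- diff(time_ms)
  if (any(dtv <= 0)) stop("time base must be strictly increasing")
  if (baseline_window[2] > t0_agonist)
    stop("baseline_window must end at or before t0_agonist")
  if (baseline_window[2] > analysis_window[1])
    stop("baseline_window must not overlap analysis_window")
  structure(
    list(
      time_ms = time_ms, sweeps = sweeps, dt = dtv[1],
      v_hold = v_hold, t0_agonist = t0_agonist, pulse_dur = pulse_dur,
      baseline_window = baseline_window, analysis_window = analysis_window,
      labels = labels, seed = seed
    ),
    class = "sweep_set"
  )
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf(
    "<sweep_set> %d sweeps x %d samples (dt = %g ms, %g ms total)\n",
    ncol(x$sweeps), nrow(x$sweeps), x$dt, max(x$time_ms)))
  cat(sprintf("  v_hold = %g mV; agonist %g ms at t = %g ms; seed = %s\n",
              x$v_hold, x$pulse_dur, x$t0_agonist, as.character(x$seed)))
  if (length(x$labels))
    cat("  labels:", paste(names(x$labels), unlist(x$labels),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname sweep_set
#' @param x a `sweep_set`.
#' @export
n_sweeps <- function(x) ncol(x$sweeps)

# Index vector of samples falling in a half-open window [start, end) ms.
window_index <- function(time_ms, window) {
  which(time_ms >= window[1] & time_ms < window[2])
}

#' Per-sweep peak amplitudes
#'
#' Peak (largest-magnitude) current of each sweep within the analysis
#' window, returned as positive amplitudes in pA. Used for run-down
#' screening via [select_stable_epoch()].
#'
#' @param x a `sweep_set`.
#' @param window optional `[start, end)` ms window (defaults to the set's
#'   analysis window).
#' @return numeric vector, one amplitude per sweep.
#' @export
peak_amplitudes <- function(x, window = x$analysis_window) {
  idx <- window_index(x$time_ms, window)
  if (!length(idx)) stop("window contains no samples")
  apply(abs(x$sweeps[idx, , drop = FALSE]), 2, max)
}
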
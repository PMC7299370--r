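#' Select a stable epoch of responses by Spearman run-down screening
#'
#' Progressive run-down of the peak response violates the stationarity that
#' ensemble-variance analysis assumes. This screen finds the longest
#' contiguous run of sweeps (ties broken by earliest start) whose peak
#' amplitudes show no significant monotone trend against sweep index, judged
#' by a two-sided Spearman rank-order correlation test at level `alpha`:
#' a window qualifies when its p-value is at least `alpha`.
#'
#' @param peak_amplitudes per-sweep peak amplitudes (pA), e.g. from
#'   [peak_amplitudes()].
#' @param alpha significance level (default 0.05, two-sided).
#' @param min_len,max_len smallest and largest admissible epoch length
#'   (defaults 50 and 350 sweeps).
#' @return a `stable_epoch` object: `found` (logical), `start`, `end`
#'   (1-based inclusive sweep indices), `length`, `rho`, `p_value`. When no
#'   window qualifies, `found` is `FALSE` and the indices are `NA` — this is
#'   an explicit outcome, not an error.
#' @export
select_stable_epoch <- function(peak_amplitudes, alpha = 0.05,
                                min_len = 50, max_len = 350) {
  m <- length(peak_amplitudes)
  if (m < min_len) stop("fewer sweeps than min_len")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  for (len in seq(min(max_len, m), min_len)) {
    for (start in seq_len(m - len + 1)) {
      w <- peak_amplitudes[start:(start + len - 1)]
      sp <- spearman_trend(w)
      if (sp["p"] >= alpha) {
        return(structure(
          list(found = TRUE, start = start, end = start + len - 1,
               length = len, rho = unname(sp["rho"]),
               p_value = unname(sp["p"])),
          class = "stable_epoch"
        ))
      }
    }
  }
  structure(
    list(found = FALSE, start = NA_integer_, end = NA_integer_,
         length = 0L, rho = NA_real_, p_value = NA_real_),
    class = "stable_epoch"
  )
}

# Spearman rho of x against its index with the two-sided t-approximation
# p-value. A constant window has no trend: rho = 0, p = 1.
spearman_trend <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(c(rho = 0, p = 1))
  rho <- stats::cor(rank(x), seq_len(n))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' @export
print.stable_epoch <- function(x, ...) {
  if (x$found)
    cat(sprintf(
      "<stable_epoch> sweeps %d-%d (n = %d), Spearman rho = %.3f, p = %.3f\n",
      x$start, x$end, x$length, x$rho, x$p_value))
  else cat("<stable_epoch> no stable epoch found\n")
  invisible(x)
}

#' Pairwise ensemble variance of successive sweeps
#'
#' Computes the ensemble variance of all successive pairs of responses:
#' for difference traces `d_k = sweep_(k+1) - sweep_k` within the epoch,
#' `var(t) = sum_k d_k(t)^2 / (2 K)` with `K` the number of pairs. This
#' local estimator is insensitive to slow drift compared with the plain
#' per-time-point sample variance. The background variance `sigma_b2_hat`
#' is the time-average of the variance trace over the baseline window.
#'
#' @param x a [sweep_set()].
#' @param epoch a `stable_epoch`, a length-2 integer `c(start, end)`, or
#'   `NULL` for all sweeps.
#' @return an `ensemble_stats` object: `mean_trace`, `var_trace` (pA^2),
#'   `sigma_b2_hat`, `n_sweeps_used`, `epoch`, plus the time base and
#'   protocol metadata carried over from `x`.
#' @export
pairwise_variance <- function(x, epoch = NULL) {
  if (is.null(epoch)) {
    idx <- seq_len(n_sweeps(x))
  } else if (inherits(epoch, "stable_epoch")) {
    if (!epoch$found) stop("epoch was not found; cannot compute variance")
    idx <- epoch$start:epoch$end
  } else {
    idx <- epoch[1]:epoch[2]
  }
  if (length(idx) < 2) stop("epoch must contain at least 2 sweeps")
  sw <- x$sweeps[, idx, drop = FALSE]
  k <- ncol(sw) - 1
  d <- sw[, -1, drop = FALSE] - sw[, -ncol(sw), drop = FALSE]
  var_trace <- rowSums(d^2) / (2 * k)
  base_idx <- window_index(x$time_ms, x$baseline_window)
  structure(
    list(
      mean_trace = rowMeans(sw), var_trace = var_trace,
      sigma_b2_hat = mean(var_trace[base_idx]),
      n_sweeps_used = length(idx), epoch = range(idx),
      time_ms = x$time_ms, v_hold = x$v_hold,
      t0_agonist = x$t0_agonist, pulse_dur = x$pulse_dur,
      analysis_window = x$analysis_window
    ),
    class = "ensemble_stats"
  )
}

#' Parabolic variance-mean fit (non-stationary fluctuation analysis)
#'
#' Fits the parabola `sigma^2 = sigma_B^2 + i I - I^2 / N` to binned
#' (mean current, ensemble variance) points from the decay phase of the
#' response (peak to pulse end; the rising phase is excluded because
#' opening-latency correlations violate the binomial assumption there).
#' Points are binned into `n_bins` equal-count bins of |I| and the fit is
#' solved by count-weighted linear least squares, which is exact for this
#' model (linear in `i` and `1/N`); both regressors (I and I^2) are
#' averaged within bins so the aggregation introduces no curvature bias
#' however wide a bin is. With `fix_background = TRUE` the
#' baseline-window variance estimate is subtracted and only `(i, N)` are
#' free; otherwise `sigma_B^2` is a third free parameter.
#'
#' Derived quantities: weighted-mean single-channel conductance
#' `g = 1000 i / |V|` (pS) at the corrected holding potential, and peak
#' open probability `Po = I_peak / (i N)`.
#'
#' @param stats an `ensemble_stats` from [pairwise_variance()].
#' @param n_bins number of equal-count bins (default 10, >= 3).
#' @param fix_background subtract the baseline variance estimate (default
#'   `TRUE`) instead of fitting it.
#' @return an `nsfa_result`: `i_hat` (pA), `n_hat` (channels), `sigma_b2`
#'   (pA^2), `g_hat` (pS), `po_peak_hat`, `bins` (data frame of bin-mean
#'   current, bin-mean squared current, variance, count), `fit_sse`,
#'   `v_hold_corrected`, `ok` and `flags`.
#'   A non-convergent or negative-curvature fit returns `ok = FALSE` with
#'   the offending estimates in `flags`, not silent values.
#' @export
fit_parabola <- function(stats, n_bins = 10, fix_background = TRUE) {
  stopifnot(inherits(stats, "ensemble_stats"))
  if (n_bins < 3) stop("n_bins must be >= 3")

  ana_idx <- window_index(stats$time_ms, stats$analysis_window)
  amean <- abs(stats$mean_trace)
  peak_idx <- ana_idx[which.max(amean[ana_idx])]
  pulse_end <- stats$t0_agonist + stats$pulse_dur
  decay_idx <- peak_idx:max(window_index(stats$time_ms,
                                         c(stats$time_ms[peak_idx], pulse_end)))
  i_abs <- amean[decay_idx]
  v_obs <- stats$var_trace[decay_idx]
  i_peak <- amean[peak_idx]

  flags <- character()
  if ((max(i_abs) - min(i_abs)) < 0.5 * i_peak)
    flags <- c(flags, "mean-current span below 50% of peak")

  # Equal-count bins over |I|. The parabola is linear in I and I^2, so
  # binning is made exact by aggregating both regressors within each bin
  # (evaluating the curve at the bin-mean current alone would bias the
  # curvature for wide bins).
  ord <- order(i_abs)
  grp <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  grp <- pmin(grp, n_bins)
  bin_i <- as.vector(tapply(i_abs[ord], grp, mean))
  bin_isq <- as.vector(tapply(i_abs[ord]^2, grp, mean))
  bin_v <- as.vector(tapply(v_obs[ord], grp, mean))
  bin_n <- as.vector(table(grp))
  bins <- data.frame(mean_pA = bin_i, mean_sq_pA2 = bin_isq,
                     var_pA2 = bin_v, count = bin_n)

  if (fix_background) {
    y <- bin_v - stats$sigma_b2_hat
    fit <- stats::lm(y ~ 0 + bin_i + bin_isq, weights = bin_n)
    co <- stats::coef(fit)
    sigma_b2 <- stats$sigma_b2_hat
  } else {
    y <- bin_v
    fit <- stats::lm(y ~ bin_i + bin_isq, weights = bin_n)
    co <- stats::coef(fit)
    sigma_b2 <- unname(co[1])
    co <- co[-1]
  }
  i_hat <- unname(co[1])
  curv <- unname(co[2])          # = -1/N
  ok <- is.finite(i_hat) && is.finite(curv) && i_hat > 0 && curv < 0
  n_hat <- if (ok) -1 / curv else NA_real_
  if (!ok) flags <- c(flags, "non-positive i or non-negative curvature")

  po <- if (ok) i_peak / (i_hat * n_hat) else NA_real_
  if (ok && po > 1) flags <- c(flags, "po_peak_hat exceeds 1")
  g_hat <- if (ok) conductance_from_current(i_hat, stats$v_hold) else NA_real_

  structure(
    list(
      i_hat = i_hat, n_hat = n_hat, sigma_b2 = sigma_b2,
      g_hat = g_hat, po_peak_hat = po, i_peak = i_peak,
      bins = bins, fit_sse = sum(bins$count * stats::resid(fit)^2),
      v_hold_corrected = stats$v_hold,
      n_sweeps_used = stats$n_sweeps_used,
      fix_background = fix_background, ok = ok, flags = flags
    ),
    class = "nsfa_result"
  )
}

#' @export
print.nsfa_result <- function(x, ...) {
  cat("<nsfa_result>\n")
  if (x$ok) {
    cat(sprintf("  i = %.3f pA, N = %.1f channels, sigma_B2 = %.3f pA^2\n",
                x$i_hat, x$n_hat, x$sigma_b2))
    cat(sprintf("  g = %.2f pS at %g mV; Po,peak = %.3f (I_peak = %.1f pA)\n",
                x$g_hat, x$v_hold_corrected, x$po_peak_hat, x$i_peak))
  } else cat("  fit failed\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Weighted-mean single-channel conductance from single-channel current
#'
#' `g(pS) = 1000 * i(pA) / |V(mV)|` at the liquid-junction-corrected
#' holding potential (e.g. 0.912 pA at -55 mV gives 16.58 pS).
#'
#' @param i_hat single-channel current in pA.
#' @param v_hold_corrected corrected holding potential in mV (non-zero).
#' @return conductance in pS.
#' @export
conductance_from_current <- function(i_hat, v_hold_corrected) {
  if (v_hold_corrected == 0) stop("holding potential must be non-zero")
  1000 * i_hat / abs(v_hold_corrected)
}

#' Full NSFA chain on a sweep ensemble
#'
#' Convenience wrapper: run-down screening ([select_stable_epoch()]),
#' pairwise ensemble variance ([pairwise_variance()]) and the parabolic
#' fit ([fit_parabola()]) in one call.
#'
#' @param x a [sweep_set()].
#' @param n_bins,fix_background passed to [fit_parabola()].
#' @param alpha,min_len,max_len passed to [select_stable_epoch()];
#'   `min_len` is capped at the number of sweeps.
#' @return an `nsfa_result` with the selected `epoch` attached; if no
#'   stable epoch exists, a failed result with flag "no stable epoch".
#' @export
nsfa <- function(x, n_bins = 10, fix_background = TRUE,
                 alpha = 0.05, min_len = 50, max_len = 350) {
  ep <- select_stable_epoch(peak_amplitudes(x), alpha = alpha,
                            min_len = min(min_len, n_sweeps(x)),
                            max_len = max_len)
  if (!ep$found) {
    return(structure(
      list(i_hat = NA_real_, n_hat = NA_real_, sigma_b2 = NA_real_,
           g_hat = NA_real_, po_peak_hat = NA_real_, i_peak = NA_real_,
           bins = NULL, fit_sse = NA_real_, v_hold_corrected = x$v_hold,
           n_sweeps_used = 0L, fix_background = fix_background,
           ok = FALSE, flags = "no stable epoch", epoch = ep),
      class = "nsfa_result"
    ))
  }
  res <- fit_parabola(pairwise_variance(x, ep), n_bins = n_bins,
                      fix_background = fix_background)
  res$epoch <- ep
  res
}
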
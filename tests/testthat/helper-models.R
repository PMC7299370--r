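# Small, fast generative models and hand-built ensemble statistics used
# across the test files. All fixtures are built in code.

# A compact patch: few channels, short pulse, cheap to simulate.
tiny_model <- function(...) {
  args <- list(
    n_channels = 50, conductance = 20, v_hold = -55, po_peak = 0.6,
    tau_rise = 0.2, tau_f_des = 1.5, tau_s_des = 6, frac_fast = 0.8,
    ss_fraction = 0.05, tau_recovery = 40, sigma_b2 = 0.5,
    label = "tiny"
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(channel_model, args)
}

# Exact ensemble statistics following the parabola sigma^2 = s_b2 + iI - I^2/N,
# with an exponentially decaying mean trace (no sampling noise anywhere).
exact_parabola_stats <- function(i = 1, n_ch = 100, sigma_b2 = 0,
                                 i_peak = 0.9 * i * n_ch,
                                 tau = 3, t_end = 30, dt = 0.02) {
  time_ms <- seq(0, t_end, by = dt)
  mean_tr <- -i_peak * exp(-time_ms / tau)   # inward current, peak at t = 0
  iabs <- abs(mean_tr)
  structure(
    list(
      mean_trace = mean_tr,
      var_trace = sigma_b2 + i * iabs - iabs^2 / n_ch,
      sigma_b2_hat = sigma_b2, n_sweeps_used = 100L, epoch = c(1L, 100L),
      time_ms = time_ms, v_hold = -55, t0_agonist = 0, pulse_dur = t_end,
      analysis_window = c(0, t_end)
    ),
    class = "ensemble_stats"
  )
}

# Independent epoch-selection oracle: exhaustive scan of every contiguous
# window, using stats::cor.test as the Spearman p-value reference,
# longest-then-earliest.
brute_force_epoch <- function(peaks, alpha = 0.05, min_len = 50,
                              max_len = 350) {
  m <- length(peaks)
  for (len in seq(min(max_len, m), min_len)) {
    for (start in seq_len(m - len + 1)) {
      w <- peaks[start:(start + len - 1)]
      p <- if (stats::sd(w) == 0) 1 else
        suppressWarnings(stats::cor.test(w, seq_along(w),
                                         method = "spearman",
                                         exact = FALSE)$p.value)
      if (p >= alpha) return(c(start = start, end = start + len - 1))
    }
  }
  NULL
}

# Profile SSE of the single-exponential recovery model for a fixed tau
# (amplitude solved by linear least squares).
recovery_profile_sse <- function(tau, dt, r) {
  x <- exp(-dt / tau)
  a <- sum(x * (1 - r)) / sum(x^2)
  sum((r - (1 - a * x))^2)
}

# Sample indices of a half-open [start, end) ms window of a sweep_set.
window_index_for_tests <- function(s, w) {
  which(s$time_ms >= w[1] & s$time_ms < w[2])
}
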
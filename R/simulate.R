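#' Deterministic open-probability waveform of a channel model
#'
#' The gating waveform `p(t)` around which channels fluctuate: zero before
#' agonist onset, an exponential rise (time constant `tau_rise`) that
#' completes at `5 * tau_rise`, then a bi-exponential desensitization decay
#' from `po_peak` toward the steady-state plateau
#' `po_peak * ss_fraction`, and zero after agonist removal. The decay clock
#' starts at the peak, so the amplitude shares of the two components over
#' the decay phase are exactly `frac_fast` and `1 - frac_fast` and the
#' decay's amplitude-weighted time constant equals
#' `frac_fast * tau_f_des + (1 - frac_fast) * tau_s_des`.
#'
#' @param model a [channel_model()].
#' @param time_ms sample times (ms).
#' @param t0 agonist onset (ms).
#' @param pulse_dur agonist pulse duration (ms).
#' @return numeric vector of open probabilities, same length as `time_ms`.
#' @export
open_probability_waveform <- function(model, time_ms, t0, pulse_dur) {
  tp <- 5 * model$tau_rise  # rise essentially complete (99.3%)
  tr <- time_ms - t0
  p <- numeric(length(time_ms))
  rising <- tr >= 0 & tr < pmin(tp, pulse_dur)
  p[rising] <- model$po_peak *
    (1 - exp(-tr[rising] / model$tau_rise)) / (1 - exp(-tp / model$tau_rise))
  decaying <- tr >= tp & tr < pulse_dur
  s <- tr[decaying] - tp
  f <- model$frac_fast
  p[decaying] <- model$po_peak *
    (model$ss_fraction + (1 - model$ss_fraction) *
       (f * exp(-s / model$tau_f_des) + (1 - f) * exp(-s / model$tau_s_des)))
  p
}

# Empirical Boltzmann factor attenuating outward current; identity for
# V <= 0 or when block is disabled.
block_factor <- function(model, v_mV) {
  if (is.null(model$block_v50) || v_mV <= 0) return(1)
  1 / (1 + exp((v_mV - model$block_v50) / model$block_slope))
}

# Draw the stochastic sweep matrix for a given waveform. Channels gate as
# independent binomial occupancy around p(t); Gaussian baseline noise is
# added everywhere. `i_signed` is the signed single-channel current (pA).
draw_sweeps <- function(model, p, n_sweeps_total, i_signed) {
  n_t <- length(p)
  cur <- matrix(stats::rnorm(n_t * n_sweeps_total, 0, sqrt(model$sigma_b2)),
                n_t, n_sweeps_total)
  active <- which(p > 0)
  if (length(active)) {
    for (k in seq_len(n_sweeps_total)) {
      pk <- p[active] * (1 - model$rundown_per_sweep)^(k - 1)
      cur[active, k] <- cur[active, k] +
        i_signed * stats::rbinom(length(active), model$n_channels, pk)
    }
  }
  cur
}

#' Simulate an ensemble of agonist-evoked sweeps
#'
#' Repeated agonist applications onto a patch described by a
#' [channel_model()]. At each time point the number of open channels is
#' drawn as `Binomial(n_channels, p(t))` independently across sweeps; the
#' current is `i * n_open` plus Gaussian baseline noise of variance
#' `sigma_b2`. Optional multiplicative run-down scales `p(t)` by
#' `(1 - rundown_per_sweep)^(k-1)` on sweep `k`. The ensemble variance
#' therefore follows the parabolic law
#' `sigma^2(t) = sigma_b2 + i * I(t) - I(t)^2 / N` that non-stationary
#' fluctuation analysis fits.
#'
#' @param model a [channel_model()].
#' @param pulse_dur agonist pulse duration in ms (default 100).
#' @param n_sweeps number of sweeps (>= 2).
#' @param seed integer RNG seed; identical arguments give an identical
#'   `sweep_set`.
#' @param dt sampling interval in ms (default 0.05, i.e. 20 kHz).
#' @param baseline_ms pre-agonist baseline duration (default 10 ms).
#' @param tail_ms post-pulse duration (default 20 ms).
#' @return a [sweep_set()].
#' @examples
#' m <- ampar_preset("CP_0T", n_channels = 50, sigma_b2 = 0.5)
#' s <- simulate_sweeps(m, pulse_dur = 30, n_sweeps = 20, seed = 1)
#' s
#' @export
simulate_sweeps <- function(model, pulse_dur = 100, n_sweeps, seed,
                            dt = 0.05, baseline_ms = 10, tail_ms = 20) {
  validate_channel_model(model)
  if (dt <= 0) stop("dt must be positive")
  if (n_sweeps < 2) stop("n_sweeps must be >= 2")
  t_total <- baseline_ms + pulse_dur + tail_ms
  time_ms <- seq(0, t_total, by = dt)
  t0 <- baseline_ms
  p <- open_probability_waveform(model, time_ms, t0, pulse_dur)

  set.seed(seed)
  i_signed <- model$conductance * model$v_hold / 1000
  cur <- draw_sweeps(model, p, n_sweeps, i_signed)
  colnames(cur) <- sprintf("sweep_%04d", seq_len(n_sweeps))

  sweep_set(
    time_ms, cur, v_hold = model$v_hold,
    t0_agonist = t0, pulse_dur = pulse_dur,
    baseline_window = c(0, t0),
    analysis_window = c(t0, t0 + pulse_dur),
    labels = list(condition = model$label), seed = seed
  )
}

#' Simulate a two-pulse recovery-from-desensitization protocol
#'
#' For each inter-pulse interval (onset-to-onset, ms) a `sweep_set` is
#' generated containing two agonist pulses. The second pulse re-uses the
#' first-pulse waveform scaled by the recovered fraction
#' `1 - (1 - ss_fraction) * exp(-dt / tau_recovery)`, so the expected
#' peak ratio P2/P1 follows a single-exponential recovery toward 1.
#'
#' @param model a [channel_model()].
#' @param intervals positive, sorted onset-to-onset intervals in ms; each
#'   must be at least `pulse_dur` (shorter intervals would overlap pulses).
#' @param pulse_dur pulse duration in ms (default 20).
#' @param sweeps_per_interval sweeps per interval (>= 2).
#' @param seed integer RNG seed.
#' @param dt sampling interval in ms.
#' @return a named list of [sweep_set()]s, one per interval, with the
#'   interval recorded in `labels$interval_ms`.
#' @export
simulate_two_pulse <- function(model, intervals, pulse_dur = 20,
                               sweeps_per_interval, seed, dt = 0.05) {
  validate_channel_model(model)
  if (any(intervals <= 0) || is.unsorted(intervals))
    stop("intervals must be positive and sorted")
  if (any(intervals < pulse_dur))
    stop("interval shorter than pulse_dur: pulses would overlap")
  baseline_ms <- 5
  set.seed(seed)
  i_signed <- model$conductance * model$v_hold / 1000
  out <- lapply(intervals, function(gap) {
    t0 <- baseline_ms
    t2 <- t0 + gap
    t_total <- t2 + pulse_dur + 10
    time_ms <- seq(0, t_total, by = dt)
    p1 <- open_probability_waveform(model, time_ms, t0, pulse_dur)
    p2 <- open_probability_waveform(model, time_ms, t2, pulse_dur)
    recovered <- 1 - (1 - model$ss_fraction) * exp(-gap / model$tau_recovery)
    p <- pmin(p1 + recovered * p2, 1)
    cur <- draw_sweeps(model, p, sweeps_per_interval, i_signed)
    colnames(cur) <- sprintf("sweep_%04d", seq_len(sweeps_per_interval))
    sweep_set(
      time_ms, cur, v_hold = model$v_hold,
      t0_agonist = t0, pulse_dur = pulse_dur,
      baseline_window = c(0, t0),
      analysis_window = c(t0, t0 + pulse_dur),
      labels = list(condition = model$label, interval_ms = gap,
                    t0_pulse2 = t2),
      seed = seed
    )
  })
  names(out) <- sprintf("dt_%g", intervals)
  out
}

#' Simulate a current-voltage family
#'
#' One sweep ensemble per holding potential. Driving current scales
#' linearly with voltage (reversal at 0 mV); for positive potentials it is
#' additionally multiplied by the model's empirical Boltzmann block factor
#' `b(V) = 1 / (1 + exp((V - block_v50) / block_slope))` (identity when
#' block is disabled), emulating intracellular polyamine block of
#' calcium-permeable receptors.
#'
#' @param model a [channel_model()].
#' @param voltages holding potentials in mV (0 allowed; zero current).
#' @param n_sweeps sweeps per voltage (>= 2).
#' @param seed integer RNG seed.
#' @param pulse_dur pulse duration in ms (default 100).
#' @param dt sampling interval in ms.
#' @return a named list of [sweep_set()]s keyed `"V_<mV>"`.
#' @export
simulate_iv <- function(model, voltages = seq(-80, 80, by = 20), n_sweeps,
                        seed, pulse_dur = 100, dt = 0.05) {
  validate_channel_model(model)
  if (!length(voltages)) stop("voltages must be non-empty")
  baseline_ms <- 10
  t_total <- baseline_ms + pulse_dur + 20
  time_ms <- seq(0, t_total, by = dt)
  p <- open_probability_waveform(model, time_ms, baseline_ms, pulse_dur)
  set.seed(seed)
  out <- lapply(voltages, function(v) {
    i_signed <- model$conductance * v / 1000 * block_factor(model, v)
    cur <- draw_sweeps(model, p, n_sweeps, i_signed)
    colnames(cur) <- sprintf("sweep_%04d", seq_len(n_sweeps))
    sweep_set(
      time_ms, cur, v_hold = v,
      t0_agonist = baseline_ms, pulse_dur = pulse_dur,
      baseline_window = c(0, baseline_ms),
      analysis_window = c(baseline_ms, baseline_ms + pulse_dur),
      labels = list(condition = model$label, voltage_mV = v), seed = seed
    )
  })
  names(out) <- sprintf("V_%g", voltages)
  out
}

#' Ensemble mean trace
#'
#' @param x a [sweep_set()].
#' @param sweeps optional sweep indices to average (default all).
#' @return numeric vector of mean current (pA) per time point.
#' @export
mean_trace <- function(x, sweeps = seq_len(n_sweeps(x))) {
  rowMeans(x$sweeps[, sweeps, drop = FALSE])
}
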
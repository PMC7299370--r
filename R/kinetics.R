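#' Amplitude-weighted time constant of a two-component exponential
#'
#' `tau_w = tau_f * A_f / (A_f + A_s) + tau_s * A_s / (A_f + A_s)`, the
#' summary used for both desensitization and recovery kinetics.
#'
#' @param tau_f,tau_s fast and slow time constants (ms).
#' @param a_f,a_s corresponding amplitudes (same units; signs ignored).
#' @return weighted time constant in ms.
#' @export
weighted_tau <- function(tau_f, tau_s, a_f, a_s) {
  a_f <- abs(a_f); a_s <- abs(a_s)
  unname((tau_f * a_f + tau_s * a_s) / (a_f + a_s))
}

#' Bi-exponential desensitization fit with weighted time constant
#'
#' Fits `A_f exp(-(t - t_peak)/tau_f) + A_s exp(-(t - t_peak)/tau_s) + C`
#' to the decaying segment `[t_peak, t_end)` of a mean current trace by
#' nonlinear least squares, and summarises it with the amplitude-weighted
#' time constant. When the two components are degenerate (time-constant
#' ratio < 1.2 or a component's amplitude share < 2%) the fit falls back to
#' a single exponential and reports `tau_w = tau`; the fallback is recorded
#' in `flags`.
#'
#' @param time_ms sample times (ms).
#' @param trace mean current (pA; sign is handled internally).
#' @param t_peak,t_end fit window bounds (ms), `t_peak < t_end`. Defaults:
#'   `t_peak` at the trace's absolute peak, `t_end` at the last sample.
#' @return a `kinetics_fit`: `tau_f`, `tau_s`, `a_f`, `a_s` (pA), `tau_w`
#'   (ms), `ss_level` (fitted plateau, pA), `n_components`, `fit_window`,
#'   `ok`, `flags`. A non-decaying segment yields `ok = FALSE`.
#' @export
fit_desensitization <- function(time_ms, trace, t_peak = NULL, t_end = NULL) {
  y_all <- abs(trace)
  if (is.null(t_peak)) t_peak <- time_ms[which.max(y_all)]
  if (is.null(t_end)) t_end <- time_ms[length(time_ms)] + 1e-9
  if (t_peak >= t_end) stop("t_peak must precede t_end")
  idx <- which(time_ms >= t_peak & time_ms < t_end)
  if (length(idx) < 5) stop("decaying segment is empty or too short")
  t <- time_ms[idx] - time_ms[idx[1]]
  y <- y_all[idx]

  fail <- function(why) structure(
    list(tau_f = NA_real_, tau_s = NA_real_, a_f = NA_real_, a_s = NA_real_,
         tau_w = NA_real_, ss_level = NA_real_, n_components = 0L,
         fit_window = c(t_peak, t_end), ok = FALSE, flags = why),
    class = "kinetics_fit")

  peak <- y[1]
  tail_lvl <- mean(y[t >= 0.9 * max(t)])
  if (peak - tail_lvl <= 0 || stats::cor(t, y) > 0)
    return(fail("segment does not decay"))

  # starts: split the decaying amplitude, bracket the 1/e crossing
  amp <- peak - tail_lvl
  t_e <- t[which.min(abs(y - (tail_lvl + amp * exp(-1))))]
  t_e <- max(t_e, t[2])
  start2 <- list(af = 0.6 * amp, tf = t_e / 2, as = 0.4 * amp, ts = 2 * t_e,
                 c = tail_lvl)
  fit2 <- tryCatch(
    minpack.lm::nlsLM(
      y ~ af * exp(-t / tf) + as * exp(-t / ts) + c,
      start = start2,
      lower = c(af = 0, tf = 1e-4, as = 0, ts = 1e-4, c = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  flags <- character()
  use_single <- is.null(fit2)
  if (!use_single) {
    co <- stats::coef(fit2)
    tf <- min(co["tf"], co["ts"]); ts <- max(co["tf"], co["ts"])
    af <- if (co["tf"] <= co["ts"]) co["af"] else co["as"]
    as_ <- if (co["tf"] <= co["ts"]) co["as"] else co["af"]
    share_f <- af / (af + as_)
    if (ts / tf < 1.2 || min(share_f, 1 - share_f) < 0.02) {
      use_single <- TRUE
      flags <- c(flags, "degenerate two-component fit; single-exponential fallback")
    }
  }
  if (use_single) {
    fit1 <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * exp(-t / tau) + c,
        start = list(a = amp, tau = t_e, c = tail_lvl),
        lower = c(a = 0, tau = 1e-4, c = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit1)) return(fail("exponential fit did not converge"))
    co <- stats::coef(fit1)
    return(structure(
      list(tau_f = unname(co["tau"]), tau_s = unname(co["tau"]),
           a_f = unname(co["a"]), a_s = 0, tau_w = unname(co["tau"]),
           ss_level = unname(co["c"]), n_components = 1L,
           fit_window = c(t_peak, t_end), ok = TRUE, flags = flags),
      class = "kinetics_fit"))
  }
  structure(
    list(tau_f = unname(tf), tau_s = unname(ts),
         a_f = unname(af), a_s = unname(as_),
         tau_w = weighted_tau(tf, ts, af, as_),
         ss_level = unname(co["c"]), n_components = 2L,
         fit_window = c(t_peak, t_end), ok = TRUE, flags = flags),
    class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("<kinetics_fit>")
  if (!x$ok) { cat(" failed:", x$flags, "\n"); return(invisible(x)) }
  if (x$n_components == 2L)
    cat(sprintf(
      "\n  tau_f = %.3g ms (A = %.3g pA), tau_s = %.3g ms (A = %.3g pA)\n  tau_w = %.3g ms, plateau = %.3g pA\n",
      x$tau_f, x$a_f, x$tau_s, x$a_s, x$tau_w, x$ss_level))
  else
    cat(sprintf(" single exponential: tau = %.3g ms, plateau = %.3g pA\n",
                x$tau_f, x$ss_level))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Rise time of current activation
#'
#' Default mode `"10-90"`: time between the 10% and 90% crossings of the
#' peak amplitude on the rising limb, by linear interpolation. Mode
#' `"onset-peak"`: time from onset (first crossing of `onset_frac` of peak,
#' default 5%) to the peak sample.
#'
#' @param time_ms sample times (ms).
#' @param trace current trace (pA).
#' @param mode `"10-90"` or `"onset-peak"`.
#' @param onset_frac onset threshold as a fraction of peak (onset-peak mode).
#' @return rise time in ms.
#' @export
rise_time <- function(time_ms, trace, mode = c("10-90", "onset-peak"),
                      onset_frac = 0.05) {
  mode <- match.arg(mode)
  y <- abs(trace)
  ipk <- which.max(y)
  if (ipk == 1) stop("peak at first sample; no rising limb")
  peak <- y[ipk]
  cross <- function(level) {
    k <- which(y[1:ipk] >= level)[1]
    if (is.na(k)) stop("threshold not crossed")
    if (k == 1) return(time_ms[1])
    # linear interpolation between samples k-1 and k
    t0 <- time_ms[k - 1]; t1 <- time_ms[k]
    y0 <- y[k - 1]; y1 <- y[k]
    t0 + (level - y0) / (y1 - y0) * (t1 - t0)
  }
  if (mode == "10-90") cross(0.9 * peak) - cross(0.1 * peak)
  else time_ms[ipk] - cross(onset_frac * peak)
}

#' Steady-state current as a percentage of peak
#'
#' `100 * mean(|I|) over the window / |I_peak|`, with the window placed
#' late in the pulse after desensitization has equilibrated (default
#' convention: the last 10 ms of a 100-ms pulse).
#'
#' @param time_ms sample times (ms).
#' @param trace current trace (pA).
#' @param window half-open `[start, end)` window in ms.
#' @return steady-state percentage of peak.
#' @export
steady_state_percent <- function(time_ms, trace, window) {
  idx <- window_index(time_ms, window)
  if (!length(idx)) stop("steady-state window contains no samples")
  y <- abs(trace)
  100 * mean(y[idx]) / max(y)
}

#' Fit recovery from desensitization
#'
#' Fits the paired-pulse ratio against inter-pulse interval. Single mode
#' (default): `P2/P1 = 1 - A exp(-dt / tau_rec)`. Double mode: the
#' two-component analogue, summarised by the amplitude-weighted time
#' constant. When every ratio is already ~1 the time constant is below the
#' protocol's resolution and is flagged rather than reported.
#'
#' @param intervals inter-pulse intervals (ms), >= 4 points.
#' @param p2_over_p1 paired-pulse peak ratios.
#' @param mode `"single"` or `"double"`.
#' @return a `recovery_fit`: `intervals`, `p2_over_p1`, `tau_rec` (ms),
#'   `amplitude` (A, the blocked fraction extrapolated to dt = 0), `mode`,
#'   `ok`, `flags`.
#' @export
fit_recovery <- function(intervals, p2_over_p1,
                         mode = c("single", "double")) {
  mode <- match.arg(mode)
  if (length(intervals) < 4) stop("need at least 4 interval points")
  if (length(intervals) != length(p2_over_p1))
    stop("intervals and ratios differ in length")
  base <- list(intervals = intervals, p2_over_p1 = p2_over_p1, mode = mode)
  if (all(abs(p2_over_p1 - 1) < 0.02)) {
    return(structure(
      c(base, list(tau_rec = NA_real_, amplitude = 0, ok = FALSE,
                   flags = "full recovery at all intervals; tau below resolution")),
      class = "recovery_fit"))
  }
  dt <- intervals; r <- p2_over_p1
  a0 <- max(min(1 - min(r), 1), 0.05)
  # interval nearest half recovery as a tau start
  t0 <- dt[which.min(abs(r - (1 - a0 / 2)))]
  if (mode == "single") {
    fit <- tryCatch(
      minpack.lm::nlsLM(r ~ 1 - a * exp(-dt / tau),
                        start = list(a = a0, tau = max(t0, min(dt))),
                        lower = c(a = 0, tau = 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit))
      return(structure(c(base, list(tau_rec = NA_real_, amplitude = NA_real_,
                                    ok = FALSE, flags = "fit did not converge")),
                       class = "recovery_fit"))
    co <- stats::coef(fit)
    return(structure(
      c(base, list(tau_rec = unname(co["tau"]), amplitude = unname(co["a"]),
                   ok = TRUE, flags = character())),
      class = "recovery_fit"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ 1 - af * exp(-dt / tf) - as * exp(-dt / ts),
      start = list(af = 0.6 * a0, tf = max(t0 / 2, min(dt) / 2),
                   as = 0.4 * a0, ts = 2 * max(t0, min(dt))),
      lower = c(af = 0, tf = 1e-3, as = 0, ts = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(c(base, list(tau_rec = NA_real_, amplitude = NA_real_,
                                  ok = FALSE, flags = "fit did not converge")),
                     class = "recovery_fit"))
  co <- stats::coef(fit)
  structure(
    c(base, list(
      tau_rec = weighted_tau(unname(co["tf"]), unname(co["ts"]),
                             unname(co["af"]), unname(co["as"])),
      amplitude = unname(co["af"] + co["as"]),
      ok = TRUE, flags = character())),
    class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat("<recovery_fit>", x$mode, "mode;")
  if (x$ok)
    cat(sprintf(" tau_rec = %.2f ms (A = %.2f), %d intervals\n",
                x$tau_rec, x$amplitude, length(x$intervals)))
  else cat(" not fitted:", x$flags, "\n")
  invisible(x)
}

#' Paired-pulse ratio from a two-pulse sweep set
#'
#' Peak of the mean trace in each pulse window; P2 is measured from the
#' second pulse onset (stored by [simulate_two_pulse()] in
#' `labels$t0_pulse2`, or supplied explicitly).
#'
#' @param x a two-pulse [sweep_set()].
#' @param t0_pulse2 onset of the second pulse (ms).
#' @return named vector `c(p1, p2, ratio)` (amplitudes in pA).
#' @export
paired_pulse_ratio <- function(x, t0_pulse2 = x$labels$t0_pulse2) {
  if (is.null(t0_pulse2)) stop("second-pulse onset unknown")
  m <- abs(mean_trace(x))
  w1 <- window_index(x$time_ms, c(x$t0_agonist, x$t0_agonist + x$pulse_dur))
  w2 <- window_index(x$time_ms, c(t0_pulse2, t0_pulse2 + x$pulse_dur))
  p1 <- max(m[w1]); p2 <- max(m[w2])
  c(p1 = p1, p2 = p2, ratio = p2 / p1)
}

#' Percent block of a current by a drug
#'
#' `100 * (1 - I_drug / I_control)`. A drug current larger than control
#' yields a negative block with a warning.
#'
#' @param i_control,i_drug peak currents (pA), same sign (or `i_drug = 0`).
#' @return percent block.
#' @export
percent_block <- function(i_control, i_drug) {
  if (i_control == 0) stop("control current must be non-zero")
  if (i_drug != 0 && sign(i_drug) != sign(i_control))
    stop("drug and control currents must share a sign")
  pb <- 100 * (1 - i_drug / i_control)
  if (pb < 0) warning("drug current exceeds control: negative block")
  pb
}
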
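test_that("weighted tau follows the amplitude-weighted formula", {
  expect_equal(weighted_tau(1.7, 5, 3, 0), 1.7)       # single component
  expect_equal(weighted_tau(1, 3, 2, 2), 2)           # equal amplitudes
  expect_equal(weighted_tau(2, 8, 1, 3), (2 + 24) / 4)
  # monotone non-decreasing in the slow-component weight for tau_f < tau_s
  shares <- seq(0, 1, by = 0.1)
  tw <- vapply(shares, function(w) weighted_tau(1, 5, 1 - w, w), numeric(1))
  expect_true(all(diff(tw) >= 0))
})

test_that("noiseless bi-exponentials are recovered to < 1% relative", {
  tm <- seq(0, 60, by = 0.02)
  cases <- expand.grid(tau_f = c(1, 2.5), ratio = c(2, 4),
                       share_f = c(0.3, 0.6, 0.85))
  for (k in seq_len(nrow(cases))) {
    tf <- cases$tau_f[k]; ts <- tf * cases$ratio[k]; sf <- cases$share_f[k]
    y <- -(100 * sf * exp(-tm / tf) + 100 * (1 - sf) * exp(-tm / ts) + 5)
    fit <- fit_desensitization(tm, y, t_peak = 0)
    expect_true(fit$ok)
    expect_equal(fit$n_components, 2L)
    expect_equal(fit$tau_f, tf, tolerance = 0.01)
    expect_equal(fit$tau_s, ts, tolerance = 0.01)
    expect_equal(fit$a_f / (fit$a_f + fit$a_s), sf, tolerance = 0.01)
    expect_equal(fit$tau_w, weighted_tau(tf, ts, sf, 1 - sf),
                 tolerance = 0.01)
  }
})

test_that("pure single exponentials fall back and report tau_w = tau", {
  tm <- seq(0, 40, by = 0.02)
  y <- 80 * exp(-tm / 3) + 2
  fit <- fit_desensitization(tm, y, t_peak = 0)
  expect_true(fit$ok)
  expect_equal(fit$n_components, 1L)
  expect_equal(fit$tau_w, 3, tolerance = 0.01)
  # non-decaying segment is a flagged failure, not an exception
  bad <- fit_desensitization(tm, tm * 0.5 + 1, t_peak = 0)
  expect_false(bad$ok)
  expect_error(fit_desensitization(tm, y, t_peak = 10, t_end = 5))
})

test_that("rise time: linear ramp, exponential closed form, error cases", {
  tm <- seq(0, 3, by = 0.001)
  ramp <- pmin(tm, 1) * 100             # 0 -> peak over 1 ms
  expect_equal(rise_time(tm, ramp, mode = "10-90"), 0.8, tolerance = 1e-3)
  expo <- 1 - exp(-tm / 0.2)            # tau = 0.2 ms rise
  expect_equal(rise_time(tm, expo, mode = "10-90"), log(9) * 0.2,
               tolerance = 0.02)
  expect_gt(rise_time(tm, expo, mode = "onset-peak"),
            rise_time(tm, expo, mode = "10-90"))
  expect_error(rise_time(tm, rev(ramp)))  # peak at the first sample

  # simulated mean rise matches the noiseless waveform's rise time
  m <- ampar_preset("CP_0T", n_channels = 400)
  s <- simulate_sweeps(m, pulse_dur = 20, n_sweeps = 200, seed = 3)
  p <- open_probability_waveform(m, s$time_ms, s$t0_agonist, s$pulse_dur)
  rt_true <- rise_time(s$time_ms, p)
  rt_sim <- rise_time(s$time_ms, mean_trace(s))
  expect_equal(rt_sim, rt_true, tolerance = 0.1)
})

test_that("steady-state percentage: limits and window contract", {
  tm <- seq(0, 100, by = 0.1)
  expect_equal(steady_state_percent(tm, rep(-50, length(tm)), c(90, 100)), 100)
  decay <- -100 * exp(-tm / 2)
  expect_lt(steady_state_percent(tm, decay, c(90, 100)), 1e-4)
  expect_error(steady_state_percent(tm, decay, c(200, 210)))
})

test_that("recovery fit: exact identifiability, resolution flag, grid oracle", {
  dt <- c(20, 40, 70, 120, 200, 320, 480, 720)
  r_exact <- 1 - exp(-dt / 100)
  fit <- fit_recovery(dt, r_exact)
  expect_true(fit$ok)
  expect_equal(fit$tau_rec, 100, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)

  flat <- fit_recovery(dt, rep(1, 8))
  expect_false(flat$ok)
  expect_match(flat$flags, "resolution")
  expect_error(fit_recovery(c(10, 20, 30), c(0.5, 0.7, 0.9)))

  # noisy curve: fitted tau matches a 1-D profile-SSE scan
  set.seed(8)
  r_noisy <- pmin(1 - 0.9 * exp(-dt / 80) + rnorm(8, 0, 0.02), 1)
  fit_n <- fit_recovery(dt, r_noisy)
  taus <- seq(40, 160, by = 0.1)
  sses <- vapply(taus, recovery_profile_sse, numeric(1), dt = dt, r = r_noisy)
  expect_equal(fit_n$tau_rec, taus[which.min(sses)], tolerance = 0.005)

  # double mode on a genuinely two-component curve reports the weighted tau
  r2 <- 1 - 0.5 * exp(-dt / 30) - 0.5 * exp(-dt / 200)
  fit2 <- fit_recovery(dt, r2, mode = "double")
  expect_true(fit2$ok)
  expect_equal(fit2$tau_rec, weighted_tau(30, 200, 0.5, 0.5),
               tolerance = 0.01)
})

test_that("simulated paired-pulse ratios are monotone and near 1 at 720 ms", {
  m <- ampar_preset("CP_0T", n_channels = 200)  # slowest-recovering condition
  dt <- c(20, 120, 720)
  tp <- simulate_two_pulse(m, intervals = dt, sweeps_per_interval = 15,
                           seed = 6)
  ratios <- vapply(tp, function(s) paired_pulse_ratio(s)[["ratio"]],
                   numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_gt(ratios[3], 0.95)
})

test_that("percent block arithmetic and guards", {
  expect_equal(percent_block(-200, 0), 100)
  expect_equal(percent_block(-200, -200), 0)
  expect_equal(percent_block(-200, -105.3), 47.35)
  expect_warning(pb <- percent_block(-100, -120))
  expect_lt(pb, 0)
  expect_error(percent_block(0, -10))
  expect_error(percent_block(-100, 50))
})
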
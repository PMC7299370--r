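test_that("model invariants and presets hold", {
  m <- ampar_preset("CP_0T")
  expect_equal(m$conductance, 16.58)
  expect_equal(m$po_peak, 0.54)
  expect_equal(single_channel_current(m), 16.58 * 55 / 1000, tolerance = 1e-12)
  expect_equal(single_channel_current(m), 0.912, tolerance = 1e-3)
  expect_equal(ampar_preset("CI_0T")$conductance, 5.13)
  expect_equal(model_tau_w(ampar_preset("CP_4T")), 6.70, tolerance = 1e-9)
  # decay components are solved to reproduce each preset's weighted tau
  for (cc in ampar_conditions()) {
    m <- ampar_preset(cc)
    expect_equal(model_tau_w(m),
                 preset_truth()$tau_w_ms[preset_truth()$condition == cc],
                 tolerance = 1e-9)
  }
  expect_error(ampar_preset("CP_1T"))
  expect_error(channel_model(conductance = 10, po_peak = 1.2,
                             tau_f_des = 1, tau_s_des = 4))
  expect_error(channel_model(conductance = 10, po_peak = 0.5,
                             tau_f_des = -1, tau_s_des = 4))
  expect_error(simulate_sweeps(tiny_model(), n_sweeps = 10, seed = 1, dt = 0))
  expect_error(simulate_sweeps(tiny_model(), n_sweeps = 1, seed = 1))
})

test_that("a degenerate single channel passes exactly i during the pulse", {
  m <- channel_model(n_channels = 1, conductance = 20, v_hold = -50,
                     po_peak = 1, tau_rise = 0.05, tau_f_des = 1,
                     tau_s_des = 4, ss_fraction = 1, sigma_b2 = 0)
  s <- simulate_sweeps(m, pulse_dur = 10, n_sweeps = 5, seed = 3,
                       baseline_ms = 2, tail_ms = 2)
  i_signed <- 20 * -50 / 1000
  on <- s$time_ms >= s$t0_agonist + 5 * m$tau_rise &
    s$time_ms < s$t0_agonist + s$pulse_dur
  off <- s$time_ms < s$t0_agonist | s$time_ms >= s$t0_agonist + s$pulse_dur
  expect_true(all(s$sweeps[on, ] == i_signed))
  expect_true(all(s$sweeps[off, ] == 0))
})

test_that("identical model, protocol and seed give bit-identical sweeps", {
  m <- tiny_model()
  a <- simulate_sweeps(m, pulse_dur = 20, n_sweeps = 10, seed = 11)
  b <- simulate_sweeps(m, pulse_dur = 20, n_sweeps = 10, seed = 11)
  expect_identical(a, b)
  c2 <- simulate_sweeps(m, pulse_dur = 20, n_sweeps = 10, seed = 12)
  expect_false(identical(a$sweeps, c2$sweeps))
})

test_that("ensemble variance follows the analytic binomial parabola", {
  m <- ampar_preset("CP_0T", n_channels = 200)
  s <- simulate_sweeps(m, pulse_dur = 30, n_sweeps = 1000, seed = 5,
                       dt = 0.1, tail_ms = 5)
  st <- pairwise_variance(s)
  idx <- window_index_for_tests(s, c(s$t0_agonist, s$t0_agonist + 30))
  iabs <- abs(st$mean_trace[idx])
  pred <- m$sigma_b2 + single_channel_current(m) * iabs - iabs^2 / m$n_channels
  sel <- iabs > 0.1 * max(iabs)
  rel_err <- abs(st$var_trace[idx][sel] - pred[sel]) / pred[sel]
  expect_lt(mean(rel_err), 0.05)

  # mean peak current converges on i * N * po_peak
  i_nk_po <- single_channel_current(m) * m$n_channels * m$po_peak
  peak_hat <- max(abs(st$mean_trace))
  sem <- sqrt(max(pred) / n_sweeps(s))
  expect_lt(abs(peak_hat - i_nk_po), 3 * sem + 0.01 * i_nk_po)
})

test_that("multiplicative run-down attenuates later sweeps as (1-r)^k", {
  m <- channel_model(n_channels = 4000, conductance = 20, v_hold = -55,
                     po_peak = 0.5, tau_rise = 0.1, tau_f_des = 1,
                     tau_s_des = 4, ss_fraction = 1, sigma_b2 = 0,
                     rundown_per_sweep = 0.005)
  s <- simulate_sweeps(m, pulse_dur = 5, n_sweeps = 200, seed = 7,
                       baseline_ms = 2, tail_ms = 2)
  pk <- peak_amplitudes(s)
  expect_equal(unname(pk[200] / pk[1]), (1 - 0.005)^199, tolerance = 0.05)
})

test_that("two-pulse protocol reproduces the closed-form recovery", {
  # near-instant recovery: all ratios ~1
  m_fast <- tiny_model(tau_recovery = 1e-6, sigma_b2 = 0,
                       n_channels = 2000)
  tp <- simulate_two_pulse(m_fast, intervals = c(30, 60, 120, 400),
                           sweeps_per_interval = 5, seed = 1)
  ratios <- vapply(tp, function(s) paired_pulse_ratio(s)[["ratio"]],
                   numeric(1))
  expect_equal(unname(ratios), rep(1, 4), tolerance = 0.03)

  # full desensitization at pulse-1 end, interval = tau_rec: P2/P1 = 1 - 1/e
  m <- channel_model(n_channels = 5000, conductance = 20, v_hold = -55,
                     po_peak = 0.5, tau_rise = 0.1, tau_f_des = 1.5,
                     tau_s_des = 6, ss_fraction = 0, tau_recovery = 60,
                     sigma_b2 = 0)
  tp <- simulate_two_pulse(m, intervals = c(20, 60), pulse_dur = 20,
                           sweeps_per_interval = 5, seed = 2)
  r60 <- paired_pulse_ratio(tp[["dt_60"]])[["ratio"]]
  expect_equal(r60, 1 - exp(-1), tolerance = 0.02)

  expect_error(simulate_two_pulse(m, intervals = c(10), pulse_dur = 20,
                                  sweeps_per_interval = 5, seed = 1),
               "shorter than pulse_dur")
  expect_error(simulate_two_pulse(m, intervals = c(40, 30),
                                  sweeps_per_interval = 5, seed = 1))
})

test_that("IV families are ohmic without block and silent at 0 mV", {
  m <- tiny_model(n_channels = 1000, sigma_b2 = 0.2)
  fam <- simulate_iv(m, voltages = c(-60, 0, 60), n_sweeps = 100, seed = 4,
                     pulse_dur = 20)
  pk <- iv_peaks(fam)
  expect_equal(abs(pk$peak_pA[pk$voltage_mV == 60]) /
                 abs(pk$peak_pA[pk$voltage_mV == -60]), 1, tolerance = 0.03)
  # at 0 mV there is no driving force: mean current is pure baseline noise
  m0 <- mean_trace(fam[["V_0"]])
  expect_lt(max(abs(m0)), 5 * sqrt(0.2 / 100))
  expect_error(simulate_iv(m, voltages = numeric(0), n_sweeps = 5, seed = 1))
})
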
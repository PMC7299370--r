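test_that("stable-epoch screening handles flat and monotone peak series", {
  ep <- select_stable_epoch(rep(100, 100), min_len = 50)
  expect_true(ep$found)
  expect_equal(c(ep$start, ep$end), c(1, 100))

  ep2 <- select_stable_epoch(seq(100, 1, length.out = 100), min_len = 50)
  expect_false(ep2$found)
  expect_s3_class(ep2, "stable_epoch")  # explicit outcome, not an error

  expect_error(select_stable_epoch(rep(1, 10), min_len = 50))
  expect_error(select_stable_epoch(rep(1, 100), alpha = 0))
})

test_that("epoch selection matches an exhaustive window scan", {
  set.seed(42)
  # stable for 200 sweeps, then pronounced run-down over the last 100
  peaks <- c(100 + rnorm(200, 0, 2),
             100 * cumprod(rep(0.985, 100)) + rnorm(100, 0, 2))
  ep <- select_stable_epoch(peaks, min_len = 50, max_len = 350)
  oracle <- brute_force_epoch(peaks, min_len = 50, max_len = 350)
  expect_true(ep$found)
  expect_equal(c(ep$start, ep$end), unname(oracle))
  expect_lte(ep$end, 220)  # run-down region excluded

  # shorter series against the same oracle, several seeds
  for (sd in 1:3) {
    set.seed(sd)
    pk <- 50 + rnorm(80, 0, 1) + c(rep(0, 60), -cumsum(rep(0.4, 20)))
    got <- select_stable_epoch(pk, min_len = 30, max_len = 80)
    want <- brute_force_epoch(pk, min_len = 30, max_len = 80)
    expect_equal(c(got$start, got$end), unname(want))
  }
})

test_that("pairwise variance: degenerate and constant-offset cases", {
  tm <- seq(0, 5, by = 0.5)
  base <- sin(tm)
  x <- sweep_set(tm, cbind(base, base, base), v_hold = -55,
                 t0_agonist = 1, pulse_dur = 4,
                 baseline_window = c(0, 1), analysis_window = c(1, 5))
  st <- pairwise_variance(x)
  expect_true(all(st$var_trace == 0))

  y <- sweep_set(tm, cbind(base, base + 2), v_hold = -55,
                 t0_agonist = 1, pulse_dur = 4,
                 baseline_window = c(0, 1), analysis_window = c(1, 5))
  expect_equal(unique(pairwise_variance(y)$var_trace), 2^2 / 2)
  expect_error(pairwise_variance(x, epoch = c(1, 1)))
})

test_that("pairwise variance agrees with the direct sample variance", {
  m <- tiny_model(n_channels = 100)
  s <- simulate_sweeps(m, pulse_dur = 20, n_sweeps = 1000, seed = 9,
                       dt = 0.1, tail_ms = 2)
  st <- pairwise_variance(s)
  idx <- window_index_for_tests(s, c(s$t0_agonist + 1, s$t0_agonist + 20))
  direct <- apply(s$sweeps[idx, ], 1, var)
  rel <- abs(st$var_trace[idx] - direct) / direct
  expect_lt(mean(rel), 0.05)
})

test_that("noiseless parabola is identified to 1e-6 relative", {
  st <- exact_parabola_stats(i = 1, n_ch = 100, sigma_b2 = 0)
  r <- fit_parabola(st, n_bins = 10, fix_background = TRUE)
  expect_true(r$ok)
  expect_equal(r$i_hat, 1, tolerance = 1e-6)
  expect_equal(r$n_hat, 100, tolerance = 1e-6)

  # free-background mode recovers sigma_B^2 as well
  st2 <- exact_parabola_stats(i = 0.8, n_ch = 250, sigma_b2 = 1.5)
  r2 <- fit_parabola(st2, n_bins = 10, fix_background = FALSE)
  expect_equal(r2$i_hat, 0.8, tolerance = 1e-6)
  expect_equal(r2$n_hat, 250, tolerance = 1e-6)
  expect_equal(r2$sigma_b2, 1.5, tolerance = 1e-6)
  expect_error(fit_parabola(st, n_bins = 2))
})

test_that("scaling all sweeps scales i and leaves N unchanged", {
  st <- exact_parabola_stats(i = 1, n_ch = 100, sigma_b2 = 0)
  s <- 3
  st_scaled <- st
  st_scaled$mean_trace <- s * st$mean_trace
  st_scaled$var_trace <- s^2 * st$var_trace
  st_scaled$sigma_b2_hat <- s^2 * st$sigma_b2_hat
  r <- fit_parabola(st, 10, TRUE)
  rs <- fit_parabola(st_scaled, 10, TRUE)
  expect_equal(rs$i_hat, s * r$i_hat, tolerance = 1e-9)
  expect_equal(rs$n_hat, r$n_hat, tolerance = 1e-9)
})

test_that("parabola fit matches a brute-force grid search on the same SSE", {
  m <- tiny_model(n_channels = 80)
  s <- simulate_sweeps(m, pulse_dur = 25, n_sweeps = 300, seed = 13,
                       dt = 0.05, tail_ms = 2)
  r <- fit_parabola(pairwise_variance(s), n_bins = 10, fix_background = TRUE)
  expect_true(r$ok)
  sse <- function(i, n_ch) {
    pred <- i * r$bins$mean_pA - r$bins$mean_sq_pA2 / n_ch
    sum(r$bins$count * (r$bins$var_pA2 - r$sigma_b2 - pred)^2)
  }
  i_grid <- seq(0.8, 1.2, length.out = 81) * r$i_hat
  n_grid <- seq(0.8, 1.2, length.out = 81) * r$n_hat
  grid <- outer(i_grid, n_grid, Vectorize(sse))
  best <- which(grid == min(grid), arr.ind = TRUE)[1, ]
  # the analytic fit lies at the grid optimum (to grid resolution)
  expect_equal(i_grid[best[1]], r$i_hat, tolerance = 0.01)
  expect_equal(n_grid[best[2]], r$n_hat, tolerance = 0.01)
  expect_lte(sse(r$i_hat, r$n_hat), min(grid) + 1e-9)
})

test_that("fitted background matches the baseline estimate on simulated data", {
  m <- tiny_model(n_channels = 100, sigma_b2 = 1)
  s <- simulate_sweeps(m, pulse_dur = 25, n_sweeps = 400, seed = 21, dt = 0.05)
  r <- fit_parabola(pairwise_variance(s), fix_background = FALSE)
  expect_true(r$ok)
  expect_equal(r$sigma_b2, 1, tolerance = 0.5)
})

test_that("degenerate variance data is flagged rather than silently fitted", {
  st <- exact_parabola_stats(i = 1, n_ch = 100)
  st$var_trace <- 0.5 + 0.2 * abs(st$mean_trace) +
    abs(st$mean_trace)^2 / 150  # positive curvature: not a channel parabola
  r <- fit_parabola(st, 10, TRUE)
  expect_false(r$ok)
  expect_true(any(grepl("curvature", r$flags)))
})

test_that("conductance conversion follows g = 1000 i / |V|", {
  expect_equal(conductance_from_current(0, -55), 0)
  expect_equal(conductance_from_current(0.912, -55), 16.58, tolerance = 1e-2)
  expect_equal(conductance_from_current(1.339, -55), 24.34, tolerance = 1e-2)
  expect_error(conductance_from_current(1, 0))
})

test_that("full NSFA chain keeps Po in a physical range on simulated data", {
  for (cc in c("CP_0T", "CI_2T_A2")) {
    m <- ampar_preset(cc)
    r <- nsfa(simulate_sweeps(m, n_sweeps = 100, seed = 17))
    expect_true(r$ok)
    expect_gt(r$po_peak_hat, 0)
    expect_lt(r$po_peak_hat, 1.1)
    expect_equal(r$g_hat, m$conductance, tolerance = 0.15)
  }
})
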
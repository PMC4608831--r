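test_that("steady-state gates match their analytic values", {
  g <- steady_state_gates(-73)
  expect_equal(g$h_inf, 0.5)
  g <- steady_state_gates(-63)
  expect_equal(g$s_inf, 0.5)
  g <- steady_state_gates(-75)
  expect_equal(g$tau_h, 1 / (0.011 * 2), tolerance = 1e-12)
  # removable singularity: alpha_m(-40.7) -> 1, continuous in a neighborhood
  g0 <- steady_state_gates(-40.7)
  gl <- steady_state_gates(-40.7 - 1e-6)
  gr <- steady_state_gates(-40.7 + 1e-6)
  expect_equal(g0$m_inf, 1 / (1 + 4 * exp(-0.05 * 9) / 1), tolerance = 1e-6)
  expect_equal(gl$m_inf, g0$m_inf, tolerance = 1e-6)
  expect_equal(gr$m_inf, g0$m_inf, tolerance = 1e-6)
  # all gates bounded and monotone trends sensible across the physiological range
  V <- seq(-120, 60, by = 0.5)
  gg <- steady_state_gates(V)
  for (nm in c("m_inf", "s_inf", "n_inf", "h_inf"))
    expect_true(all(gg[[nm]] >= 0 & gg[[nm]] <= 1))
  expect_true(all(diff(gg$eta_inf) < 0))  # inactivation closes with depolarization
  expect_true(all(gg$tau_n > 0) && all(gg$tau_h > 0))
})

test_that("ionic currents vanish at their reversal potentials", {
  p <- ts_params()
  st <- steady_state_gates(-65)
  cur <- ionic_currents(60, st$eta_inf, st$h_inf, st$n_inf, p)
  expect_equal(cur$I_Na, 0)
  cur <- ionic_currents(-85, st$eta_inf, st$h_inf, st$n_inf, p)
  expect_equal(cur$I_KDR, 0)
  cur <- ionic_currents(-65, st$eta_inf, st$h_inf, st$n_inf, p)
  expect_equal(cur$I_leak, 0)
  cur <- ionic_currents(-30, st$eta_inf, st$h_inf, st$n_inf, p)
  expect_equal(cur$I_h, 0)
  cur <- ionic_currents(120, st$eta_inf, st$h_inf, st$n_inf, p)
  expect_equal(cur$I_T, 0)
})

total_current <- function(V, p) {
  st <- steady_state_gates(V, p$eta_parse)
  cur <- ionic_currents(V, st$eta_inf, st$h_inf, st$n_inf, p)
  cur$I_Na + cur$I_KDR + cur$I_h + cur$I_T + cur$I_leak + p$I_bias
}

test_that("noiseless hyperpolarized integration converges to the fixed point", {
  p <- ts_params(I_bias = -2, sigma_noise = 0, g_h = 0, g_T = 0)
  v <- integrate_ts(p, t_end = 2000)
  n <- length(v$V)
  expect_length(v$spike_times, 0)
  # step-to-step change collapses
  expect_lt(abs(v$V[n] - v$V[n - 1]), 1e-9)
  # and the resting level is a root of the steady-state current balance
  vstar <- stats::uniroot(total_current, c(-120, -50), p = p)$root
  expect_equal(v$V[n], vstar, tolerance = 1e-4)
})

test_that("the deterministic integrator agrees with a half-step reference", {
  for (ib in c(3.5, 6)) {
    p <- ts_params(I_bias = ib, sigma_noise = 0, g_h = 0, g_T = 0)
    p2 <- ts_params(I_bias = ib, sigma_noise = 0, g_h = 0, g_T = 0,
                    dt = 0.0125)
    n1 <- length(integrate_ts(p, t_end = 1000)$spike_times)
    n2 <- length(integrate_ts(p2, t_end = 1000)$spike_times)
    expect_gt(n1, 5)  # constant suprathreshold drive spikes periodically
    expect_lte(abs(n1 - n2), 1)
  }
})

test_that("fixed seeds give bit-identical traces and gates stay bounded", {
  p <- ts_params(I_bias = 2, sigma_noise = 1)
  a <- integrate_ts(p, t_end = 500, seed = 42)
  b <- integrate_ts(p, t_end = 500, seed = 42)
  expect_identical(a$V, b$V)
  expect_identical(a$spike_times, b$spike_times)
  c_ <- integrate_ts(p, t_end = 500, seed = 43)
  expect_false(identical(a$V, c_$V))
  for (run in list(a, b, c_)) {
    h <- run$final_state[3]; n <- run$final_state[4]
    expect_true(h >= -0.05 && h <= 1.05)
    expect_true(n >= -0.05 && n <= 1.05)
  }
})

test_that("spike detection is threshold-invariant for clean overshooting spikes", {
  p <- ts_params(I_bias = 5, sigma_noise = 0, g_h = 0, g_T = 0)
  v <- integrate_ts(p, t_end = 1000)
  expect_gt(max(v$V), 30)  # spikes overshoot well past 0 mV
  counts <- vapply(c(-20, -10, 0), function(thr)
    length(detect_spikes(v$V, v$dt, thr)), numeric(1))
  expect_true(all(counts == counts[1]))
})

test_that("spike detector applies one-spike-per-event lockout", {
  dt <- 0.1
  v <- rep(-60, 3000)
  bump <- 30 * exp(-(seq(-20, 20)^2) / 20)  # clean suprathreshold bump
  for (t0 in c(500, 1500, 2500)) v[t0 + seq(-20, 20)] <- -60 + bump * 3
  expect_length(detect_spikes(v, dt, threshold = 0), 3)
  # jittered double crossings within 1 ms collapse to one spike
  v2 <- rep(-60, 1000)
  v2[500:520] <- 10
  v2[505] <- -5  # dip below threshold and re-crossing 0.6 ms later
  expect_length(detect_spikes(v2, dt, threshold = 0), 1)
  expect_length(detect_spikes(rep(-70, 1000), dt, 0), 0)
})

test_that("eta_inf parses are both monotone but numerically distinct", {
  V <- seq(-100, -40, by = 1)
  lit <- steady_state_gates(V, "literal")$eta_inf
  pro <- steady_state_gates(V, "product")$eta_inf
  expect_true(all(diff(lit) < 0))
  expect_true(all(diff(pro) < 0))
  expect_gt(max(abs(lit - pro)), 0.1)
})

test_that("simulated trials are reproducible and respect the duration", {
  stim <- short_stimuli()
  pairs <- generate_population_psths(stim, seed = 5)
  p <- ts_params(I_bias = -18, g_h = 1, g_T = 0.5)
  syn <- synaptic_config(sigma_B = 0.5, W_s = 0.8)
  a <- simulate_trials(pairs[[1]], p, syn, n_trials = 3, seed = 8)
  b <- simulate_trials(pairs[[1]], p, syn, n_trials = 3, seed = 8)
  expect_identical(a, b)
  expect_true(all(unlist(a) >= 0 & unlist(a) <= attr(a, "duration")))
})
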
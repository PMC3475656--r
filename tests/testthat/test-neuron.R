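test_that("rate constants are positive with correct asymptotics and limits", {
  V <- seq(-100, 50, by = 0.5)
  r <- wb_rate_constants(V)
  expect_true(all(as.matrix(r[-1]) > 0))
  g <- wb_gate_inf(V)
  expect_true(all(g$m_inf > 0 & g$m_inf < 1))
  expect_true(all(g$h_inf > 0 & g$h_inf < 1))
  expect_true(all(g$n_inf > 0 & g$n_inf < 1))

  # removable singularities evaluated as analytic limits
  for (v0 in c(-35, -34)) {
    at <- wb_rate_constants(v0)
    near <- wb_rate_constants(c(v0 - 1e-6, v0 + 1e-6))
    expect_equal(at$alpha_m, mean(near$alpha_m), tolerance = 1e-6)
    expect_equal(at$alpha_n, mean(near$alpha_n), tolerance = 1e-6)
  }

  # monotone activation/inactivation over the physiological range
  gg <- wb_gate_inf(seq(-100, 0, by = 0.25))
  expect_true(all(diff(gg$m_inf) > 0))
  expect_true(all(diff(gg$h_inf) < 0))
})

test_that("derivatives honour the membrane equation", {
  p0 <- wb_params(g_Na = 0, g_K = 0)
  d <- wb_derivatives(V = -65, h = 0.5, n = 0.5, I_inj = 0, params = p0)
  expect_equal(d$dV, 0)

  # slow potassium current arithmetic: g_slow * z * (V - E_K)
  ps <- wb_params(g_slow = 0.5)
  d0 <- wb_derivatives(-65, 0.5, 0.5, z = 0, params = ps)
  d1 <- wb_derivatives(-65, 0.5, 0.5, z = 1, params = ps)
  expect_equal(d0$dV - d1$dV, 0.5 * (-65 - (-90)))  # 12.5 uA/cm2
})

test_that("leak-only integration matches the closed-form exponential", {
  p <- wb_params(g_Na = 0, g_K = 0)
  stim <- stim_waveform(rep(0, 20000), dt_ms = 0.05)
  tr <- simulate_trial(p, stim, V0 = -80)
  tau <- p$C_m / p$g_L  # 10 ms
  v_exact <- p$E_L + (-80 - p$E_L) * exp(-tr$t_ms / tau)
  expect_lt(max(abs(tr$V - v_exact)), 1e-4)
})

test_that("rest is a fixed point: no spikes and negligible drift", {
  p <- wb_params()
  v_rest <- uniroot(function(v) {
    g <- wb_gate_inf(v)
    wb_derivatives(v, g$h_inf, g$n_inf, params = p)$dV
  }, c(-70, -60), tol = 1e-10)$root
  expect_lt(abs(v_rest - -65), 5)  # near E_L
  stim <- stim_waveform(rep(0, 20000), dt_ms = 0.05)
  tr <- simulate_trial(p, stim, V0 = v_rest)
  expect_length(detect_spikes(tr), 0)
  expect_lt(max(tr$V) - min(tr$V), 0.01)
})

test_that("constant suprathreshold drive gives periodic spiking; period is step-converged", {
  p <- wb_params()
  stim <- stim_waveform(rep(1, 20000), dt_ms = 0.05)  # 1 uA/cm2, 1000 ms
  s <- detect_spikes(simulate_trial(p, stim))
  expect_gt(length(s), 10)
  isi <- diff(s)
  steady <- tail(isi, length(isi) - 3)
  expect_lt(max(steady) - min(steady), 1e-3 + 0.051)  # identical to step size
  # refine dt tenfold as the oracle: the long-run period converges (the
  # residual discretisation error of RK2 at 0.05 ms is about 1%)
  per_c <- (tail(s, 1) - s[5]) / (length(s) - 5)
  stim_f <- stim_waveform(rep(1, 200000), dt_ms = 0.005)
  s_f <- detect_spikes(simulate_trial(p, stim_f, dt = 0.005))
  per_f <- (tail(s_f, 1) - s_f[5]) / (length(s_f) - 5)
  expect_lt(abs(per_c - per_f) / per_f, 0.015)
})

test_that("firing rate is non-decreasing in constant drive", {
  p <- wb_params()
  rates <- vapply(c(0.3, 0.6, 1.2, 2.4), function(I) {
    stim <- stim_waveform(rep(I, 20000), dt_ms = 0.05)
    length(detect_spikes(simulate_trial(p, stim)))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("gates stay inside [0, 1] during noisy integration", {
  h <- generate_frozen_noise(3, 5000)
  stim <- scale_stimulus(h, 1, 0.2, 0.8)
  tr <- simulate_trial(wb_params(g_slow = 0.5), stim, lam = 0.025, seed = 9,
                       record_gates = TRUE)
  expect_true(all(tr$h >= 0 & tr$h <= 1))
  expect_true(all(tr$n >= 0 & tr$n <= 1))
  expect_true(all(tr$z >= 0 & tr$z <= 1))
})

test_that("spike detection uses the upward 0 mV crossing convention", {
  # constructed trace: below zero except two excursions; dt = 0.05 ms
  V <- rep(-60, 500)
  V[101:105] <- c(0, 10, 5, 1, -1)    # first reaches 0 exactly at sample 101
  V[401:403] <- c(5, 5, -5)
  tr <- tibble::tibble(t_ms = (seq_along(V) - 1) * 0.05, V = V)
  expect_equal(detect_spikes(tr), c(5.0, 20.0))

  expect_length(detect_spikes(tibble::tibble(t_ms = 1:10, V = rep(-1, 10))),
                0)
  # touching exactly zero counts as a crossing
  tr2 <- tibble::tibble(t_ms = 0:4, V = c(-1, -1, 0, -1, -1))
  expect_equal(detect_spikes(tr2), 2)
})

test_that("trial simulation is seed-deterministic and the noise obeys its contract", {
  h <- generate_frozen_noise(1, 2000)
  stim <- scale_stimulus(h, 1, 0.2, 0.5)
  a <- simulate_trial(wb_params(), stim, lam = 0.001, seed = 7)
  b <- simulate_trial(wb_params(), stim, lam = 0.001, seed = 7)
  expect_identical(a$V, b$V)

  lam <- 0.00025
  dt <- 0.05
  expect_equal(noise_half_width(lam, dt), sqrt(6 * lam / dt))
  expect_equal(noise_half_width(lam, dt, "literal"), 12 * lam / dt)
  set.seed(11)
  draws <- spikepatterns:::.noise_draws_cpp(1e6, noise_half_width(lam, dt))
  expect_lt(abs(var(draws) / (2 * lam / dt) - 1), 0.01)
  expect_lt(abs(mean(draws)), 3 * sqrt(var(draws) / 1e6))
})

test_that("ensembles respect seeds, additivity and the noiseless degeneracy", {
  h <- generate_frozen_noise(2, 3000)
  stim <- scale_stimulus(h, 1, 0.25, 0.6)
  expect_error(simulate_ensemble(wb_params(), stim, seeds = c(1, 1)),
               "distinct")

  ens <- simulate_ensemble(wb_params(), stim, seeds = 1:5, lam = 0.001)
  trains <- spike_trains(ens)
  expect_equal(nrow(ens), sum(lengths(trains)))
  # per-trial detection matches a direct single-trial run
  tr3 <- simulate_trial(wb_params(), stim, lam = 0.001, seed = 3)
  expect_equal(trains[[3]], detect_spikes(tr3))

  # lam = 0: all trials identical, R = 1 at any sigma
  ens0 <- simulate_ensemble(wb_params(), stim, seeds = 1:4, lam = 0)
  tr0 <- spike_trains(ens0)
  expect_true(all(vapply(tr0, identical, logical(1), tr0[[1]])))
  expect_gt(length(tr0[[1]]), 0)
  expect_equal(r_reliability(ens0, sigma = 3)$R, 1)
})
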
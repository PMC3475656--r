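test_that("pairwise similarity matches its analytic and gridded forms", {
  expect_equal(similarity_pair(c(10, 20, 30), c(10, 20, 30), 3), 1)
  # single-spike pair: exp(-dt^2 / (4 sigma^2))
  expect_equal(similarity_pair(10, 13, 3), exp(-9 / 36), tolerance = 1e-12)
  # numerical convolution oracle on multi-spike trains
  a <- c(10, 22, 40)
  b <- c(12, 25, 41, 60)
  expect_equal(similarity_pair(a, b, 3, cutoff = Inf),
               similarity_grid(a, b, 3), tolerance = 1e-3)
  # empty-train convention
  expect_equal(similarity_pair(numeric(), 10, 3), 0)
  expect_equal(similarity_pair(numeric(), numeric(), 3), 0)
  expect_error(similarity_pair(1, 2, sigma = 0), "sigma")
})

test_that("the 6-sigma cutoff is consistent with the exact sum", {
  # far-separated spikes: zero under the cutoff, tiny without
  expect_equal(similarity_pair(10, 10 + 100, 3), 0)
  expect_lt(similarity_pair(10, 10 + 100, 3, cutoff = Inf), 1e-3)
  # for sigma >= 1 ms the cutoff changes the similarity by at most the
  # order of a dropped pair's kernel value, exp(-9) ~ 1.2e-4
  set.seed(5)
  for (i in 1:20) {
    a <- sort(runif(8, 0, 200))
    b <- sort(runif(8, 0, 200))
    expect_lt(abs(similarity_pair(a, b, 1) -
                    similarity_pair(a, b, 1, cutoff = Inf)), 1e-4)
  }
})

test_that("R-reliability has the documented sigma limits and invariances", {
  trains <- list(c(10, 50), c(12, 60), c(15, 70), c(20, 80), c(30, 90))
  expect_lt(r_reliability(trains, sigma = 1e-6)$R, 1e-6)
  expect_gt(r_reliability(trains, sigma = 1e4)$R, 0.999)
  # common time shift leaves R unchanged
  r1 <- r_reliability(trains, 3)$R
  r2 <- r_reliability(lapply(trains, `+`, 17.3), 3)$R
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(r_reliability(list(c(1, 2)), 3), "2 trials")
  # R is the mean of the pair similarities
  r <- r_reliability(trains, 3)
  expect_equal(r$R, mean(r$pairs$S))
  expect_equal(nrow(r$pairs), choose(5, 2))
})

test_that("VP distance obeys unit costs and the exhaustive oracle", {
  for (q in c(0.01, 1, 100)) {
    expect_equal(vp_distance(numeric(), 50, q), 1)
  }
  expect_equal(vp_distance(c(1, 5, 9), c(1, 5, 9), 2), 0)
  expect_equal(vp_distance(0, 1, 0.5), 0.5)
  expect_equal(vp_distance(0, 1, 10), 2)
  set.seed(8)
  for (i in 1:200) {
    a <- sort(runif(sample(0:3, 1), 0, 20))
    b <- sort(runif(sample(0:3, 1), 0, 20))
    q <- runif(1, 0, 3)
    expect_equal(vp_distance(a, b, q), vp_exhaustive(a, b, q),
                 tolerance = 1e-12)
  }
})

test_that("VP matrix is symmetric, zero-diagonal and matches pairwise calls", {
  set.seed(9)
  trains <- lapply(1:6, function(i) sort(runif(sample(1:5, 1), 0, 100)))
  D <- vp_distance_matrix(trains, q = 0.7)
  expect_equal(unclass(D), t(unclass(D)), ignore_attr = TRUE)
  expect_true(all(diag(D) == 0))
  for (i in 1:6) for (j in 1:6) {
    expect_equal(D[i, j], vp_distance(trains[[i]], trains[[j]], 0.7))
  }
  # q = 0: spike-count difference
  D0 <- vp_distance_matrix(trains, q = 0)
  n <- lengths(trains)
  expect_equal(unclass(D0), abs(outer(n, n, `-`)), ignore_attr = TRUE)
  # identical trials give a zero matrix
  expect_true(all(vp_distance_matrix(rep(trains[1], 3), 1) == 0))
})

test_that("PSTH conserves spike mass and scales to Hz", {
  ens <- ensemble_from_trains(list(c(10, 30), c(10.2, 50), numeric()), 100)
  p <- psth(ens, bin_width = 0.5)
  # pre-smoothing mass: sum(rate * dt_s) = spikes per trial
  expect_equal(sum(p$rate_raw) * 0.5 / 1000, 4 / 3, tolerance = 1e-12)
  # smoothing preserves mass away from edges (kernel normalised)
  expect_equal(sum(p$rate) * 0.5 / 1000, 4 / 3, tolerance = 1e-3)

  # one spike, one trial, 0.5 ms bins: peak bin = 1/(1 * 0.0005 s) = 2000 Hz
  e1 <- ensemble_from_trains(list(42.1), 100)
  p1 <- psth(e1, 0.5, smooth_sd_bins = 0)
  expect_equal(max(p1$rate_raw), 2000)
  expect_equal(p1$t_ms[which.max(p1$rate_raw)], 42)

  e0 <- ensemble_from_trains(list(numeric(), numeric()), 100)
  expect_true(all(psth(e0)$rate == 0))
})

test_that("firing rates average per-trial counts over duration", {
  ens <- ensemble_from_trains(list(1:10 * 10, 1:12 * 10, 1:14 * 10), 1000)
  fr <- firing_rate(ens)
  expect_equal(fr$rate_mean, 12)
  expect_equal(fr$rate_sd, 2)  # sample SD across trials
  e0 <- ensemble_from_trains(list(numeric(), numeric()), 1000)
  expect_equal(firing_rate(e0)$rate_mean, 0)
})

test_that("STA recovers planted stimulus history", {
  # constant stimulus -> constant STA
  stim <- stim_waveform(rep(2.5, 2000), dt_ms = 0.1)
  ens <- ensemble_from_trains(list(c(50, 100), 150), 200)
  sta <- spike_triggered_average(ens, stim)
  expect_true(all(sta$sta == 2.5))
  expect_equal(range(sta$lag_ms), c(-25, 0))

  # single spike: STA equals that spike's stimulus segment exactly
  set.seed(10)
  stim2 <- stim_waveform(rnorm(2000), dt_ms = 0.1)
  e1 <- ensemble_from_trains(list(100), 200)
  sta1 <- spike_triggered_average(e1, stim2)
  idx <- floor(100 / 0.1) + 1
  expect_equal(sta1$sta, stim2$current[(idx - 250):idx])

  # spikes planted 5 ms after isolated triangular pulses peak at lag -5 ms
  cur <- rep(0, 5000)
  peaks <- c(1000, 2500, 4000)  # sample indices of pulse apex
  for (pk in peaks) cur[(pk - 20):(pk + 20)] <- 1 - abs(-20:20) / 20
  stim3 <- stim_waveform(cur, dt_ms = 0.1)
  spike_t <- (peaks - 1) * 0.1 + 5
  e3 <- ensemble_from_trains(list(spike_t), 500)
  sta3 <- spike_triggered_average(e3, stim3)
  expect_equal(sta3$lag_ms[which.max(sta3$sta)], -5, tolerance = 0.11)

  # spikes without a full history are excluded; none eligible -> error
  e4 <- ensemble_from_trains(list(10), 200)
  expect_error(spike_triggered_average(e4, stim2), "history")
})
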
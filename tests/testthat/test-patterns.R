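block_matrix <- function(n1, n2, within = 0.1, between = 10) {
  n <- n1 + n2
  D <- matrix(between, n, n)
  D[1:n1, 1:n1] <- within
  D[(n1 + 1):n, (n1 + 1):n] <- within
  diag(D) <- 0
  D
}

test_that("FCM recovers block structure in the distance matrix", {
  D <- block_matrix(12, 8)
  pa <- fcm_cluster(D, 2, seed = 1)
  lab <- pa$label
  expect_equal(length(unique(lab[1:12])), 1)
  expect_equal(length(unique(lab[13:20])), 1)
  expect_false(lab[1] == lab[20])
  memb <- attr(pa, "membership")
  expect_true(all(apply(memb, 1, max) > 0.95))
  expect_equal(rowSums(memb), rep(1, 20), tolerance = 1e-6)
  # hard labels are argmax memberships
  expect_equal(lab, apply(memb, 1, which.max))
})

test_that("single-cluster and invalid requests behave", {
  D <- block_matrix(5, 5)
  pa1 <- fcm_cluster(D, 1)
  expect_true(all(pa1$label == 1))
  expect_true(all(attr(pa1, "membership") == 1))
  expect_error(fcm_cluster(D, 11), "exceed")
})

test_that("FCM restarts do not disturb the caller's RNG stream", {
  D <- block_matrix(10, 10)
  set.seed(123)
  before <- .Random.seed
  invisible(fcm_cluster(D, 2, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("cluster-count selection finds blob structure and rejects noise", {
  # one Gaussian blob -> no structure
  k1 <- vapply(1:5, function(s) {
    set.seed(s)
    x <- matrix(rnorm(80), ncol = 2)
    select_n_clusters(as.matrix(dist(x)), seed = s)
  }, integer(1))
  expect_true(mean(k1 == 1) >= 0.8)

  # three well-separated blobs -> k = 3 in >= 90% of 20 seeds
  k3 <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rbind(matrix(rnorm(40, 0), ncol = 2),
               matrix(rnorm(40, 10), ncol = 2),
               cbind(rnorm(20, 0), rnorm(20, 10)))
    select_n_clusters(as.matrix(dist(x)), seed = s)
  }, integer(1))
  expect_gte(mean(k3 == 3), 0.9)

  # degenerate, all-identical trials
  expect_equal(select_n_clusters(matrix(0, 10, 10)), 1L)
})

test_that("segmentation cuts at quiet gaps and falls back to fixed cuts", {
  # trials silent in 500-520 ms
  set.seed(2)
  trains <- lapply(1:20, function(i) {
    sort(c(runif(8, 0, 495), runif(8, 525, 1000)))
  })
  ens <- ensemble_from_trains(trains, 1000)
  seg <- segment_trials(ens, target_len_ms = 500)
  expect_equal(nrow(seg), 2)
  expect_gt(seg$start[2], 495)
  expect_lt(seg$start[2], 525)
  expect_equal(seg$start[1], 0)
  expect_equal(seg$end[2], 1000)

  # uniformly dense firing: no sub-threshold minima -> fixed-length warning
  set.seed(3)
  dense <- lapply(1:20, function(i) sort(runif(200, 0, 1000)))
  ens2 <- ensemble_from_trains(dense, 1000)
  expect_warning(seg2 <- segment_trials(ens2, target_len_ms = 500,
                                        rate_threshold = 0),
                 "fixed-length")
  expect_equal(seg2$start, c(0, 500))
})

test_that("pattern occupations are normalized and recover designed mixes", {
  specs <- list(pattern_spec(c(30, 70), occupation = 0.6, jitters = 0.5),
                pattern_spec(c(50, 90), occupation = 0.4, jitters = 0.5))
  ens <- generate_pattern_ensemble(specs, 100, 120, seed = 6)
  pa <- find_spike_patterns(ens, n_c = 2, seed = 1)
  occ <- pattern_occupation(pa$assignment)
  expect_equal(sum(occ$occupation), 1, tolerance = 1e-12)
  # recovered occupation within binomial 99% CI of 0.6
  expect_lt(abs(max(occ$occupation) - 0.6), 2.58 * sqrt(0.6 * 0.4 / 100))

  # conditions: occupations sum to 1 within each condition
  conds <- tibble::tibble(trial = 1:100,
                          amp = rep(c("lo", "hi"), each = 50))
  occ2 <- pattern_occupation(pa$assignment, conds)
  sums <- tapply(occ2$occupation, occ2$amp, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("trial order permutation leaves occupations and event stats unchanged", {
  specs <- three_pattern_specs()
  ens <- generate_pattern_ensemble(specs, 45, 300, seed = 11)
  pa <- find_spike_patterns(ens, n_c = 3, seed = 2)

  perm <- sample(45)
  sp <- tibble::as_tibble(ens)
  sp$trial <- match(sp$trial, perm)
  ens_p <- spike_ensemble(sp[c("trial", "time")],
                          trials = tibble::tibble(trial = 1:45),
                          duration_ms = 300)
  pa_p <- find_spike_patterns(ens_p, n_c = 3, seed = 2)

  expect_equal(sort(pattern_occupation(pa$assignment)$occupation),
               sort(pattern_occupation(pa_p$assignment)$occupation))
  ev <- pa$events$events
  ev_p <- pa_p$events$events
  expect_equal(ev$mean_time, ev_p$mean_time, tolerance = 1e-9)
  expect_equal(ev$reliability, ev_p$reliability)
})
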
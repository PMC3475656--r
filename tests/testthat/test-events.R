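agg <- function(times, trial = 1) tibble::tibble(trial = trial, time = times)

test_that("interval method splits the aggregate train at gaps over t_ISI", {
  es <- interval_events(agg(c(1.0, 1.5, 2.0, 10.0, 10.5)), t_isi = 3,
                        n_trials = 1)
  expect_equal(nrow(es$events), 2)
  expect_equal(es$spikes$event, c(1L, 1L, 1L, 2L, 2L))

  # single spike -> one event; all gaps below threshold -> one event
  expect_equal(nrow(interval_events(agg(5), 3)$events), 1)
  expect_equal(nrow(interval_events(agg(c(1, 3, 5, 7)), 3)$events), 1)
  # a gap exactly equal to t_ISI does not split
  expect_equal(nrow(interval_events(agg(c(1, 4)), 3)$events), 1)
  expect_equal(nrow(interval_events(agg(c(1, 4.001)), 3)$events), 2)
})

test_that("ROC discriminability matches hand-computed rank sums", {
  # identical samples: AUC = 0.5, d = 0
  expect_equal(roc_discriminability(c(1, 2, 3), c(1, 2, 3)), 0)
  # disjoint supports: AUC = 1, d = 1
  expect_equal(roc_discriminability(c(1, 2, 3), c(10, 11, 12)), 1)
  # hand-computed: x = {1, 3}, y = {2} -> U = 1, AUC = 0.5, d = 0
  expect_equal(roc_discriminability(c(1, 3), 2), 0)
  # singleton vs sample still defined
  expect_equal(roc_discriminability(5, c(1, 2)), 1)
})

test_that("ROC merging pools shared events and is idempotent", {
  # two patterns with one shared event (indistinguishable times) and one
  # pattern-specific event each
  p1 <- interval_events(tibble::tibble(trial = c(1, 2, 1, 2),
                                       time = c(50, 50.4, 120, 120.5)),
                        t_isi = 3, n_trials = 4, pattern = 1)
  p2 <- interval_events(tibble::tibble(trial = c(3, 4, 3, 4),
                                       time = c(50.2, 50.6, 200, 200.3)),
                        t_isi = 3, n_trials = 4, pattern = 2)
  merged <- roc_merge(list(p1, p2), t_roc = 0.5, n_trials = 4)
  expect_equal(nrow(merged$events), 3)
  shared <- merged$events[which.min(abs(merged$events$mean_time - 50)), ]
  expect_equal(shared$n_trials_hit, 4)
  expect_equal(shared$reliability, 1)
  expect_setequal(shared$patterns[[1]], c(1, 2))

  # events with disjoint time supports never merge
  far <- roc_merge(list(
    interval_events(agg(c(1, 2, 3), trial = 1:3), 3, n_trials = 6,
                    pattern = 1),
    interval_events(agg(c(10, 11, 12), trial = 4:6), 3, n_trials = 6,
                    pattern = 2)
  ), t_roc = 0.5, n_trials = 6)
  expect_equal(nrow(far$events), 2)

  # idempotence: merging the merged set changes nothing
  again <- roc_merge(merged, t_roc = 0.5, n_trials = 4)
  expect_equal(again$events$mean_time, merged$events$mean_time)
  expect_equal(again$events$n_spikes, merged$events$n_spikes)
})

test_that("event statistics follow their definitions", {
  # 45 of 50 trials contribute -> reliability 0.9
  sp <- tibble::tibble(trial = 1:45, time = rnorm(45, 100, 1), event = 1L)
  es <- event_set(sp, n_trials = 50)
  expect_equal(es$events$reliability, 0.9)

  # jitter is the sample SD; precision its inverse
  sp2 <- tibble::tibble(trial = 1:3, time = c(9, 10, 11), event = 1L)
  es2 <- event_set(sp2, n_trials = 3)
  expect_equal(es2$events$jitter, 1)
  expect_equal(es2$events$precision, 1)

  # single-spike event: jitter 0, precision missing, excluded from averages
  sp3 <- tibble::tibble(trial = c(1, 1:3), time = c(10, 49, 50, 51),
                        event = c(1L, 2L, 2L, 2L))
  es3 <- event_set(sp3, n_trials = 3)
  single <- es3$events[es3$events$n_spikes == 1, ]
  expect_equal(single$jitter, 0)
  expect_true(is.na(single$precision))
  st <- event_statistics(es3)
  expect_equal(st$summary$precision, 1)

  # weakly supported events are reclassified as noise
  es4 <- drop_sparse_events(es3, min_trials = 2)
  expect_equal(nrow(es4$events), 1)
  expect_equal(sum(is.na(es4$spikes$event)), 1)
})

test_that("every spike ends up in exactly one event or in noise", {
  specs <- three_pattern_specs()
  ens <- generate_pattern_ensemble(specs, 45, 300, noise_rate = 2, seed = 3)
  pa <- find_spike_patterns(ens, seed = 3)
  sp <- pa$events$spikes
  expect_equal(nrow(sp), nrow(ens))
  assigned <- sp[!is.na(sp$event), ]
  expect_true(all(assigned$event %in% pa$events$events$event))
  # event spike lists are time-ordered within events
  ord <- tapply(assigned$time, assigned$event, function(x) all(diff(sort(x)) >= 0))
  expect_true(all(unlist(ord)))
})
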
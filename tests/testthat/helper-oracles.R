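# Independent oracles used across the suite. All are deliberately naive
# (loops, grids, exhaustive enumeration) and never share code with the
# implementation they check.

# first-order recursion y[n] = x[n] + ar * y[n-1], zero initial state
recursive_filter_loop <- function(x, ar) {
  y <- numeric(length(x))
  prev <- 0
  for (i in seq_along(x)) {
    y[i] <- x[i] + ar * prev
    prev <- y[i]
  }
  y
}

# exhaustive VP distance for small trains: every monotone matching between
# equal-size ordered subsets, shift cost q|dt|, unmatched spikes cost 1 each
vp_exhaustive <- function(a, b, q) {
  a <- sort(a)
  b <- sort(b)
  n <- length(a)
  m <- length(b)
  if (n == 0 || m == 0) return(n + m)
  best <- Inf
  for (k in 0:min(n, m)) {
    ia <- utils::combn(n, k)
    ib <- utils::combn(m, k)
    for (ca in seq_len(ncol(ia))) {
      for (cb in seq_len(ncol(ib))) {
        cost <- q * sum(abs(a[ia[, ca]] - b[ib[, cb]])) + (n - k) + (m - k)
        best <- min(best, cost)
      }
    }
  }
  best
}

# cosine similarity of Gaussian-smoothed trains by brute-force gridding
similarity_grid <- function(a, b, sigma) {
  lo <- min(a, b) - 8 * sigma
  hi <- max(a, b) + 8 * sigma
  t <- seq(lo, hi, length.out = 20000)
  fa <- rowSums(vapply(a, function(s) stats::dnorm(t, s, sigma), t))
  fb <- rowSums(vapply(b, function(s) stats::dnorm(t, s, sigma), t))
  sum(fa * fb) / sqrt(sum(fa^2) * sum(fb^2))
}

# cumulative phase of a piecewise-constant-frequency waveform by numerical
# integration on a fine grid
fm_phase_at <- function(segments, t_ms) {
  edges <- cumsum(c(0, segments$duration_ms))
  f_of <- function(t) segments$freq_hz[findInterval(t, edges,
                                                    rightmost.closed = TRUE,
                                                    all.inside = TRUE)]
  tt <- seq(0, t_ms, length.out = 200001)
  mid <- (tt[-1] + tt[-length(tt)]) / 2
  2 * pi * sum(f_of(mid)) * (tt[2] - tt[1]) / 1000
}

# tiny deterministic ensemble builders
ensemble_from_trains <- function(trains, duration_ms, t0_ms = 0) {
  spikes <- tibble::tibble(
    trial = rep(seq_along(trains), lengths(trains)),
    time = unlist(trains, use.names = FALSE)
  )
  spike_ensemble(spikes,
                 trials = tibble::tibble(trial = seq_along(trains)),
                 duration_ms = duration_ms, t0_ms = t0_ms)
}

three_pattern_specs <- function() {
  list(
    pattern_spec(c(50, 120, 200), 0.9, 1, 1 / 3),
    pattern_spec(c(80, 150, 230), 0.9, 1, 1 / 3),
    pattern_spec(c(30, 100, 260), 0.9, 1, 1 / 3)
  )
}
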
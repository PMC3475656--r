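#' Similarity between two spike trains (Schreiber measure)
#'
#' Each train is convolved with a Gaussian of SD `sigma`; the similarity is
#' the cosine of the angle between the two smoothed waveforms. Because the
#' inner product of two unit Gaussians centred at `t_k` and `t_l` is
#' proportional to `exp(-(t_k - t_l)^2 / (4 sigma^2))`, the cosine is
#' computed analytically as a normalised sum of these kernel values over
#' spike pairs; pairs separated by more than `6 sigma` are skipped (their
#' contribution is below `exp(-9)`). If either train is empty the similarity
#' is 0 by convention, so silent trials count as unreliable.
#'
#' @param train_a,train_b numeric vectors of spike times, ms.
#' @param sigma Gaussian SD, ms.
#' @param cutoff drop spike pairs further apart than `cutoff * sigma`
#'   (`Inf` disables the cutoff).
#' @return similarity in \[0, 1\].
#' @export
similarity_pair <- function(train_a, train_b, sigma, cutoff = 6) {
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("`sigma` must be positive", call. = FALSE)
  }
  if (length(train_a) == 0 || length(train_b) == 0) return(0)
  cross <- gauss_overlap_sum(train_a, train_b, sigma, cutoff)
  if (cross == 0) return(0)
  aa <- gauss_overlap_sum(train_a, train_a, sigma, cutoff)
  bb <- gauss_overlap_sum(train_b, train_b, sigma, cutoff)
  cross / sqrt(aa * bb)
}

gauss_overlap_sum <- function(a, b, sigma, cutoff) {
  d2 <- outer(a, b, `-`)^2
  if (is.finite(cutoff)) d2[d2 > (cutoff * sigma)^2] <- Inf
  sum(exp(-d2 / (4 * sigma^2)))
}

#' R-reliability of a spike-train ensemble
#'
#' The mean pairwise [similarity_pair()] across all distinct trial pairs.
#' As `sigma -> 0` only identical spike times overlap, so R -> 0 for trains
#' with distinct times; as `sigma` grows far beyond the trial length all
#' spikes overlap and R -> 1. The measure conflates spike-time precision and
#' trial-to-trial reliability at timescale `sigma`.
#'
#' @param ensemble a [spike_ensemble()] (or a list of spike-time vectors).
#' @param sigma Gaussian SD, ms (3 ms is the conventional choice for slice
#'   recordings; 1 ms resolves the faster model-neuron spiking).
#' @param cutoff passed to [similarity_pair()].
#' @return an `r_reliability` object: list with `R`, `sigma` and the tibble
#'   `pairs` of per-pair similarities.
#' @export
r_reliability <- function(ensemble, sigma, cutoff = 6) {
  trains <- if (inherits(ensemble, "spike_ensemble")) {
    spike_trains(ensemble)
  } else {
    ensemble
  }
  n <- length(trains)
  if (n < 2) stop("need at least 2 trials", call. = FALSE)
  pairs <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n)) |>
    dplyr::filter(.data$i < .data$j)
  pairs$S <- purrr::map2_dbl(pairs$i, pairs$j, function(i, j) {
    similarity_pair(trains[[i]], trains[[j]], sigma, cutoff)
  })
  structure(list(R = mean(pairs$S), sigma = sigma, pairs = pairs),
            class = "r_reliability")
}

#' @export
print.r_reliability <- function(x, ...) {
  cat(sprintf("R-reliability: %.4f (sigma = %g ms, %d pairs)\n",
              x$R, x$sigma, nrow(x$pairs)))
  invisible(x)
}

#' @export
tidy.r_reliability <- function(x, ...) x$pairs

#' @export
glance.r_reliability <- function(x, ...) {
  tibble::tibble(R = x$R, sigma = x$sigma, n_pairs = nrow(x$pairs))
}

#' Victor-Purpura distance between two spike trains
#'
#' Minimum cost of editing one train into the other, where inserting or
#' deleting a spike costs 1 and shifting a spike by `dt` ms costs `q * |dt|`.
#' `q` (1/ms) sets the timing sensitivity: at `q = 0` the distance is the
#' spike-count difference; for large `q` moving spikes is never worthwhile
#' and the distance counts non-coincident spikes. Computed by the standard
#' dynamic program over the sorted trains.
#'
#' @param train_a,train_b numeric vectors of spike times, ms (sorted
#'   internally if needed).
#' @param q shift cost per ms.
#' @return distance (>= 0).
#' @export
vp_distance <- function(train_a, train_b, q) {
  stopifnot(q >= 0)
  .vp_distance_cpp(sort(as.numeric(train_a)), sort(as.numeric(train_b)), q)
}

#' Pairwise Victor-Purpura distance matrix
#'
#' @param ensemble a [spike_ensemble()] (or list of spike-time vectors).
#' @param q shift cost per ms.
#' @return a `vp_matrix` object: symmetric zero-diagonal matrix with
#'   attribute `q`.
#' @export
vp_distance_matrix <- function(ensemble, q) {
  stopifnot(q >= 0)
  trains <- if (inherits(ensemble, "spike_ensemble")) {
    spike_trains(ensemble)
  } else {
    ensemble
  }
  d <- .vp_matrix_cpp(lapply(trains, function(x) sort(as.numeric(x))), q)
  attr(d, "q") <- q
  class(d) <- c("vp_matrix", class(d))
  d
}

#' Peri-stimulus time histogram (PSTH)
#'
#' Spike counts in half-open bins `[t, t + bin)` pooled across trials,
#' normalised by trial count and bin width in seconds (units Hz), then
#' smoothed with a Gaussian kernel of SD `smooth_sd_bins` bins, truncated at
#' +/- 4 SD and renormalised at the edges.
#'
#' @param ensemble a [spike_ensemble()].
#' @param bin_width bin width, ms.
#' @param smooth_sd_bins Gaussian SD in bins (0 skips smoothing).
#' @return a tibble with columns `t_ms` (bin left edge), `rate` (smoothed,
#'   Hz) and `rate_raw` (unsmoothed, Hz).
#' @export
psth <- function(ensemble, bin_width = 0.5, smooth_sd_bins = 4) {
  stopifnot(bin_width > 0)
  t0 <- ens_t0(ensemble)
  dur <- ens_duration(ensemble)
  edges <- seq(t0, t0 + dur + bin_width, by = bin_width)
  counts <- graphics::hist(ensemble$time,
                           breaks = edges, right = FALSE,
                           plot = FALSE)$counts
  rate_raw <- counts / (n_trials(ensemble) * bin_width / 1000)
  rate <- if (smooth_sd_bins > 0) {
    gauss_smooth(rate_raw, smooth_sd_bins)
  } else {
    rate_raw
  }
  tibble::tibble(t_ms = edges[-length(edges)], rate = rate,
                 rate_raw = rate_raw)
}

# Gaussian smoothing with truncated (+/- 4 SD), edge-renormalised kernel
gauss_smooth <- function(x, sd_bins) {
  half <- ceiling(4 * sd_bins)
  k <- stats::dnorm(-half:half, sd = sd_bins)
  k <- k / sum(k)
  n <- length(x)
  num <- stats::convolve(x, rev(k), type = "open")
  den <- stats::convolve(rep(1, n), rev(k), type = "open")
  idx <- (half + 1):(half + n)
  num[idx] / den[idx]
}

#' Trial-averaged firing rate
#'
#' Per-trial spike count divided by the trial duration in seconds, averaged
#' (with sample SD) across trials sharing a condition.
#'
#' @param ensemble a [spike_ensemble()].
#' @param by trial-table columns defining a condition (character vector;
#'   empty = one group).
#' @return a tibble with `n`, `rate_mean`, `rate_sd` per condition.
#' @export
firing_rate <- function(ensemble, by = character()) {
  dur_s <- ens_duration(ensemble) / 1000
  counts <- tibble::as_tibble(ensemble) |>
    dplyr::count(.data$trial, name = "n_spikes")
  per_trial <- ens_trials(ensemble) |>
    dplyr::left_join(counts, by = "trial") |>
    dplyr::mutate(n_spikes = dplyr::coalesce(.data$n_spikes, 0L),
                  rate = .data$n_spikes / dur_s)
  per_trial |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n = dplyr::n(),
                     rate_mean = mean(.data$rate),
                     rate_sd = stats::sd(.data$rate),
                     .groups = "drop")
}

#' Spike-triggered average of the stimulus
#'
#' For every spike with at least `window_ms` of stimulus history, the
#' stimulus segment over the `window_ms` before the spike is extracted on
#' the stimulus sample grid and averaged across spikes. The lag axis runs
#' from `-window_ms` to 0 (the spike).
#'
#' @param ensemble a [spike_ensemble()].
#' @param stimulus a [stim_waveform()] covering the trial window.
#' @param window_ms history window, ms.
#' @return a tibble with columns `lag_ms` and `sta`; attribute `n_spikes`
#'   is the number of contributing spikes.
#' @export
spike_triggered_average <- function(ensemble, stimulus, window_ms = 25) {
  dt <- stim_dt(stimulus)
  n_lag <- round(window_ms / dt) + 1
  t0 <- stimulus$t_ms[1]
  # index of the last stimulus sample at or before each spike
  idx <- floor((ensemble$time - t0) / dt) + 1
  ok <- idx >= n_lag & idx <= nrow(stimulus)
  if (!any(ok)) stop("no spikes with a full stimulus history", call. = FALSE)
  idx <- idx[ok]
  seg <- vapply(idx, function(i) stimulus$current[(i - n_lag + 1):i],
                numeric(n_lag))
  out <- tibble::tibble(lag_ms = seq(-window_ms, 0, by = dt),
                        sta = rowMeans(seg))
  attr(out, "n_spikes") <- length(idx)
  out
}
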
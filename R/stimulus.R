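#' Stimulus waveforms
#'
#' A stimulus waveform is a tibble with columns `t_ms` (time, ms) and
#' `current` (injected current; dimensionless for the unscaled frozen-noise
#' template, µA/cm² once scaled for the model neuron), sampled uniformly.
#' The sample interval is carried in attribute `dt_ms`.
#'
#' @param current numeric vector of samples.
#' @param dt_ms sample interval in ms.
#' @param t0_ms time of the first sample, ms.
#' @return a `stim_waveform` tibble.
#' @export
stim_waveform <- function(current, dt_ms, t0_ms = 0) {
  stopifnot(is.numeric(current), length(current) > 0, dt_ms > 0)
  out <- tibble::tibble(
    t_ms = t0_ms + (seq_along(current) - 1) * dt_ms,
    current = as.numeric(current)
  )
  attr(out, "dt_ms") <- dt_ms
  class(out) <- c("stim_waveform", class(out))
  out
}

#' @export
print.stim_waveform <- function(x, ...) {
  cat(sprintf(
    "<stim_waveform: %d samples, dt = %g ms, duration = %g ms>\n",
    nrow(x), stim_dt(x), nrow(x) * stim_dt(x)
  ))
  NextMethod()
}

#' Sample interval of a stimulus waveform (ms)
#' @param x a `stim_waveform`.
#' @export
stim_dt <- function(x) attr(x, "dt_ms")

#' Generate the frozen-noise stimulus template h(t)
#'
#' Draws uniform white noise on \[0, 1\] at sampling rate `fs`, low-pass
#' filters it twice — first the causal first-order recursion
#' `y[n] = x[n] + 0.99 y[n-1]` (corner frequency about 100 Hz at 10 kHz),
#' then a causal 50-sample running average (5 ms) — discards the first 500
#' output samples as filter transient, and standardises the remainder to
#' zero mean and unit population variance. The same template, repeated on
#' every trial, is the "frozen noise"; trial-to-trial variability then comes
#' only from the neuron's intrinsic noise.
#'
#' Both filters use direct-form causal recursion with zero initial state.
#'
#' @param seed integer seed for the white-noise draw.
#' @param n_keep number of samples to return (10000 = 1000 ms at 10 kHz).
#' @param fs sampling rate, Hz.
#' @param n_discard transient samples dropped after filtering.
#' @return a `stim_waveform` with mean 0 and population variance 1.
#' @export
generate_frozen_noise <- function(seed, n_keep = 10000, fs = 10000,
                                  n_discard = 500) {
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (!is.numeric(n_keep) || n_keep < 1) {
    stop("`n_keep` must be at least 1", call. = FALSE)
  }
  n_raw <- n_keep + n_discard
  set.seed(seed)
  white <- stats::runif(n_raw)
  h <- frozen_noise_filters(white)
  if (length(h) <= n_discard) {
    stop("`n_keep` exceeds the filtered length after transient discard",
         call. = FALSE)
  }
  h <- h[-seq_len(n_discard)]
  h <- standardize_population(h)
  stim_waveform(h, dt_ms = 1000 / fs)
}

#' Apply the two frozen-noise filters to a raw sample vector
#'
#' Exposed as a testing hook: the first-order recursive low-pass
#' `y[n] = x[n] + 0.99 y[n-1]` followed by the causal 50-sample running
#' average, both with zero initial conditions.
#'
#' @param x numeric vector.
#' @param ar recursive coefficient of the first filter.
#' @param ma_len running-average length in samples.
#' @return filtered numeric vector, same length as `x`.
#' @export
frozen_noise_filters <- function(x, ar = 0.99, ma_len = 50) {
  y1 <- as.numeric(stats::filter(x, ar, method = "recursive", init = 0))
  if (ma_len == 1) return(y1)
  # causal moving average with zero padding (MATLAB filter semantics)
  y2 <- stats::filter(c(rep(0, ma_len - 1), y1), rep(1 / ma_len, ma_len),
                      method = "convolution", sides = 1)
  as.numeric(y2[-seq_len(ma_len - 1)])
}

standardize_population <- function(x) {
  x <- x - mean(x)
  s2 <- mean(x^2)
  if (s2 <= 0) {
    stop("cannot normalize a zero-variance waveform", call. = FALSE)
  }
  x / sqrt(s2)
}

#' Scale the frozen-noise template into an injected current
#'
#' The injected current is `I(t) = nu * (a + b * h(t))`: `a` is the relative
#' DC offset, `b` the relative fluctuation amplitude, and `nu` an overall
#' gain. For a unit-variance template the resulting offset is `nu * a` and
#' the RMS fluctuation size is `nu * |b|`.
#'
#' @param h a `stim_waveform`, normally the unscaled frozen-noise template.
#' @param nu overall gain.
#' @param a relative offset.
#' @param b relative amplitude.
#' @return a `stim_waveform` of currents.
#' @export
scale_stimulus <- function(h, nu, a, b) {
  stopifnot(inherits(h, "stim_waveform"))
  vals <- c(nu = nu, a = a, b = b)
  if (!all(is.finite(vals))) stop("nu, a, b must be finite", call. = FALSE)
  stim_waveform(nu * (a + b * h$current), dt_ms = stim_dt(h),
                t0_ms = h$t_ms[1])
}

#' Generate a frequency-modulated sinusoidal drive
#'
#' Piecewise-constant instantaneous frequency with phase continuous across
#' segment boundaries, so the waveform is a chain of upswings of equal peak
#' amplitude arriving at variable intervals and slopes. Used as a simplified
#' fluctuating drive whose "features" (upswings) are unambiguous, e.g. for
#' stimulus-reconstruction experiments.
#'
#' @param segments a data frame with columns `duration_ms` and `freq_hz`,
#'   one row per constant-frequency segment.
#' @param fs sampling rate, Hz.
#' @param amplitude peak amplitude of the sinusoid.
#' @param offset DC offset added to the waveform.
#' @return a `stim_waveform`.
#' @export
generate_fm_waveform <- function(segments, fs = 10000, amplitude = 1,
                                 offset = 0) {
  segments <- tibble::as_tibble(segments)
  if (nrow(segments) == 0) stop("`segments` must be non-empty", call. = FALSE)
  stopifnot(all(c("duration_ms", "freq_hz") %in% names(segments)))
  if (any(segments$duration_ms <= 0) || any(segments$freq_hz <= 0)) {
    stop("durations and frequencies must be positive", call. = FALSE)
  }
  dt_ms <- 1000 / fs
  # per-sample instantaneous frequency, then cumulative phase
  n_per <- round(segments$duration_ms / dt_ms)
  freq <- rep(segments$freq_hz, times = n_per)
  # phase at sample k (t = k*dt) integrates frequency over preceding samples
  dphi <- 2 * pi * freq * (dt_ms / 1000)
  phase <- c(0, cumsum(dphi))[seq_along(freq)]
  stim_waveform(offset + amplitude * sin(phase), dt_ms = dt_ms)
}

#' Default FM segment table
#'
#' Frequencies between 5 and 25 Hz in a fixed irregular order, giving about
#' 15 upswings over 1100 ms.
#'
#' @param duration_ms total duration, ms.
#' @return a tibble with `duration_ms` and `freq_hz` columns.
#' @export
fm_default_segments <- function(duration_ms = 1100) {
  freqs <- c(8, 20, 5, 14, 25, 10, 18, 6, 22, 12, 16)
  n <- length(freqs)
  tibble::tibble(duration_ms = rep(duration_ms / n, n), freq_hz = freqs)
}

#' @describeIn stim_waveform line plot of the waveform.
#' @param object a `stim_waveform`.
#' @param ... ignored.
#' @export
autoplot.stim_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_ms, y = .data$current)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "current")
}
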
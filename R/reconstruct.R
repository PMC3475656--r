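#' Event-based stimulus reconstruction
#'
#' Every detected event with reliability above `min_reliability` contributes
#' one equally weighted copy of the spike-triggered average, anchored so the
#' STA's lag-0 point sits at the event's mean time (the STA is the stimulus
#' history before a spike, so each event "paints" the 25 ms of stimulus
#' preceding it). Contributions from overlapping events sum. The summed
#' waveform is z-scored over the analysis window so it can be compared to a
#' z-scored stimulus.
#'
#' @param events an [event_set()] (or its events tibble).
#' @param sta a [spike_triggered_average()] tibble (`lag_ms`, `sta` with
#'   lags in `[-window, 0]`).
#' @param duration_ms length of the reconstruction window, ms.
#' @param dt_ms sample interval of the reconstruction grid, ms (defaults to
#'   the STA grid).
#' @param t0_ms start of the window, ms.
#' @param min_reliability events below this reliability are ignored.
#' @param standardize z-score the summed waveform (the reconstruction is
#'   linear in the event set before this step).
#' @return a `reconstruction` tibble with columns `t_ms`, `value`;
#'   attributes `contributing_events`, `min_reliability`.
#' @export
event_based_reconstruction <- function(events, sta, duration_ms,
                                       dt_ms = NULL, t0_ms = 0,
                                       min_reliability = 0.05,
                                       standardize = TRUE) {
  ev <- if (inherits(events, "event_set")) events$events else
    tibble::as_tibble(events)
  if (is.null(dt_ms)) dt_ms <- sta$lag_ms[2] - sta$lag_ms[1]
  n <- round(duration_ms / dt_ms)
  value <- numeric(n)
  keep <- ev$reliability >= min_reliability
  if (!any(keep)) {
    warning("no events above the reliability threshold; ",
            "returning a zero reconstruction")
  }
  used <- ev$event[keep]
  for (tm in ev$mean_time[keep]) {
    # grid index of the event time; STA lags are placed before it
    anchor <- round((tm - t0_ms) / dt_ms) + 1
    idx <- anchor + round(sta$lag_ms / dt_ms)
    ok <- idx >= 1 & idx <= n
    value[idx[ok]] <- value[idx[ok]] + sta$sta[ok]
  }
  if (standardize && any(keep) && stats::sd(value) > 0) {
    value <- (value - mean(value)) / stats::sd(value)
  }
  out <- tibble::tibble(t_ms = t0_ms + (seq_len(n) - 1) * dt_ms,
                        value = value)
  attr(out, "contributing_events") <- used
  attr(out, "min_reliability") <- min_reliability
  class(out) <- c("reconstruction", class(out))
  out
}

#' Correlation between a reconstruction and the true stimulus
#'
#' Pearson correlation over the common support of the two waveforms, both
#' z-scored (the correlation is invariant to that, but it keeps the
#' comparison honest when either side was offset for display).
#'
#' @param recon a [event_based_reconstruction()] tibble (`t_ms`, `value`).
#' @param stimulus a [stim_waveform()].
#' @return Pearson r, or `NA` if either side has zero variance.
#' @export
reconstruction_quality <- function(recon, stimulus) {
  t_lo <- max(min(recon$t_ms), min(stimulus$t_ms))
  t_hi <- min(max(recon$t_ms), max(stimulus$t_ms))
  r <- recon[recon$t_ms >= t_lo & recon$t_ms <= t_hi, ]
  s_at <- stats::approx(stimulus$t_ms, stimulus$current, xout = r$t_ms,
                        rule = 2)$y
  if (stats::sd(r$value) == 0 || stats::sd(s_at) == 0) return(NA_real_)
  stats::cor(r$value, s_at)
}
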
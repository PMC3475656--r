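#' Spike-train ensembles
#'
#' An ensemble holds the spike times of repeated trials. Spikes live in a
#' tidy tibble with columns `trial` (integer) and `time` (ms); a companion
#' trial table (attribute `trials`) keeps one row per trial — including
#' silent trials, which would otherwise vanish from the spike table — with
#' any condition metadata (amplitude `b`, offset `a`, gain `nu`, noise level
#' `lam`, `seed`, ...).
#'
#' @param spikes data frame with columns `trial` and `time` (ms).
#' @param trials data frame with a `trial` column, one row per trial, plus
#'   condition columns. Defaults to the trials present in `spikes`.
#' @param duration_ms trial duration, ms.
#' @param t0_ms trial start time, ms.
#' @return a `spike_ensemble` tibble of spikes.
#' @export
spike_ensemble <- function(spikes, trials = NULL, duration_ms, t0_ms = 0) {
  spikes <- tibble::as_tibble(spikes)
  stopifnot(all(c("trial", "time") %in% names(spikes)))
  if (is.null(trials)) {
    trials <- tibble::tibble(trial = sort(unique(spikes$trial)))
  }
  trials <- tibble::as_tibble(trials)
  stopifnot("trial" %in% names(trials), !anyDuplicated(trials$trial))
  if (!all(spikes$trial %in% trials$trial)) {
    stop("spike table refers to trials missing from the trial table",
         call. = FALSE)
  }
  spikes <- dplyr::arrange(spikes, .data$trial, .data$time)
  attr(spikes, "trials") <- trials
  attr(spikes, "duration_ms") <- duration_ms
  attr(spikes, "t0_ms") <- t0_ms
  class(spikes) <- unique(c("spike_ensemble", class(spikes)))
  spikes
}

#' @export
print.spike_ensemble <- function(x, ...) {
  cat(sprintf("<spike_ensemble: %d spikes, %d trials, %g ms>\n",
              nrow(x), n_trials(x), ens_duration(x)))
  NextMethod()
}

#' Trial table of an ensemble
#' @param x a `spike_ensemble`.
#' @export
ens_trials <- function(x) attr(x, "trials")

#' Number of trials (including silent ones)
#' @param x a `spike_ensemble`.
#' @export
n_trials <- function(x) nrow(ens_trials(x))

#' Trial duration (ms)
#' @param x a `spike_ensemble`.
#' @export
ens_duration <- function(x) attr(x, "duration_ms")

#' Trial start time (ms)
#' @param x a `spike_ensemble`.
#' @export
ens_t0 <- function(x) attr(x, "t0_ms")

#' Spike times split per trial
#'
#' @param x a `spike_ensemble`.
#' @return a named list of numeric vectors, one per trial (empty vectors for
#'   silent trials), in trial-table order.
#' @export
spike_trains <- function(x) {
  ids <- ens_trials(x)$trial
  out <- split(x$time, factor(x$trial, levels = ids))
  lapply(out, as.numeric)
}

#' Restrict an ensemble to a time window
#'
#' Spikes are kept on the half-open window `[from, to)`.
#'
#' @param x a `spike_ensemble`.
#' @param from,to window bounds, ms.
#' @export
window_ensemble <- function(x, from, to) {
  spikes <- dplyr::filter(tibble::as_tibble(x),
                          .data$time >= from, .data$time < to)
  spike_ensemble(spikes, trials = ens_trials(x),
                 duration_ms = to - from, t0_ms = from)
}

#' Read / write spike-train tables
#'
#' The on-disk format is a plain CSV with columns `trial`, `time` and any
#' condition columns; condition columns are constant within a trial and are
#' lifted into the trial table on read.
#'
#' @param x a `spike_ensemble`.
#' @param path file path.
#' @param duration_ms trial duration to attach on read, ms.
#' @export
write_spikes_csv <- function(x, path) {
  tab <- dplyr::left_join(tibble::as_tibble(x), ens_trials(x), by = "trial")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path, duration_ms) {
  tab <- tibble::as_tibble(utils::read.csv(path))
  extra <- setdiff(names(tab), c("trial", "time"))
  # only columns constant within each trial belong in the trial table
  constant <- vapply(extra, function(nm) {
    all(tapply(tab[[nm]], tab$trial, dplyr::n_distinct) == 1)
  }, logical(1))
  trials <- dplyr::distinct(tab[c("trial", extra[constant])])
  spike_ensemble(tab[c("trial", "time", extra[!constant])], trials = trials,
                 duration_ms = duration_ms)
}

#' Rastergram of a spike ensemble
#'
#' @param object a `spike_ensemble`.
#' @param order_by optional trial-table column used to order the rows
#'   (e.g. a condition or a pattern label), given as a string.
#' @param ... ignored.
#' @export
autoplot.spike_ensemble <- function(object, order_by = NULL, ...) {
  trials <- ens_trials(object)
  if (!is.null(order_by)) {
    trials <- dplyr::arrange(trials, .data[[order_by]])
  }
  trials$row <- seq_len(nrow(trials))
  df <- dplyr::left_join(tibble::as_tibble(object),
                         trials[c("trial", "row")], by = "trial")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$row)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (ms)", y = "trial")
}
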
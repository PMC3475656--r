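#' Specify a spike pattern for the synthetic generator
#'
#' A pattern is a stereotyped sequence of events. A trial expressing the
#' pattern emits, for each event, one spike with probability
#' `reliability`, at a time drawn from `Normal(time, jitter)`.
#' `occupation` is the probability that a trial expresses this pattern.
#'
#' @param event_times event mean times, ms.
#' @param reliabilities per-event spike probabilities in \[0, 1\].
#' @param jitters per-event Gaussian SDs, ms.
#' @param occupation probability of a trial expressing this pattern.
#' @return a `pattern_spec` list.
#' @export
pattern_spec <- function(event_times, reliabilities = 1, jitters = 1,
                         occupation = 1) {
  k <- length(event_times)
  reliabilities <- rep_len(reliabilities, k)
  jitters <- rep_len(jitters, k)
  stopifnot(all(reliabilities >= 0 & reliabilities <= 1), all(jitters >= 0),
            occupation >= 0, occupation <= 1)
  structure(list(event_times = as.numeric(event_times),
                 reliabilities = reliabilities, jitters = jitters,
                 occupation = occupation),
            class = "pattern_spec")
}

#' Generate a spike-train ensemble with known pattern structure
#'
#' Each trial first draws which pattern it expresses (by the occupation
#' probabilities), then realises that pattern's events, then receives
#' homogeneous-Poisson contaminant spikes at `noise_rate`. Jittered event
#' spikes are truncated to the trial window. The ground truth — per-trial
#' pattern labels and per-spike event labels (`NA` for contaminants) — is
#' returned alongside so recovery by the analysis pipeline can be scored.
#'
#' @param specs a list of [pattern_spec()]s; occupations must sum to 1.
#' @param n_trials number of trials.
#' @param duration_ms trial duration, ms; must cover every event time
#'   +/- 5 jitters.
#' @param noise_rate contaminant spike rate, Hz.
#' @param seed integer seed.
#' @return a [spike_ensemble()]; the trial table carries the true pattern in
#'   column `pattern`, and the spike table carries the true event index in
#'   column `event_true` (pattern-local index, `NA` for noise spikes).
#' @export
generate_pattern_ensemble <- function(specs, n_trials, duration_ms,
                                      noise_rate = 0, seed = 1) {
  if (inherits(specs, "pattern_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, n_trials >= 1)
  occ <- vapply(specs, `[[`, numeric(1), "occupation")
  if (abs(sum(occ) - 1) > 1e-8) {
    stop("pattern occupations must sum to 1", call. = FALSE)
  }
  for (sp in specs) {
    if (any(sp$event_times - 5 * sp$jitters < 0) ||
        any(sp$event_times + 5 * sp$jitters > duration_ms)) {
      stop("`duration_ms` must cover all event times +/- 5 jitters",
           call. = FALSE)
    }
    if (length(sp$event_times) > 1) {
      gaps <- diff(sort(sp$event_times))
      jit <- pmax(sp$jitters[-1], sp$jitters[-length(sp$jitters)])
      if (any(gaps < jit)) {
        warning("events closer than one jitter within a pattern: ",
                "event structure is ambiguous by construction")
      }
    }
  }
  set.seed(seed)
  labels <- sample.int(length(specs), n_trials, replace = TRUE, prob = occ)
  rows <- purrr::map(seq_len(n_trials), function(i) {
    sp <- specs[[labels[i]]]
    fire <- stats::runif(length(sp$event_times)) < sp$reliabilities
    times <- stats::rnorm(length(sp$event_times), sp$event_times, sp$jitters)
    keep <- fire & times >= 0 & times <= duration_ms
    ev <- which(keep)
    t_ev <- times[keep]
    n_noise <- stats::rpois(1, noise_rate * duration_ms / 1000)
    t_noise <- stats::runif(n_noise, 0, duration_ms)
    tibble::tibble(trial = i,
                   time = c(t_ev, t_noise),
                   event_true = c(ev, rep(NA_integer_, n_noise)))
  })
  spikes <- dplyr::bind_rows(rows)
  trials <- tibble::tibble(trial = seq_len(n_trials), pattern = labels)
  spike_ensemble(spikes, trials = trials, duration_ms = duration_ms)
}
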
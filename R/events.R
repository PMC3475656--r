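#' Event sets
#'
#' An event is a temporally localised concentration of spike-time density
#' across trials. An `event_set` bundles the per-event summary table with
#' the per-spike assignments: every input spike belongs to exactly one event
#' or is classified as noise (`event = NA`).
#'
#' @param spikes tibble with columns `trial`, `time`, `event` (integer id or
#'   `NA` for noise) and optionally `pattern`.
#' @param n_trials number of trials in the ensemble the spikes came from.
#' @param params named list of analysis parameters to record.
#' @return an `event_set`: list with `events` (summary tibble), `spikes`,
#'   `n_trials`, `params`.
#' @export
event_set <- function(spikes, n_trials, params = list()) {
  spikes <- tibble::as_tibble(spikes)
  stopifnot(all(c("trial", "time", "event") %in% names(spikes)))
  events <- summarise_events(spikes, n_trials)
  structure(list(events = events, spikes = spikes, n_trials = n_trials,
                 params = params),
            class = "event_set")
}

summarise_events <- function(spikes, n_trials) {
  assigned <- dplyr::filter(spikes, !is.na(.data$event))
  if (nrow(assigned) == 0) {
    return(tibble::tibble(event = integer(), mean_time = numeric(),
                          t_min = numeric(), t_max = numeric(),
                          n_spikes = integer(), n_trials_hit = integer(),
                          reliability = numeric(), jitter = numeric(),
                          precision = numeric(), patterns = list()))
  }
  has_pattern <- "pattern" %in% names(spikes)
  assigned |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(
      mean_time = mean(.data$time),
      t_min = min(.data$time),
      t_max = max(.data$time),
      n_spikes = dplyr::n(),
      n_trials_hit = dplyr::n_distinct(.data$trial),
      reliability = n_trials_hit / n_trials,
      jitter = if (dplyr::n() > 1) stats::sd(.data$time) else 0,
      precision = ifelse(jitter > 0, 1 / jitter, NA_real_),
      patterns = if (has_pattern) list(sort(unique(.data$pattern)))
                 else list(integer()),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean_time)
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set: %d events, %d/%d spikes assigned, %d trials>\n",
              nrow(x$events), sum(!is.na(x$spikes$event)), nrow(x$spikes),
              x$n_trials))
  print(x$events)
  invisible(x)
}

#' @export
tidy.event_set <- function(x, ...) x$events

#' @export
glance.event_set <- function(x, ...) {
  ev <- x$events
  tibble::tibble(
    n_events = nrow(ev),
    n_noise_spikes = sum(is.na(x$spikes$event)),
    reliability = mean(ev$reliability),
    jitter = mean(ev$jitter),
    precision = mean(ev$precision, na.rm = TRUE)
  )
}

#' Detect events in an aggregate spike train (interval method)
#'
#' All spikes of all trials expressing one pattern are pooled into a single
#' time-ordered aggregate train. Within an event, consecutive aggregate
#' spikes sit closer together than spikes in different events, so a new
#' event starts wherever the gap between consecutive aggregate spikes
#' exceeds `t_isi` (a gap exactly equal to `t_isi` does not split).
#'
#' @param spikes tibble with columns `trial`, `time` — the trials of one
#'   pattern.
#' @param t_isi gap threshold, ms.
#' @param n_trials trial count used for reliability (defaults to the trials
#'   present).
#' @param pattern optional pattern id recorded on the spikes.
#' @return an [event_set()].
#' @export
interval_events <- function(spikes, t_isi = 3, n_trials = NULL,
                            pattern = NA_integer_) {
  stopifnot(t_isi > 0)
  spikes <- tibble::as_tibble(spikes)
  if (is.null(n_trials)) n_trials <- dplyr::n_distinct(spikes$trial)
  spikes <- dplyr::arrange(spikes, .data$time)
  ev <- if (nrow(spikes) == 0) {
    integer()
  } else {
    cumsum(c(1L, as.integer(diff(spikes$time) > t_isi)))
  }
  spikes$event <- ev
  spikes$pattern <- pattern
  event_set(spikes, n_trials = n_trials, params = list(t_isi = t_isi))
}

#' Merge events shared between patterns (ROC analysis)
#'
#' Events found separately on each pattern may be the same underlying event.
#' For every pair of events from different patterns whose time supports
#' overlap, the spike-time samples are compared by a Mann-Whitney AUC;
#' the discriminability is `d = 2 |AUC - 0.5|`, 0 for indistinguishable
#' samples and 1 for fully separated ones. Pairs with `d <= t_roc` are
#' merged (transitively, via union-find); merged events pool their spikes,
#' keep the union of contributing patterns, and have their statistics
#' recomputed. Events from the same pattern (or sharing any pattern) are
#' never merged, which also makes the operation idempotent.
#'
#' @param event_sets a single [event_set()] whose spikes carry a `pattern`
#'   column, or a list of per-pattern event sets to combine.
#' @param t_roc discriminability threshold in \[0, 1\].
#' @param n_trials trial count of the full ensemble (defaults to the max
#'   over the inputs).
#' @return an [event_set()] with merged events renumbered by mean time.
#' @export
roc_merge <- function(event_sets, t_roc = 0.5, n_trials = NULL) {
  if (inherits(event_sets, "event_set")) event_sets <- list(event_sets)
  stopifnot(length(event_sets) >= 1, t_roc >= 0, t_roc <= 1)
  if (is.null(n_trials)) {
    n_trials <- max(vapply(event_sets, `[[`, numeric(1), "n_trials"))
  }
  # pool spikes, making event ids globally unique
  spikes <- purrr::imap(event_sets, function(es, i) {
    sp <- es$spikes
    if (!"pattern" %in% names(sp)) sp$pattern <- i
    sp$key <- paste(i, sp$event)
    sp
  }) |> dplyr::bind_rows()
  assigned <- dplyr::filter(spikes, !is.na(.data$event))
  keys <- unique(assigned$key)
  if (length(keys) == 0) {
    return(event_set(dplyr::select(spikes, -"key"), n_trials,
                     params = list(t_roc = t_roc)))
  }
  info <- assigned |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(t_min = min(.data$time), t_max = max(.data$time),
                     patterns = list(unique(.data$pattern)),
                     times = list(.data$time), .groups = "drop")
  # union-find over events
  parent <- stats::setNames(seq_len(nrow(info)), info$key)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(info))) {
    for (j in seq_len(nrow(info))) {
      if (j <= i) next
      if (length(intersect(info$patterns[[i]], info$patterns[[j]])) > 0) next
      if (info$t_min[i] > info$t_max[j] || info$t_min[j] > info$t_max[i]) next
      d <- roc_discriminability(info$times[[i]], info$times[[j]])
      if (d <= t_roc) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(nrow(info)), find, numeric(1))
  merged_id <- match(root, unique(root))
  spikes$event_merged <- merged_id[match(spikes$key, info$key)]
  out <- spikes |>
    dplyr::mutate(event = .data$event_merged) |>
    dplyr::select("trial", "time", "event", "pattern")
  # renumber events by mean time
  means <- out |>
    dplyr::filter(!is.na(.data$event)) |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(m = mean(.data$time), .groups = "drop") |>
    dplyr::arrange(.data$m)
  out$event <- match(out$event, means$event)
  event_set(out, n_trials = n_trials, params = list(t_roc = t_roc))
}

#' Mann-Whitney discriminability of two spike-time samples
#'
#' `d = 2 |AUC - 0.5|` where AUC is the rank-based probability that a random
#' spike from `x` is later than a random spike from `y` (ties count 1/2).
#' Defined for singleton samples as well.
#'
#' @param x,y numeric spike-time samples.
#' @return d in \[0, 1\].
#' @export
roc_discriminability <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  auc <- u / (length(x) * length(y))
  2 * abs(auc - 0.5)
}

#' Reclassify weakly supported events as noise
#'
#' Events whose spikes come from fewer than `min_trials` distinct trials are
#' not population events; their spikes are marked as noise.
#'
#' @param es an [event_set()].
#' @param min_trials minimum distinct trials per event.
#' @return an [event_set()].
#' @export
drop_sparse_events <- function(es, min_trials = 2) {
  weak <- es$events$event[es$events$n_trials_hit < min_trials]
  sp <- es$spikes
  sp$event[sp$event %in% weak] <- NA_integer_
  # renumber remaining events by mean time
  keep <- sort(unique(sp$event[!is.na(sp$event)]))
  sp$event <- match(sp$event, keep)
  event_set(sp, es$n_trials, params = es$params)
}

#' Per-event and condition-level event statistics
#'
#' Event reliability is the fraction of trials contributing at least one
#' spike to the event; jitter is the sample SD of the event's spike times;
#' precision is 1/jitter (undefined for single-spike events, which are
#' excluded from the condition-level averages).
#'
#' @param es an [event_set()].
#' @return a list with `events` (per-event tibble) and `summary`
#'   (one-row tibble of unweighted means across events).
#' @export
event_statistics <- function(es) {
  stopifnot(inherits(es, "event_set"))
  ev <- es$events
  list(events = ev,
       summary = tibble::tibble(
         n_events = nrow(ev),
         reliability = mean(ev$reliability),
         jitter = mean(ev$jitter),
         precision = mean(ev$precision, na.rm = TRUE)
       ))
}

#' Pattern occupation per condition
#'
#' The occupation of a pattern at a condition is the fraction of that
#' condition's trials expressing the pattern.
#'
#' @param assignment a [fcm_cluster()] result (or tibble with `trial` and
#'   `label`).
#' @param conditions optional tibble with `trial` plus condition columns;
#'   when omitted all trials form one condition.
#' @param by names of the condition columns.
#' @return a tibble with the condition columns, `label`, `n` and
#'   `occupation` (summing to 1 within a condition).
#' @export
pattern_occupation <- function(assignment, conditions = NULL,
                               by = setdiff(names(conditions), "trial")) {
  tab <- tibble::as_tibble(assignment)[c("trial", "label")]
  if (!is.null(conditions)) {
    tab <- dplyr::left_join(tab, tibble::as_tibble(conditions), by = "trial")
  } else {
    by <- character()
  }
  tab |>
    dplyr::count(dplyr::across(dplyr::all_of(by)), .data$label) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(occupation = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Full pattern-and-event analysis of one segment
#'
#' Runs the event-finding pipeline on a spike-train ensemble (one analysis
#' segment): Victor-Purpura distance matrix, gap-statistic choice of the
#' cluster count (unless `n_c` is given), fuzzy c-means pattern clustering,
#' interval-method event detection per pattern, ROC-based merging of events
#' shared between patterns, and reclassification of weakly supported events
#' as noise.
#'
#' @param ensemble a [spike_ensemble()].
#' @param q VP shift cost, 1/ms.
#' @param t_isi interval-method gap threshold, ms.
#' @param t_roc ROC merge threshold.
#' @param n_c cluster count; `NULL` selects it by [select_n_clusters()].
#' @param k_max,B_refs gap-statistic controls.
#' @param seed integer seed for clustering restarts and references.
#' @param restarts FCM restarts.
#' @param min_trials events on fewer distinct trials become noise.
#' @return a `pattern_analysis` list: `assignment`, `events`
#'   (an [event_set()]), `occupation`, `n_c`, `D`.
#' @export
find_spike_patterns <- function(ensemble, q = 0.5, t_isi = 3, t_roc = 0.5,
                                n_c = NULL, k_max = 6, B_refs = 20, seed = 1,
                                restarts = 10, min_trials = 2) {
  D <- vp_distance_matrix(ensemble, q)
  if (is.null(n_c)) {
    n_c <- select_n_clusters(D, k_max = k_max, B_refs = B_refs, seed = seed,
                             restarts = restarts)
  }
  assignment <- fcm_cluster(D, n_c, seed = seed, restarts = restarts)
  per_pattern <- lapply(seq_len(n_c), function(k) {
    ids <- assignment$trial[assignment$label == k]
    sp <- dplyr::filter(tibble::as_tibble(ensemble), .data$trial %in% ids)
    interval_events(sp[c("trial", "time")], t_isi = t_isi,
                    n_trials = n_trials(ensemble), pattern = k)
  })
  merged <- roc_merge(per_pattern, t_roc = t_roc,
                      n_trials = n_trials(ensemble))
  merged <- drop_sparse_events(merged, min_trials = min_trials)
  merged$params <- list(q = q, t_isi = t_isi, t_roc = t_roc, n_c = n_c)
  structure(list(assignment = assignment, events = merged,
                 occupation = pattern_occupation(assignment,
                                                 ens_trials(ensemble)),
                 n_c = n_c, D = D),
            class = "pattern_analysis")
}

#' @export
print.pattern_analysis <- function(x, ...) {
  cat(sprintf("<pattern_analysis: %d patterns, %d events>\n",
              x$n_c, nrow(x$events$events)))
  print(x$events$events)
  invisible(x)
}

#' @export
tidy.pattern_analysis <- function(x, ...) x$events$events

#' @export
glance.pattern_analysis <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_c = x$n_c), glance(x$events))
}
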
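#' Amplitude / offset sweeps of the model neuron
#'
#' Simulates an ensemble of noisy trials at every condition of a sweep over
#' the relative amplitude `b` (offset `a` fixed) or over the offset (`b`
#' fixed), and summarises each condition by its R-reliability and its
#' spike-count mean and SD across trials. Dips of the (3-point smoothed)
#' reliability curve that coincide with changes in mean spike count flag
#' bifurcation candidates: stimulus strengths at which the spike sequence
#' reorganises and multiple patterns coexist.
#'
#' Per-trial seeds are derived deterministically from `base_seed`, the
#' condition index and the trial index, so any single condition can be
#' reproduced in isolation.
#'
#' @param params a [wb_params()] list.
#' @param h the unscaled frozen-noise template ([stim_waveform()]).
#' @param amplitudes relative amplitudes `b` (sorted).
#' @param offsets relative offsets `a` (sorted).
#' @param a,b the fixed offset / amplitude for the respective scan.
#' @param nu overall gain.
#' @param n_trials trials per condition.
#' @param lam noise intensity, mV²/ms.
#' @param sigma R-reliability timescale, ms.
#' @param dt integration step, ms.
#' @param base_seed integer seed.
#' @return a `scan_result` tibble with one row per condition: `cond`, `a`,
#'   `b`, `R_raw`, `R_smooth`, `count_mean`, `count_sd`, `rate_mean`;
#'   attribute `candidates` holds [detect_bifurcation_candidates()] output.
#' @export
scan_amplitude <- function(params, h, amplitudes, a = 0.2, nu = 1,
                           n_trials = 25, lam = 0.00025, sigma = 1,
                           dt = 0.05, base_seed = 1) {
  stopifnot(!is.unsorted(amplitudes))
  conds <- tibble::tibble(cond = seq_along(amplitudes), a = a,
                          b = amplitudes)
  run_scan(params, h, conds, nu, n_trials, lam, sigma, dt, base_seed)
}

#' @rdname scan_amplitude
#' @export
scan_offset <- function(params, h, offsets, b = 0.5, nu = 1,
                        n_trials = 25, lam = 0.00025, sigma = 1,
                        dt = 0.05, base_seed = 1) {
  stopifnot(!is.unsorted(offsets))
  conds <- tibble::tibble(cond = seq_along(offsets), a = offsets, b = b)
  run_scan(params, h, conds, nu, n_trials, lam, sigma, dt, base_seed)
}

run_scan <- function(params, h, conds, nu, n_trials, lam, sigma, dt,
                     base_seed) {
  rows <- purrr::pmap(conds, function(cond, a, b) {
    stim <- scale_stimulus(h, nu = nu, a = a, b = b)
    seeds <- scan_seeds(base_seed, cond, n_trials)
    ens <- simulate_ensemble(params, stim, seeds = seeds, dt = dt, lam = lam,
                             condition = list(a = a, b = b, nu = nu))
    counts <- vapply(spike_trains(ens), length, integer(1))
    R <- if (all(counts == 0)) NA_real_ else r_reliability(ens, sigma)$R
    tibble::tibble(cond = cond, a = a, b = b, R_raw = R,
                   count_mean = mean(counts), count_sd = stats::sd(counts),
                   rate_mean = mean(counts) / (ens_duration(ens) / 1000))
  })
  out <- dplyr::bind_rows(rows)
  out$R_smooth <- running_mean3(out$R_raw)
  out <- out[c("cond", "a", "b", "R_raw", "R_smooth", "count_mean",
               "count_sd", "rate_mean")]
  class(out) <- c("scan_result", class(out))
  attr(out, "sigma") <- sigma
  attr(out, "lam") <- lam
  attr(out, "candidates") <- detect_bifurcation_candidates(out)
  out
}

#' Deterministic per-trial seeds for a sweep
#'
#' @param base_seed integer base seed.
#' @param cond condition index.
#' @param n_trials trials per condition.
#' @return integer vector of distinct seeds (kept well below 2^31).
#' @export
scan_seeds <- function(base_seed, cond, n_trials) {
  as.integer((base_seed %% 100000L) * 10000L + cond * 100L +
               seq_len(n_trials))
}

#' Three-point running average with shrinking endpoints
#'
#' Interior points average their two neighbours and themselves; endpoints
#' average over the available window. `NA`s are dropped from each window.
#'
#' @param x numeric vector.
#' @return smoothed vector, same length.
#' @export
running_mean3 <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - 1):min(n, i + 1)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Flag bifurcation candidates on a scan
#'
#' A bifurcation candidate is an interior strict local minimum of the
#' smoothed reliability curve, at least `min_depth` below the lower of its
#' flanking local maxima, that lies within one condition step of a change in
#' rounded mean spike count. At such stimulus strengths a small parameter
#' change reorganises the spike sequence, so trial-to-trial noise produces
#' coexisting patterns and the reliability dips.
#'
#' On a densely sampled sweep the dip is visible in the smoothed curve; on a
#' coarse grid the 3-point average can erase it, so detection defaults to
#' the raw curve.
#'
#' @param scan a `scan_result` (or tibble with `R_raw`, `R_smooth` and
#'   `count_mean`).
#' @param min_depth minimum dip depth in R units.
#' @param curve which reliability curve to scan for dips.
#' @param require_count_change if `FALSE`, dips qualify regardless of the
#'   spike count.
#' @return integer vector of condition indices.
#' @export
detect_bifurcation_candidates <- function(scan, min_depth = 0.02,
                                          curve = c("raw", "smooth"),
                                          require_count_change = TRUE) {
  curve <- match.arg(curve)
  r <- if (curve == "raw") scan$R_raw else scan$R_smooth
  n <- length(r)
  if (n < 3) return(integer())
  count_step <- c(FALSE, diff(round(scan$count_mean)) != 0)
  out <- integer()
  for (i in 2:(n - 1)) {
    if (any(is.na(r[(i - 1):(i + 1)]))) next
    if (!(r[i] < r[i - 1] && r[i] < r[i + 1])) next
    left_max <- max(r[1:(i - 1)], na.rm = TRUE)
    right_max <- max(r[(i + 1):n], na.rm = TRUE)
    if (min(left_max, right_max) - r[i] < min_depth) next
    if (require_count_change) {
      near <- count_step[max(2, i - 1):min(n, i + 1)]
      if (!any(near)) next
    }
    out <- c(out, i)
  }
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cand <- attr(x, "candidates")
  cat(sprintf("<scan_result: %d conditions, %d bifurcation candidate(s)%s>\n",
              nrow(x), length(cand),
              if (length(cand)) paste0(" at cond ",
                                       paste(cand, collapse = ", ")) else ""))
  NextMethod()
}

#' @export
glance.scan_result <- function(x, ...) {
  tibble::tibble(n_conditions = nrow(x),
                 n_candidates = length(attr(x, "candidates")),
                 sigma = attr(x, "sigma"), lam = attr(x, "lam"))
}

#' @export
autoplot.scan_result <- function(object, ...) {
  xvar <- if (length(unique(object$b)) > 1) "b" else "a"
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c(xvar, "R_smooth", "count_mean", "count_sd")],
    -dplyr::all_of(xvar), names_to = "measure"
  )
  cand <- attr(object, "candidates")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = if (xvar == "b") "relative amplitude b"
                  else "relative offset a", y = NULL)
  if (length(cand)) {
    p <- p + ggplot2::geom_vline(xintercept = object[[xvar]][cand],
                                 linetype = "dashed", colour = "grey50")
  }
  p
}
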
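#' Fuzzy c-means clustering of trials into spike patterns
#'
#' Trials expressing the same spike pattern have mutually small
#' Victor-Purpura distances: re-ordered by pattern, the distance matrix is
#' block-diagonal. Clustering uses the columns of the distance matrix as
#' feature vectors (trial i is described by its distance profile to every
#' trial) and standard fuzzy c-means (FCM) with Euclidean distance in that
#' feature space, run `restarts` times from seeded random initialisations
#' and keeping the run with the lowest objective. Hard labels are the
#' argmax memberships, ties to the lowest cluster index.
#'
#' FCM itself is delegated to [e1071::cmeans()].
#'
#' @param D a [vp_distance_matrix()] (or any symmetric matrix).
#' @param n_c number of clusters (1 <= n_c <= n_trials).
#' @param fuzzifier FCM fuzziness exponent m.
#' @param seed integer seed for the restarts.
#' @param restarts number of random restarts.
#' @param max_iter,tol FCM iteration controls.
#' @return a `pattern_assignment`: tibble with columns `trial` and `label`,
#'   attributes `membership` (n_trials x n_c matrix), `n_c` and `objective`.
#' @export
fcm_cluster <- function(D, n_c, fuzzifier = 2, seed = 1, restarts = 10,
                        max_iter = 1000, tol = 1e-6) {
  fcm_features(feature_columns(D), n_c, fuzzifier = fuzzifier, seed = seed,
               restarts = restarts, max_iter = max_iter)
}

# FCM on an arbitrary feature matrix (rows = observations)
fcm_features <- function(x, n_c, fuzzifier = 2, seed = 1, restarts = 10,
                         max_iter = 1000) {
  n <- nrow(x)
  if (n_c > n) stop("`n_c` cannot exceed the number of trials", call. = FALSE)
  stopifnot(n_c >= 1)
  if (n_c == 1) {
    memb <- matrix(1, nrow = n, ncol = 1)
    return(new_pattern_assignment(rep(1L, n), memb, objective = 0))
  }
  # seeded restarts must not disturb the caller's RNG stream (the gap
  # statistic draws reference data around these calls)
  best <- withr::with_preserve_seed({
    best <- NULL
    for (r in seq_len(restarts)) {
      set.seed(seed + r - 1)
      fit <- tryCatch(
        e1071::cmeans(x, centers = n_c, m = fuzzifier, iter.max = max_iter,
                      method = "cmeans"),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      if (is.null(best) || fit$withinerror < best$withinerror) best <- fit
    }
    best
  })
  if (is.null(best)) stop("fuzzy c-means failed on all restarts",
                          call. = FALSE)
  memb <- unname(best$membership)
  labels <- apply(memb, 1, which.max)  # which.max ties -> lowest index
  new_pattern_assignment(as.integer(labels), memb,
                         objective = best$withinerror)
}

feature_columns <- function(D) {
  D <- unclass(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  # column i is trial i's distance profile; rows of x are the feature vectors
  t(D)
}

new_pattern_assignment <- function(labels, membership, objective = NA_real_) {
  out <- tibble::tibble(trial = seq_along(labels), label = labels)
  attr(out, "membership") <- membership
  attr(out, "n_c") <- ncol(membership)
  attr(out, "objective") <- objective
  class(out) <- c("pattern_assignment", class(out))
  out
}

#' @export
print.pattern_assignment <- function(x, ...) {
  cat(sprintf("<pattern_assignment: %d trials, %d clusters>\n",
              nrow(x), attr(x, "n_c")))
  NextMethod()
}

#' @export
tidy.pattern_assignment <- function(x, ...) {
  memb <- attr(x, "membership")
  colnames(memb) <- paste0("p", seq_len(ncol(memb)))
  dplyr::bind_cols(tibble::as_tibble(x), tibble::as_tibble(memb))
}

#' @export
glance.pattern_assignment <- function(x, ...) {
  tibble::tibble(n_c = attr(x, "n_c"), n_trials = nrow(x),
                 objective = attr(x, "objective"),
                 mean_max_membership = mean(apply(attr(x, "membership"), 1,
                                                  max)))
}

#' Choose the number of spike patterns by a weighted gap statistic
#'
#' Estimates the cluster count from the distance matrix by a gap-statistic
#' heuristic adapted to distance-profile data. Trials are embedded in a
#' low-dimensional space by classical multidimensional scaling of the
#' distance matrix; at each candidate k the FCM labelling's within-cluster
#' dispersion is summarised by the size-weighted (per-pair) measure
#' `W(k) = sum_r D_r / (n_r (n_r - 1))` (Yan & Ye's weighted form, which is
#' insensitive to peeling off small sub-clusters), and compared on the log
#' scale to `B_refs` reference datasets drawn uniformly over the bounding
#' box of the embedded points: `Gap(k) = E log W_ref(k) - log W(k)`.
#'
#' The chosen k is the smaller of two candidates: (i) the smallest k with
#' non-negative gap satisfying the one-standard-error rule
#' `Gap(k) >= Gap(k+1) - s(k+1)` (a negative gap means the clustering at
#' that k fits worse than the structureless reference — typically a poor
#' intermediate-k partition below the true count — and is not a valid
#' stopping point); and (ii) the elbow of the gap curve, the k maximising
#' its second difference. The elbow covers ensembles whose gap keeps
#' creeping upward because spike unreliability creates weak sub-structure
#' inside true patterns.
#'
#' @inheritParams fcm_cluster
#' @param k_max largest cluster count considered.
#' @param B_refs number of reference datasets.
#' @param restarts FCM restarts per candidate k.
#' @param ndim embedding dimensions for the scaling step.
#' @return chosen cluster count (integer).
#' @export
select_n_clusters <- function(D, k_max = 6, B_refs = 20, seed = 1,
                              fuzzifier = 2, restarts = 5, ndim = 4) {
  stopifnot(k_max >= 1)
  Dm <- unclass(D)
  stopifnot(is.matrix(Dm), nrow(Dm) == ncol(Dm))
  n <- nrow(Dm)
  k_max <- min(k_max, n - 1L)
  # degenerate ensembles (all trials identical) carry no cluster structure
  if (k_max < 2 || max(Dm) < 1e-12) return(1L)
  x <- stats::cmdscale(Dm, k = min(ndim, n - 1))
  log_wbar <- function(x) {
    vapply(seq_len(k_max), function(k) {
      lab <- fcm_features(as.matrix(x), k, fuzzifier = fuzzifier,
                          seed = seed, restarts = restarts)$label
      w <- sum(vapply(unique(lab), function(g) {
        xs <- x[lab == g, , drop = FALSE]
        m <- nrow(xs)
        if (m < 2) 0 else sum(stats::dist(xs)^2) / (m * (m - 1))
      }, numeric(1)))
      log(w)
    }, numeric(1))
  }
  lw <- log_wbar(x)
  set.seed(seed)
  rng <- apply(x, 2, range)
  ref <- vapply(seq_len(B_refs), function(b) {
    xr <- apply(rng, 2, function(r) stats::runif(n, r[1], r[2]))
    log_wbar(xr)
  }, numeric(k_max))
  gap <- rowMeans(ref) - lw
  se <- apply(ref, 1, stats::sd) * sqrt(1 + 1 / B_refs)
  fire <- c(head(gap, -1) >= gap[-1] - se[-1], TRUE) & gap >= 0
  k_se <- if (any(fire)) which(fire)[1] else Inf
  d1 <- diff(gap)
  dd <- head(d1, -1) - d1[-1]
  k_dd <- if (length(dd)) which.max(dd) + 1 else Inf
  as.integer(min(k_se, k_dd, k_max))
}

#' Cut trials into analysis segments at quiet times
#'
#' The pattern analysis works on short segments holding roughly two to six
#' events. Boundaries are placed at local minima of the smoothed PSTH that
#' fall below `rate_threshold`, choosing the sub-threshold minimum nearest
#' to each multiple of `target_len_ms`; if no sub-threshold minimum exists
#' near a target boundary the cut falls back to the fixed position (with a
#' warning when that happens for every boundary).
#'
#' @param ensemble a [spike_ensemble()].
#' @param psth_curve optional precomputed [psth()] tibble.
#' @param target_len_ms nominal segment length, ms.
#' @param rate_threshold boundary rate ceiling, Hz; default half the mean
#'   smoothed rate.
#' @return a tibble with columns `segment`, `start`, `end` (half-open
#'   windows `[start, end)` covering the trial).
#' @export
segment_trials <- function(ensemble, psth_curve = NULL, target_len_ms = 500,
                           rate_threshold = NULL) {
  t0 <- ens_t0(ensemble)
  dur <- ens_duration(ensemble)
  n_seg <- max(1L, round(dur / target_len_ms))
  if (n_seg == 1L) {
    return(tibble::tibble(segment = 1L, start = t0, end = t0 + dur))
  }
  if (is.null(psth_curve)) psth_curve <- psth(ensemble)
  r <- psth_curve$rate
  if (is.null(rate_threshold)) rate_threshold <- 0.5 * mean(r)
  interior <- seq(2, length(r) - 1)
  is_min <- r[interior] <= r[interior - 1] & r[interior] <= r[interior + 1] &
    r[interior] <= rate_threshold
  cand <- psth_curve$t_ms[interior[is_min]]
  targets <- t0 + (seq_len(n_seg - 1)) * dur / n_seg
  cuts <- vapply(targets, function(tt) {
    if (length(cand) == 0) return(NA_real_)
    ok <- cand[abs(cand - tt) <= 0.5 * target_len_ms]
    if (length(ok) == 0) NA_real_ else ok[which.min(abs(ok - tt))]
  }, numeric(1))
  if (all(is.na(cuts))) {
    warning("no sub-threshold PSTH minima; falling back to fixed-length cuts")
  }
  cuts[is.na(cuts)] <- targets[is.na(cuts)]
  cuts <- sort(unique(cuts))
  edges <- c(t0, cuts, t0 + dur)
  tibble::tibble(segment = seq_len(length(edges) - 1),
                 start = edges[-length(edges)], end = edges[-1])
}
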
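#' Class distribution of a classification
#'
#' A classification assigns each trial a class index in `1..n_classes`
#' (e.g. the spike pattern expressed on a segment). The class distribution
#' is the fraction of trials in each class; classes with no trials get
#' probability 0.
#'
#' @param labels integer class labels.
#' @param n_classes number of classes (default: max label).
#' @return numeric probability vector of length `n_classes`.
#' @export
class_distribution <- function(labels, n_classes = max(labels)) {
  labels <- as.integer(labels)
  stopifnot(length(labels) >= 1, all(labels >= 1), all(labels <= n_classes))
  tabulate(labels, nbins = n_classes) / length(labels)
}

#' Shannon entropy of a probability vector (bits)
#'
#' `S = -sum p log2 p` over the nonzero entries (0 log 0 = 0). Zero when all
#' mass sits in one class, maximal at `log2(n_classes)` for the uniform
#' distribution.
#'
#' @param p probability vector (must sum to 1).
#' @return entropy in bits.
#' @export
entropy_bits <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1",
                                   call. = FALSE)
  p <- p[p > 0]
  -sum(p * log2(p)) + 0  # "+ 0" avoids IEEE -0 for degenerate p
}

#' Resampling bias and spread of a plug-in entropy estimate
#'
#' Treats the observed class distribution as exact, draws `n_resamples`
#' multinomial datasets of `n_trials` trials from it, and recomputes the
#' plug-in entropy of each. The bias is the mean resampled entropy minus the
#' original entropy (negative for the downward-biased plug-in estimator);
#' the spread is the SD of the resampled values.
#'
#' @param p observed class distribution.
#' @param n_trials trials behind the estimate.
#' @param n_resamples number of multinomial resamples.
#' @param seed integer seed.
#' @return a tibble with columns `entropy`, `bias`, `std`.
#' @export
entropy_resample <- function(p, n_trials, n_resamples = 1000, seed = 1) {
  stopifnot(n_trials >= 1)
  s0 <- entropy_bits(p)
  set.seed(seed)
  counts <- stats::rmultinom(n_resamples, n_trials, p)
  s <- apply(counts, 2, function(k) entropy_bits(k / n_trials))
  tibble::tibble(entropy = s0, bias = mean(s) - s0, std = stats::sd(s))
}

#' Mutual information between two classifications (bits)
#'
#' The joint distribution is the co-occurrence frequency of class pairs
#' across trials; the mutual information is the plug-in
#' `I = sum p_ij log2(p_ij / (p_i p_j))`. No bias correction is applied;
#' report a resampled bias alongside when needed.
#'
#' @param c_labels,d_labels integer class labels, one per trial.
#' @param n_c,n_d class counts.
#' @return mutual information in bits.
#' @export
mutual_information <- function(c_labels, d_labels, n_c = max(c_labels),
                               n_d = max(d_labels)) {
  if (length(c_labels) != length(d_labels)) {
    stop("classifications must have the same number of trials",
         call. = FALSE)
  }
  joint <- table(factor(c_labels, levels = seq_len(n_c)),
                 factor(d_labels, levels = seq_len(n_d)))
  p <- joint / sum(joint)
  pc <- rowSums(p)
  pd <- colSums(p)
  terms <- p * log2(p / outer(pc, pd))
  sum(terms[p > 0])
}

#' Normalized mutual information
#'
#' `I_N = I(c, d) / max(S(c), S(d))`, a number in \[0, 1\] equal to 1 exactly
#' when the two classifications are identical up to relabelling. When both
#' classifications are degenerate (zero entropy) each trivially determines
#' the other and `I_N = 1` by convention.
#'
#' @inheritParams mutual_information
#' @return normalized mutual information in \[0, 1\].
#' @export
normalized_mi <- function(c_labels, d_labels, n_c = max(c_labels),
                          n_d = max(d_labels)) {
  s_c <- entropy_bits(class_distribution(c_labels, n_c))
  s_d <- entropy_bits(class_distribution(d_labels, n_d))
  if (s_c == 0 && s_d == 0) return(1)
  mutual_information(c_labels, d_labels, n_c, n_d) / max(s_c, s_d)
}
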
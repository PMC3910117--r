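#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = tp / (tp + fn)`, `specificity = tn / (tn + fp)`, where
#' a positive is a model-following (time-course) profile and a negative a
#' noise profile.
#'
#' @param tp,fp,tn,fn Nonnegative integer counts.
#' @return Named list with `sensitivity` and `specificity`.
#' @export
sensitivity_specificity <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0))
  if (tp + fn == 0 || tn + fp == 0) {
    stop("undefined metric: a class has no members", call. = FALSE)
  }
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Sweep classification thresholds over observed F values
#'
#' Evaluates sensitivity and specificity at every distinct observed F
#' value used as a threshold (predict model-following when `F >
#' threshold`). As the threshold rises, sensitivity is non-increasing and
#' specificity non-decreasing. The returned table carries the
#' best-operating-point attribute: the threshold maximising
#' `min(sensitivity, specificity)`.
#'
#' @param f_values Numeric scores, one per profile.
#' @param truth Logical (or 0/1) vector: `TRUE` for a genuine
#'   model-following profile.
#' @return data.frame with columns `threshold`, `sensitivity`,
#'   `specificity`; attribute `best` holds the best row as a list.
#' @export
threshold_sweep <- function(f_values, truth) {
  truth <- as.logical(truth)
  stopifnot(length(f_values) == length(truth), length(truth) > 0)
  if (all(truth) || !any(truth)) {
    stop("threshold sweep needs both classes present", call. = FALSE)
  }
  thr <- sort(unique(f_values))
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  # predict positive when F > thr: counts via cumulative sums over the
  # sorted distinct thresholds
  sens <- vapply(thr, function(s) sum(f_values > s & truth) / n_pos,
                 numeric(1))
  spec <- vapply(thr, function(s) sum(f_values <= s & !truth) / n_neg,
                 numeric(1))
  out <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  best <- which.max(pmin(sens, spec))
  attr(out, "best") <- list(threshold = thr[best],
                            sensitivity = sens[best],
                            specificity = spec[best],
                            min_sens_spec = min(sens[best], spec[best]))
  out
}

#' Adjusted Rand index between two partitions
#'
#' The Hubert-Arabie chance-corrected agreement between two labellings of
#' the same N objects:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12\left[\sum_i\binom{n_{i\cdot}}{2} + \sum_j\binom{n_{\cdot j}}{2}\right] - E},
#' \quad E = \frac{\sum_i\binom{n_{i\cdot}}{2}\sum_j\binom{n_{\cdot j}}{2}}{\binom{N}{2}}}
#' built from the contingency table `n_ij` of the two partitions. It is 1
#' for identical partitions, has expectation 0 for random ones, is
#' symmetric, and is invariant to relabelling either partition. When both
#' partitions are the trivial single cluster the index is defined as 1
#' (perfect agreement).
#'
#' @param labels_u,labels_v Vectors of cluster labels, equal length >= 2
#'   (any type coercible to factor).
#' @return ARI value (<= 1).
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)) # -0.5
adjusted_rand_index <- function(labels_u, labels_v) {
  if (length(labels_u) != length(labels_v)) {
    stop("partitions label different numbers of objects", call. = FALSE)
  }
  N <- length(labels_u)
  stopifnot(N >= 2)
  nij <- table(labels_u, labels_v)
  sum_ij <- sum(choose(nij, 2))
  sum_i <- sum(choose(rowSums(nij), 2))
  sum_j <- sum(choose(colSums(nij), 2))
  expected <- sum_i * sum_j / choose(N, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Average adjusted Rand index over repeated clustering runs
#'
#' The mean of [adjusted_rand_index()] between each run's labels and a
#' reference partition (typically the generating truth). Used to score
#' the stability/quality of a stochastic clustering algorithm across
#' restarts.
#'
#' @param label_sets List of label vectors (one per run).
#' @param reference_labels Reference partition.
#' @return Mean ARI.
#' @export
aari <- function(label_sets, reference_labels) {
  stopifnot(length(label_sets) >= 1)
  mean(vapply(label_sets, adjusted_rand_index, numeric(1),
              labels_v = reference_labels))
}
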
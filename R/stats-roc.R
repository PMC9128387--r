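#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a classification threshold over the unique score values and
#' reports sensitivity/specificity at each threshold plus the area under
#' the curve by trapezoidal integration. With ties handled at unique
#' thresholds, the trapezoid AUC equals the Mann-Whitney statistic: the
#' probability that a random positive outscores a random negative, ties
#' counted one half.
#'
#' @param scores Numeric scores, larger = more positive-like.
#' @param labels Logical (or 0/1) vector, `TRUE` = positive class.
#' @return List of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`. If only one class is present, `auc` is
#'   `NA_real_` and the arrays are empty.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    return(structure(list(thresholds = numeric(0), sensitivity = numeric(0),
                          specificity = numeric(0), auc = NA_real_),
                     class = "roc_result"))
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # cumulative positives/negatives at each unique threshold (score >= thr)
  last_of_thr <- cumsum(tabulate(match(s, thr), nbins = length(thr)))
  tp <- cumsum(l)[last_of_thr]
  fp <- cumsum(!l)[last_of_thr]
  sens <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
  structure(list(thresholds = c(Inf, thr),
                 sensitivity = sens,
                 specificity = 1 - fpr,
                 auc = auc),
            class = "roc_result")
}

# Fast AUC via the rank identity; equals roc_auc()$auc (property-tested).
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap CI for an AUC, and a paired AUC-difference test
#'
#' `bootstrap_auc_ci()` resamples contacts with replacement, stratified by
#' class (so both classes are always represented and no redraws are
#' needed), recomputes the AUC per replicate, and returns the 2.5/97.5
#' percentile bounds. `auc_diff_test()` compares two score vectors over the
#' same contacts with a paired bootstrap: the two-sided p-value is twice
#' the smaller tail fraction of replicates in which the AUC difference
#' crosses zero.
#'
#' @param scores Numeric scores (for the difference test, `scores_a` and
#'   `scores_b` scored on the same contacts).
#' @param labels Logical class labels.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return `bootstrap_auc_ci()`: list with `auc`, `lo`, `hi`, `n_boot`,
#'   `n_redraws` (always 0 under stratified resampling, retained for the
#'   record), and the replicate vector. `auc_diff_test()`: list with
#'   `auc_a`, `auc_b`, `delta`, `p_value`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 1000, seed = 1L) {
  stopifnot(n_boot >= 1)
  labels <- as.logical(labels)
  i1 <- which(labels); i0 <- which(!labels)
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(i1, length(i1), replace = TRUE),
             sample(i0, length(i0), replace = TRUE))
    auc_rank(scores[idx], labels[idx])
  }, numeric(1)))
  ci <- unname(quantile(reps, c(0.025, 0.975), type = 7))
  list(auc = auc_rank(scores, labels), lo = ci[1], hi = ci[2],
       n_boot = n_boot, n_redraws = 0L, replicates = reps)
}

#' @rdname bootstrap_auc_ci
#' @param scores_a,scores_b Two score vectors over the same contacts.
#' @export
auc_diff_test <- function(scores_a, scores_b, labels, n_boot = 1000,
                          seed = 1L) {
  stopifnot(length(scores_a) == length(scores_b))
  labels <- as.logical(labels)
  i1 <- which(labels); i0 <- which(!labels)
  d <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(i1, length(i1), replace = TRUE),
             sample(i0, length(i0), replace = TRUE))
    auc_rank(scores_a[idx], labels[idx]) - auc_rank(scores_b[idx], labels[idx])
  }, numeric(1)))
  p <- 2 * min(mean(d <= 0), mean(d >= 0))
  list(auc_a = auc_rank(scores_a, labels), auc_b = auc_rank(scores_b, labels),
       delta = mean(d), p_value = min(p, 1))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' 95% confidence interval for a proportion from `successes` out of `n`
#' Bernoulli trials, by the exact binomial method.
#'
#' @param successes Number of successes, `0 <= successes <= n`.
#' @param n Number of trials, `>= 1`.
#' @param conf_level Confidence level (default 0.95).
#' @return Numeric vector `c(lo, hi)`.
#' @export
binom_ci <- function(successes, n, conf_level = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  ci <- binom.test(successes, n, conf.level = conf_level)$conf.int
  c(lo = ci[1], hi = ci[2])
}
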
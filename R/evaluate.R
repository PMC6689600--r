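#' ROC and precision-recall curves
#'
#' Both curves are built from a single threshold sweep over the unique score
#' values in descending order (questions with tied scores enter together).
#' The AUROC equals the normalized Mann-Whitney U statistic, with tied
#' score pairs receiving half credit; the AUPR is the non-interpolated
#' average precision (precision at each threshold weighted by the recall it
#' adds).
#'
#' @param scores Numeric vector of per-question scores (higher = more yes).
#' @param truth A [ground_truth()] (aligned by position) or a 0/1 vector.
#' @return `roc_curve()`: a tibble of `(fpr, tpr)` vertices from (0,0) to
#'   (1,1) with the `auroc` as an attribute and via `auroc()`. `pr_curve()`:
#'   a tibble of `(recall, precision)` with attribute `aupr`.
#' @examples
#' roc_curve(c(4, 3, 2, 1), c(1, 1, 0, 0))
#' @export
roc_curve <- function(scores, truth) {
  y <- as_binary_truth(truth, length(scores))
  sw <- threshold_sweep(scores, y)
  out <- tibble::tibble(fpr = c(0, sw$fp / sw$n0), tpr = c(0, sw$tp / sw$n1))
  attr(out, "auroc") <- auroc(scores, y)
  class(out) <- c("roc_points", class(out))
  out
}

#' @rdname roc_curve
#' @export
pr_curve <- function(scores, truth) {
  y <- as_binary_truth(truth, length(scores))
  sw <- threshold_sweep(scores, y)
  recall <- sw$tp / sw$n1
  precision <- sw$tp / (sw$tp + sw$fp)
  out <- tibble::tibble(recall = recall, precision = precision)
  attr(out, "aupr") <- sum(diff(c(0, recall)) * precision)
  class(out) <- c("pr_points", class(out))
  out
}

#' @rdname roc_curve
#' @export
auroc <- function(scores, truth) {
  if (inherits(scores, "roc_points")) return(attr(scores, "auroc"))
  y <- as_binary_truth(truth, length(scores))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname roc_curve
#' @export
aupr <- function(scores, truth) {
  if (inherits(scores, "pr_points")) return(attr(scores, "aupr"))
  attr(pr_curve(scores, truth), "aupr")
}

# cumulative TP/FP counts at each unique descending threshold
threshold_sweep <- function(scores, y) {
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    abort("Ground truth must contain both classes for ROC/PR computation.")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  list(tp = cumsum(yy)[keep], fp = cumsum(1 - yy)[keep], n1 = n1, n0 = n0)
}

as_binary_truth <- function(truth, n) {
  y <- if (is.data.frame(truth)) ground_truth(truth)$label else as.numeric(truth)
  if (length(y) != n) abort("Scores and truth have different lengths.")
  if (!all(y %in% c(0, 1))) abort("Truth labels must be 0/1.")
  y
}

#' Orientation-maximized evaluation of a consensus score
#'
#' A one-dimensional embedding is defined only up to global sign, so metrics
#' are computed on both the scores and their negative, and the better
#' orientation is reported per metric (ties keep the original orientation).
#' The same treatment is applied to supervised baselines in the
#' cross-validation harness so comparisons are fair.
#'
#' @inheritParams roc_curve
#' @return A `crowd_eval` object (list) with `auroc_raw`, `auroc_oriented`,
#'   `aupr_oriented`, per-metric `flipped` flags and the oriented `roc` and
#'   `pr` curves. Use [glance()] for a one-row summary.
#' @export
evaluate_oriented <- function(scores, truth) {
  y <- as_binary_truth(truth, length(scores))
  a_fwd <- auroc(scores, y)
  a_rev <- auroc(-scores, y)
  flip_roc <- a_rev > a_fwd
  p_fwd <- aupr(scores, y)
  p_rev <- aupr(-scores, y)
  flip_pr <- p_rev > p_fwd
  structure(list(
    auroc_raw = a_fwd,
    auroc_oriented = max(a_fwd, a_rev),
    aupr_oriented = max(p_fwd, p_rev),
    flipped_roc = flip_roc,
    flipped_pr = flip_pr,
    roc = roc_curve(if (flip_roc) -scores else scores, y),
    pr = pr_curve(if (flip_pr) -scores else scores, y)
  ), class = "crowd_eval")
}

#' @exportS3Method base::print
print.crowd_eval <- function(x, ...) {
  cat(sprintf("Oriented evaluation: AUROC %.4f%s, AUPR %.4f%s (raw AUROC %.4f)\n",
              x$auroc_oriented, if (x$flipped_roc) " (flipped)" else "",
              x$aupr_oriented, if (x$flipped_pr) " (flipped)" else "",
              x$auroc_raw))
  invisible(x)
}

#' Operating point of a binary prediction
#'
#' @param predictions 0/1 vector of predicted labels.
#' @inheritParams roc_curve
#' @return A one-row tibble with `fpr` and `tpr`.
#' @export
binary_point <- function(predictions, truth) {
  y <- as_binary_truth(truth, length(predictions))
  p <- as.numeric(predictions)
  if (!all(p %in% c(0, 1))) abort("Predictions must be 0/1.")
  tibble::tibble(fpr = sum(p == 1 & y == 0) / sum(y == 0),
                 tpr = sum(p == 1 & y == 1) / sum(y == 1))
}

#' TPR advantage of a continuous aggregate at a binary method's FPR
#'
#' Evaluates the oriented ROC curve of `scores` at the false-positive rate of
#' `predictions` (linear interpolation between adjacent ROC vertices; at a
#' vertex shared by a vertical segment the upper point is used) and returns
#' that TPR minus the binary method's TPR. Positive values mean the
#' continuous aggregate dominates the binary one at its own operating point.
#'
#' @inheritParams binary_point
#' @param scores Continuous consensus scores.
#' @return A single number, or `NA` with a warning when `predictions` is
#'   single-valued (degenerate operating point).
#' @export
tpr_difference_at_matched_fpr <- function(scores, predictions, truth) {
  p <- as.numeric(predictions)
  if (length(unique(p)) < 2) {
    warn("Binary predictions are single-valued; matched-FPR difference undefined.")
    return(NA_real_)
  }
  y <- as_binary_truth(truth, length(scores))
  ev <- evaluate_oriented(scores, y)
  pt <- binary_point(p, y)
  tpr_cont <- approx(ev$roc$fpr, ev$roc$tpr, xout = pt$fpr,
                     ties = max, rule = 2)$y
  tpr_cont - pt$tpr
}

#' Threshold scores to a fixed number of positives
#'
#' Marks the `n_positive` largest scores as 1 and the rest 0. Boundary ties
#' are broken deterministically by question index (earlier questions win).
#'
#' @param scores Numeric vector.
#' @param n_positive Number of positives, `0 <= n_positive <= length(scores)`.
#' @return A 0/1 vector.
#' @export
threshold_match_positives <- function(scores, n_positive) {
  n <- length(scores)
  if (n_positive < 0 || n_positive > n) abort("`n_positive` out of range.")
  out <- numeric(n)
  if (n_positive > 0) out[order(-scores)[seq_len(n_positive)]] <- 1
  out
}

#' Resolve sign against a binary reference
#'
#' Treats a binary aggregate as pseudo-truth: if the AUROC of `scores`
#' against it is below 0.5 the scores are negated, otherwise (including
#' exactly 0.5) returned unchanged.
#'
#' @param scores Continuous scores.
#' @param reference 0/1 vector with both values present.
#' @return The possibly negated scores.
#' @export
align_to_reference <- function(scores, reference) {
  if (auroc(scores, reference) < 0.5) -scores else scores
}

#' Proportion of disagreements between two binary aggregates
#'
#' @param pred_a,pred_b 0/1 vectors of equal length.
#' @return Fraction of questions on which the two disagree.
#' @export
proportion_of_differences <- function(pred_a, pred_b) {
  stopifnot(length(pred_a) == length(pred_b))
  mean(as.numeric(pred_a) != as.numeric(pred_b))
}

#' Absolute Spearman correlation with the true class probability
#'
#' @param scores Consensus scores.
#' @param class_probs True class probabilities (or any reference vector).
#' @return `|rho|` in `[0, 1]`.
#' @export
spearman_abs <- function(scores, class_probs) {
  abs(cor(scores, class_probs, method = "spearman"))
}

#' Oriented AUROC shortfall relative to the true class probability
#'
#' The true class probability is the best possible ranking of the questions;
#' a consensus at its level scores 0, anything less is negative.
#'
#' @inheritParams spearman_abs
#' @inheritParams roc_curve
#' @return `auroc_oriented(scores) - auroc_oriented(class_probs)`.
#' @export
auroc_difference_vs_classprob <- function(scores, class_probs, truth) {
  y <- as_binary_truth(truth, length(scores))
  evaluate_oriented(scores, y)$auroc_oriented -
    evaluate_oriented(class_probs, y)$auroc_oriented
}
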
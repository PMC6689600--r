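# Independent brute-force oracles, deliberately naive: each recomputes a
# quantity from its definition by explicit enumeration, sharing no code with
# the package implementation.

# AUROC as the probability that a random positive outranks a random negative,
# ties counting half, by enumerating every (positive, negative) pair.
oracle_auroc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Non-interpolated average precision by walking thresholds one unique score
# at a time and recounting TP/FP from scratch at each.
oracle_average_precision <- function(scores, y) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(y == 1)
  ap <- 0
  recall_prev <- 0
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(y[sel] == 1)
    prec <- tp / sum(sel)
    recall <- tp / n1
    ap <- ap + (recall - recall_prev) * prec
    recall_prev <- recall
  }
  ap
}

# Spearman correlation from the Pearson formula applied to averaged ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# TPR of the score ROC at a given FPR by exhaustive thresholding plus linear
# interpolation between the two bracketing operating points.
oracle_tpr_at_fpr <- function(scores, y, fpr_target) {
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thresholds, function(t) {
    pred <- as.numeric(scores >= t)
    c(fpr = sum(pred == 1 & y == 0) / sum(y == 0),
      tpr = sum(pred == 1 & y == 1) / sum(y == 1))
  }, c(fpr = 0, tpr = 0)))
  # keep the best tpr at each fpr, then interpolate
  agg <- tapply(pts[, "tpr"], pts[, "fpr"], max)
  fprs <- as.numeric(names(agg))
  approx(fprs, as.numeric(agg), xout = fpr_target, ties = max, rule = 2)$y
}

# small random fixtures ------------------------------------------------------

random_response_matrix <- function(n, k, seed = 1) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n * k), n, k)
    rownames(v) <- paste0("q", seq_len(n))
    colnames(v) <- paste0("ind", seq_len(k))
    response_matrix(v)
  })
}

random_scores_truth <- function(n, seed, tie_prob = 0.3) {
  withr::with_seed(seed, {
    s <- rnorm(n)
    if (runif(1) < tie_prob) {
      # force ties by coarse rounding
      s <- round(s, 1)
    }
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0) y[1] <- 1
    if (sum(y) == n) y[1] <- 0
    list(scores = s, y = y)
  })
}
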
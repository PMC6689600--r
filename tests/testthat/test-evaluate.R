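test_that("ROC handles perfect, tied and reversed rankings", {
  y <- c(1, 1, 0, 0)
  expect_equal(auroc(c(4, 3, 2, 1), y), 1)
  expect_equal(auroc(c(1, 1, 1, 1), y), 0.5)
  expect_equal(auroc(c(1, 2, 3, 4), y), 0)
  rc <- roc_curve(c(4, 3, 2, 1), y)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(unlist(rc[nrow(rc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUROC equals the brute-force concordant-pair count", {
  for (i in 1:200) {
    st <- random_scores_truth(20, seed = i)
    expect_equal(auroc(st$scores, st$y), oracle_auroc(st$scores, st$y),
                 tolerance = 1e-12)
  }
})

test_that("AUPR equals brute-force average precision and handles flips", {
  y <- c(1, 1, 0, 0)
  expect_equal(aupr(c(4, 3, 2, 1), y), 1)
  expect_equal(evaluate_oriented(c(1, 2, 3, 4), y)$aupr_oriented, 1)
  for (i in 1:100) {
    st <- random_scores_truth(15, seed = 300 + i)
    expect_equal(aupr(st$scores, st$y),
                 oracle_average_precision(st$scores, st$y), tolerance = 1e-12)
  }
})

test_that("oriented evaluation reports the better sign and is involutive", {
  y <- c(1, 1, 0, 0)
  ev <- evaluate_oriented(c(1, 2, 3, 4), y)
  expect_equal(ev$auroc_oriented, 1)
  expect_true(ev$flipped_roc)
  expect_equal(ev$auroc_raw, 0)

  # symmetric scores: no flip
  ev2 <- evaluate_oriented(c(1, 1, 1, 1), y)
  expect_equal(ev2$auroc_oriented, 0.5)
  expect_false(ev2$flipped_roc)

  # evaluating -s equals evaluating s with flags inverted
  st <- random_scores_truth(30, seed = 77)
  a <- evaluate_oriented(st$scores, st$y)
  b <- evaluate_oriented(-st$scores, st$y)
  expect_equal(a$auroc_oriented, b$auroc_oriented)
  expect_equal(a$aupr_oriented, b$aupr_oriented)
  if (a$auroc_raw != 0.5) expect_equal(a$flipped_roc, !b$flipped_roc)
})

test_that("AUROC is invariant under strictly monotone transforms", {
  st <- random_scores_truth(40, seed = 13)
  expect_equal(auroc(st$scores, st$y), auroc(exp(st$scores), st$y))
  expect_equal(auroc(st$scores, st$y), auroc(rank(st$scores), st$y))
  for (i in 1:20) {
    st <- random_scores_truth(25, seed = 500 + i)
    expect_gte(evaluate_oriented(st$scores, st$y)$auroc_oriented, 0.5)
  }
})

test_that("binary operating points are counted directly", {
  y <- c(1, 1, 0, 0)
  expect_equal(unlist(binary_point(y, y)), c(fpr = 0, tpr = 1))
  expect_equal(unlist(binary_point(1 - y, y)), c(fpr = 1, tpr = 0))
  expect_equal(unlist(binary_point(c(1, 0, 0, 0), y)), c(fpr = 0, tpr = 0.5))
})

test_that("matched-FPR TPR difference interpolates the continuous ROC", {
  y <- c(rep(1, 5), rep(0, 5))
  scores <- 10:1  # perfect ranking
  pred <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)  # (fpr 0, tpr 0.6)
  expect_equal(tpr_difference_at_matched_fpr(scores, pred, y), 0.4)

  # thresholding the continuous scores at a cut followed by a negative
  # reproduces its own ROC vertex: difference exactly 0
  y2 <- c(1, 1, 0, 1, 1, 0, 0, 0, 0, 0)
  pred2 <- threshold_match_positives(scores, 2)
  expect_equal(tpr_difference_at_matched_fpr(scores, pred2, y2), 0)

  # brute-force exhaustive-threshold oracle on random instances
  for (i in 1:50) {
    st <- random_scores_truth(20, seed = 900 + i)
    pred <- threshold_match_positives(withr::with_seed(i, rnorm(20)), 8)
    ev <- evaluate_oriented(st$scores, st$y)
    oriented <- if (ev$flipped_roc) -st$scores else st$scores
    pt <- binary_point(pred, st$y)
    expected <- oracle_tpr_at_fpr(oriented, st$y, pt$fpr) - pt$tpr
    expect_equal(tpr_difference_at_matched_fpr(st$scores, pred, st$y),
                 expected, tolerance = 1e-12)
  }

  expect_warning(
    out <- tpr_difference_at_matched_fpr(scores, rep(1, 10), y),
    "single-valued")
  expect_true(is.na(out))
})

test_that("count-matched thresholding uses index order at ties", {
  expect_equal(threshold_match_positives(c(3, 1, 2), 2), c(1, 0, 1))
  expect_equal(threshold_match_positives(c(3, 1, 2), 0), c(0, 0, 0))
  expect_equal(threshold_match_positives(c(3, 1, 2), 3), c(1, 1, 1))
  expect_equal(threshold_match_positives(c(2, 2, 2, 1), 2), c(1, 1, 0, 0))
  expect_error(threshold_match_positives(c(1, 2), 3), "out of range")
})

test_that("reference alignment flips only anti-associated scores", {
  ref <- c(1, 1, 0, 0)
  expect_equal(align_to_reference(c(1, 2, 3, 4), ref), c(-1, -2, -3, -4))
  expect_equal(align_to_reference(c(4, 3, 2, 1), ref), c(4, 3, 2, 1))
  expect_equal(align_to_reference(c(1, 1, 1, 1), ref), c(1, 1, 1, 1))
})

test_that("proportion of differences is a scaled metric on binary vectors", {
  expect_equal(proportion_of_differences(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(proportion_of_differences(c(1, 0), c(0, 1)), 1)
  expect_equal(proportion_of_differences(rep(0, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  for (i in 1:20) {
    v <- withr::with_seed(i, replicate(3, rbinom(12, 1, 0.5), simplify = FALSE))
    dab <- proportion_of_differences(v[[1]], v[[2]])
    dba <- proportion_of_differences(v[[2]], v[[1]])
    dac <- proportion_of_differences(v[[1]], v[[3]])
    dcb <- proportion_of_differences(v[[3]], v[[2]])
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb)
  }
})

test_that("Spearman statistics match the rank-formula oracle", {
  x <- c(0.2, 0.4, 0.4, 0.9, 0.1)
  expect_equal(spearman_abs(x, x), 1)
  expect_equal(spearman_abs(x, -2 * x + 3), 1)
  for (i in 1:30) {
    a <- withr::with_seed(i, round(rnorm(15), 1))
    b <- withr::with_seed(i + 1000, round(rnorm(15), 1))
    expect_equal(spearman_abs(a, b), abs(oracle_spearman(a, b)),
                 tolerance = 1e-12)
  }
})

test_that("AUROC shortfall against the class probability behaves as a bound", {
  sim <- simulate_crowd(n = 200, k = 5, seed = 31)
  y <- sim$truth$label
  cp <- sim$class_probs
  expect_equal(auroc_difference_vs_classprob(cp, cp, y), 0)
  expect_equal(auroc_difference_vs_classprob(cp^3, cp, y), 0)  # monotone map
  # pure noise cannot beat the class probability (median over replicates)
  diffs <- vapply(1:100, function(i) {
    noise <- withr::with_seed(4000 + i, rnorm(200))
    auroc_difference_vs_classprob(noise, cp, y)
  }, numeric(1))
  expect_lt(median(diffs), 0)
})
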
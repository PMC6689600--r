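#' Compare a continuous consensus with a binary aggregate
#'
#' Computes the two comparison statistics used when a continuous embedding
#' (e.g. PCA scores) is pitted against a binary crowd wisdom (e.g. SML
#' predictions) on the same questions:
#'
#' * the TPR difference at the binary method's FPR
#'   ([tpr_difference_at_matched_fpr()]), measuring how much sensitivity the
#'   continuous method retains at the binary method's own operating point;
#' * the proportion of differences after matching: the continuous scores are
#'   sign-aligned to the binary predictions ([align_to_reference()]),
#'   thresholded to the same number of positives
#'   ([threshold_match_positives()]), and the disagreement fraction reported.
#'
#' @param scores Continuous consensus scores.
#' @param predictions 0/1 predictions of the binary aggregate.
#' @param truth Optional [ground_truth()] or 0/1 vector; when supplied the
#'   matched-FPR TPR difference and both operating points are included.
#' @return A one-row tibble.
#' @export
compare_binary <- function(scores, predictions, truth = NULL) {
  p <- as.numeric(predictions)
  degenerate <- length(unique(p)) < 2
  aligned <- align_to_reference(scores, p)
  thresholded <- threshold_match_positives(aligned, sum(p == 1))
  out <- tibble::tibble(
    prop_diff = proportion_of_differences(thresholded, p),
    n_positive = sum(p == 1),
    degenerate = degenerate
  )
  if (!is.null(truth)) {
    y <- as_binary_truth(truth, length(scores))
    pt <- binary_point(p, y)
    out$tpr_diff <- if (degenerate) NA_real_ else
      tpr_difference_at_matched_fpr(scores, p, y)
    out$fpr_binary <- pt$fpr
    out$tpr_binary <- pt$tpr
    out$auroc_continuous <- evaluate_oriented(scores, y)$auroc_oriented
  }
  out
}

#' Agreement between SML and thresholded PCA across simulated crowds
#'
#' For each crowd size in `k_grid`, simulates `n_replicates` datasets,
#' perfectly binarizes the continuous responses at the true positive count,
#' runs SML on the votes and PCA on the normalized votes, and measures the
#' proportion of differing predictions after sign alignment and
#' count-matched thresholding. Replicates where SML is degenerate
#' (single-valued) are excluded from the summary. As the crowd grows the two
#' methods converge: the disagreement shrinks towards zero.
#'
#' @param k_grid Integer vector of crowd sizes.
#' @param n_replicates Replicates per crowd size.
#' @param binarize Use `perfect_binarize()` on the continuous responses
#'   (`TRUE`, default) rather than thresholding at 0/1 directly.
#' @inheritParams simulate_crowd
#' @return A tibble with one row per `k`: mean, sd and median proportion of
#'   differences and the number of replicates used.
#' @export
binary_agreement_study <- function(k_grid, n_replicates, n = 1000,
                                   p_yes = 0.3, beta = 1, alpha_mean = 1,
                                   alpha_sd = 1, seed = 1L) {
  purrr::map_dfr(seq_along(k_grid), function(gi) {
    k <- k_grid[gi]
    recs <- replicate_sims(
      function(sim) sml_vs_pca_record(sim),
      n_replicates = n_replicates, n = n, k = k, p_yes = p_yes, beta = beta,
      alpha_mean = alpha_mean, alpha_sd = alpha_sd,
      seed = seed + 100000L * (gi - 1L), drop_degenerate = TRUE
    )
    tibble::tibble(k = k,
                   mean_prop_diff = mean(recs$prop_diff),
                   sd_prop_diff = sd(recs$prop_diff),
                   median_prop_diff = median(recs$prop_diff),
                   n_used = nrow(recs))
  })
}

# one replicate of the SML vs thresholded-PCA agreement comparison
sml_vs_pca_record <- function(sim) {
  n_pos <- sum(sim$truth$label)
  votes <- perfect_binarize(sim$responses_raw, n_positive = n_pos,
                            seed = sim$params$seed)
  fit <- sml(votes)
  pca <- aggregate_crowd(normalize_responses(votes), method = "pca")
  cmp <- compare_binary(pca$scores, fit$predictions)
  tibble::tibble(prop_diff = cmp$prop_diff,
                 degenerate = fit$degenerate | cmp$degenerate)
}
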
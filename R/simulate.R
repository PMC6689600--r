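#' Simulate a crowd of raters answering binary questions
#'
#' Generates a synthetic dataset under the latent class-probability model:
#' each question i carries an unobserved posterior probability
#' p_i = P(yes | all relevant data), and each individual j independently
#' estimates it with skill alpha_j, responding
#' r_ji ~ Normal(alpha_j * p_i, 1). Concretely:
#'
#' 1. Draw a stream of pairs (p ~ Beta(beta, beta), class ~ Bernoulli(p)) and
#'    retain, in draw order, the first `round(n * p_yes)` yes-class questions
#'    and the first `n - round(n * p_yes)` no-class questions; merge and
#'    shuffle. `beta` controls question difficulty: beta = 1 gives uniform
#'    class probabilities, large beta concentrates them near 1/2 (hard
#'    questions), small beta pushes them towards 0/1 (easy questions).
#' 2. Draw skills alpha_j ~ Normal(alpha_mean, alpha_sd^2); negative alpha_j
#'    yields a worse-than-random individual whose answers anti-correlate with
#'    truth.
#' 3. Fill the n x k response matrix with r_ji ~ Normal(alpha_j * p_i, 1) and
#'    normalize it per individual.
#'
#' All randomness flows through `seed`; the same seed reproduces the dataset
#' bit for bit. Sub-seeds for the class-probability stream, the shuffle, the
#' skills and the responses are derived deterministically from `seed`, so
#' each stage is independently reproducible.
#'
#' @param n Number of questions (>= 2).
#' @param k Number of individuals (>= 2).
#' @param p_yes Target frequency of the yes class in (0, 1); the realized
#'   count is exactly `round(n * p_yes)`.
#' @param beta Beta-distribution shape (> 0) for the class probabilities.
#' @param alpha_mean,alpha_sd Mean and standard deviation (>= 0) of the
#'   individual skill distribution.
#' @param seed Integer seed.
#' @return A `crowd_sim` object: a list with `params`, `truth`
#'   (a [ground_truth()]), `class_probs`, `alphas`, `responses_raw` and
#'   `responses_normalized` (both [response_matrix()]).
#' @examples
#' sim <- simulate_crowd(n = 50, k = 5, seed = 1)
#' sum(sim$truth$label)  # exactly round(50 * 0.3)
#' @export
simulate_crowd <- function(n = 1000, k = 10, p_yes = 0.3, beta = 1,
                           alpha_mean = 1, alpha_sd = 1, seed = 1L) {
  if (n < 2 || k < 2) abort("Need n >= 2 and k >= 2.")
  if (p_yes <= 0 || p_yes >= 1) abort("`p_yes` must be in (0, 1).")
  if (beta <= 0) abort("`beta` must be positive.")
  if (alpha_sd < 0) abort("`alpha_sd` must be non-negative.")
  n_yes <- round(n * p_yes)
  n_no <- n - n_yes
  if (n_yes < 1 || n_no < 1) {
    abort("`n * p_yes` and `n * (1 - p_yes)` must each round to at least 1.")
  }
  sub <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 4L))

  # stage 1: rejection stream of (class probability, class) pairs
  drawn <- withr::with_seed(sub[1], {
    ps_yes <- numeric(0); ps_no <- numeric(0)
    total <- 0L
    while (length(ps_yes) < n_yes || length(ps_no) < n_no) {
      block <- max(2L * n, 1000L)
      p <- rbeta(block, beta, beta)
      cls <- runif(block) < p
      ps_yes <- c(ps_yes, p[cls])[seq_len(min(n_yes, length(ps_yes) + sum(cls)))]
      ps_no <- c(ps_no, p[!cls])[seq_len(min(n_no, length(ps_no) + sum(!cls)))]
      total <- total + block
      if (total > 1e7) abort("Class quota not reached after 10^7 stream draws.")
    }
    list(yes = ps_yes, no = ps_no)
  })
  class_probs <- c(drawn$yes, drawn$no)
  true_classes <- c(rep(1, n_yes), rep(0, n_no))
  ord <- withr::with_seed(sub[2], sample.int(n))
  class_probs <- class_probs[ord]
  true_classes <- true_classes[ord]

  alphas <- withr::with_seed(sub[3], rnorm(k, alpha_mean, alpha_sd))
  values <- withr::with_seed(sub[4], {
    matrix(rnorm(n * k, mean = outer(class_probs, alphas), sd = 1), n, k)
  })
  qid <- sprintf("q%0*d", nchar(n), seq_len(n))
  colnames(values) <- sprintf("ind%0*d", nchar(k), seq_len(k))
  rownames(values) <- qid

  responses_raw <- response_matrix(values, state = "raw_continuous")
  structure(list(
    params = list(n = n, k = k, p_yes = p_yes, beta = beta,
                  alpha_mean = alpha_mean, alpha_sd = alpha_sd, seed = seed),
    truth = ground_truth(tibble::tibble(question = qid, label = true_classes)),
    class_probs = setNames(class_probs, qid),
    alphas = setNames(alphas, colnames(values)),
    responses_raw = responses_raw,
    responses_normalized = normalize_responses(responses_raw)
  ), class = "crowd_sim")
}

#' @exportS3Method base::print
print.crowd_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Simulated crowd: %d questions x %d individuals (p_yes=%g, beta=%g, alpha ~ N(%g, %g^2), seed=%d)\n",
    p$n, p$k, p$p_yes, p$beta, p$alpha_mean, p$alpha_sd, p$seed))
  invisible(x)
}

#' Run an analysis over replicated simulations
#'
#' Applies `analysis` to `n_replicates` independently seeded datasets
#' (replicate i uses `seed + i`) and row-binds the records. An analysis may
#' mark a replicate degenerate (e.g. a single-valued binary consensus) by
#' returning a record with a `degenerate` column; with
#' `drop_degenerate = TRUE` such replicates are removed from the output and
#' their count reported via a message.
#'
#' @param analysis A function mapping a `crowd_sim` to a one-row data frame.
#' @param n_replicates Number of replicates (>= 1).
#' @param drop_degenerate Drop replicates flagged `degenerate`?
#' @inheritParams simulate_crowd
#' @return A tibble with one row per retained replicate, including a
#'   `replicate` index column.
#' @export
replicate_sims <- function(analysis, n_replicates, n = 1000, k = 10,
                           p_yes = 0.3, beta = 1, alpha_mean = 1,
                           alpha_sd = 1, seed = 1L, drop_degenerate = FALSE) {
  stopifnot(n_replicates >= 1)
  records <- purrr::map(seq_len(n_replicates), function(i) {
    sim <- simulate_crowd(n = n, k = k, p_yes = p_yes, beta = beta,
                          alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                          seed = seed + i)
    rec <- tibble::as_tibble(analysis(sim))
    dplyr::bind_cols(tibble::tibble(replicate = i), rec)
  })
  out <- dplyr::bind_rows(records)
  if (drop_degenerate && "degenerate" %in% names(out)) {
    n_bad <- sum(out$degenerate)
    if (n_bad > 0) {
      inform(sprintf("Dropped %d degenerate replicate(s) of %d.", n_bad, n_replicates))
      out <- dplyr::filter(out, !.data$degenerate)
    }
  }
  out
}
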
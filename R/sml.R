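#' Spectral meta-learner for binary votes
#'
#' Aggregates 0/1 votes by weighting each individual with the leading
#' eigenvector of the inter-individual vote covariance. Under the standard
#' conditional-independence model the off-diagonal of that covariance has
#' rank one, with entries proportional to the product of the individuals'
#' balanced accuracies, so the eigenvector recovers each individual's
#' reliability — including a negative weight for individuals who
#' systematically vote against the truth. The diagonal (own-variance) entries
#' do not follow the rank-one structure and are treated as unknown: starting
#' from the average off-diagonal magnitude, they are iteratively re-imputed
#' as `lambda * v^2` from the current leading eigenpair until the maximum
#' diagonal change falls below `tol`.
#'
#' Votes are recoded to ±1; the consensus score of question i is the
#' weighted vote sum `sum_j v_j b_ji`, predicted yes when positive (a score
#' of exactly 0 counts as yes). The eigenvector sign is fixed so that the
#' majority of weights are positive (tie: positive weight sum).
#'
#' @param x A [response_matrix()] in state `raw_binary` or `binarized` with
#'   at least 3 individuals and no constant column.
#' @param tol Convergence tolerance on the imputed diagonal.
#' @param max_iter Iteration cap.
#' @return An `sml_fit` object with `weights`, `scores`, `predictions`
#'   (0/1), `converged`, `n_iterations` and `degenerate` (`TRUE` when all
#'   predictions agree — the single-valued failure mode excluded from
#'   replicate comparisons). [tidy()] gives per-question scores and
#'   predictions; [glance()] a one-row summary.
#' @examples
#' sim <- simulate_crowd(n = 200, k = 6, seed = 3)
#' bin <- perfect_binarize(sim$responses_raw, n_positive = 60, seed = 1)
#' fit <- sml(bin)
#' glance(fit)
#' @export
sml <- function(x, tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(x, "response_matrix"))
  if (!response_state(x) %in% c("raw_binary", "binarized")) {
    abort("sml() expects binary votes (state 'raw_binary' or 'binarized').")
  }
  v <- rm_values(x)
  k <- ncol(v)
  if (k < 3) abort("sml() needs at least 3 individuals.")
  const <- apply(v, 2, function(col) diff(range(col)) == 0)
  if (any(const)) {
    abort(sprintf("Constant vote column(s): %s. Exclude them before calling sml().",
                  paste(individuals(x)[const], collapse = ", ")))
  }
  b <- 2 * v - 1  # ±1 coding
  n <- nrow(b)
  Q <- stats::cov(b)  # sample covariance over questions
  off <- Q[row(Q) != col(Q)]
  dvec <- rep(mean(abs(off)), k)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    Qi <- Q
    diag(Qi) <- dvec
    e <- eigen(Qi, symmetric = TRUE)
    lead <- which.max(e$values)
    lambda <- e$values[lead]
    vec <- e$vectors[, lead]
    dnew <- lambda * vec^2
    if (max(abs(dnew - dvec)) < tol) { dvec <- dnew; converged <- TRUE; break }
    dvec <- dnew
  }
  n_pos <- sum(vec > 0)
  flip <- if (n_pos > k / 2) 1
    else if (n_pos < k / 2) -1
    else if (sum(vec) >= 0) 1 else -1
  vec <- vec * flip
  scores <- drop(b %*% vec)
  predictions <- as.numeric(scores >= 0)
  structure(list(
    weights = setNames(vec, individuals(x)),
    scores = setNames(scores, questions(x)),
    predictions = setNames(predictions, questions(x)),
    converged = converged,
    n_iterations = iter,
    degenerate = length(unique(predictions)) < 2
  ), class = "sml_fit")
}

#' @exportS3Method base::print
print.sml_fit <- function(x, ...) {
  cat(sprintf("SML fit: %d questions, %d individuals; %d predicted yes%s%s\n",
              length(x$scores), length(x$weights), sum(x$predictions),
              if (!x$converged) " [not converged]" else "",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
tidy.sml_fit <- function(x, ...) {
  tibble::tibble(question = names(x$scores), score = unname(x$scores),
                 prediction = unname(x$predictions))
}

#' @export
glance.sml_fit <- function(x, ...) {
  tibble::tibble(n_questions = length(x$scores), n_individuals = length(x$weights),
                 n_yes = sum(x$predictions), converged = x$converged,
                 n_iterations = x$n_iterations, degenerate = x$degenerate)
}

#' Per-question majority vote
#'
#' @param x A binary [response_matrix()].
#' @return A named 0/1 vector; exact ties count as yes.
#' @export
majority_vote <- function(x) {
  stopifnot(inherits(x, "response_matrix"))
  if (!response_state(x) %in% c("raw_binary", "binarized")) {
    abort("majority_vote() expects binary votes.")
  }
  v <- rm_values(x)
  setNames(as.numeric(rowMeans(v) >= 0.5), questions(x))
}
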
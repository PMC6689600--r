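#' Crowd wisdom by one-dimensional embedding
#'
#' Embeds the n questions of a normalized response matrix into a single
#' dimension and uses the coordinate as the consensus score: because every
#' individual independently estimates the same latent class probability, the
#' questions lie (up to noise) on a one-dimensional structure in the
#' k-dimensional response space, and the first embedding coordinate recovers
#' the class-probability ranking. Linear methods (`pca`, `factor_analysis`)
#' also weight individuals by their estimated reliability, so worse-than-random
#' individuals receive negative weight instead of cancelling the signal as
#' they do under `mean`/`median`.
#'
#' Methods:
#' * `pca` — projection onto the leading right-singular direction; `weights`
#'   are the unit-norm loadings.
#' * `factor_analysis` — posterior factor scores of a one-factor model with
#'   per-individual noise variances (EM, deterministic initialization).
#' * `lle`, `hessian_lle`, `ltsa`, `isomap`, `spectral` — nearest-neighbour
#'   manifold embeddings of the question rows (`n_neighbors` required).
#' * `mds_classical` — Torgerson classical scaling of Euclidean distances.
#' * `mean`, `median` — simple row statistics, kept as baselines.
#'
#' The raw embedding sign is fixed deterministically (the entry of largest
#' magnitude is made positive) and then, unless `align = FALSE`, oriented
#' semantically by [align_sign()] so that the consensus agrees with the
#' majority of the crowd.
#'
#' @param x A [response_matrix()] in state `normalized` (see
#'   [normalize_responses()]).
#' @param method Aggregation method, see above.
#' @param n_neighbors Neighbourhood size for the manifold methods
#'   (`1 <= n_neighbors < n`).
#' @param align Apply majority [align_sign()] orientation? Default `TRUE`.
#' @return A `crowd_agg` object with fields `method`, `n_neighbors`,
#'   `scores` (named, higher = more yes), `weights` (per-individual loadings
#'   for `pca`/`mean`, else `NULL`), `orientation` (the sign applied) and
#'   `converged`/`n_iterations` for `factor_analysis`. [tidy()] returns the
#'   per-question scores, [glance()] a one-row summary.
#' @examples
#' sim <- simulate_crowd(n = 100, k = 5, seed = 1)
#' agg <- aggregate_crowd(sim$responses_normalized, method = "pca")
#' head(tidy(agg))
#' @export
aggregate_crowd <- function(x, method = c("pca", "factor_analysis", "lle",
                                          "hessian_lle", "ltsa", "isomap",
                                          "spectral", "mds_classical",
                                          "mean", "median"),
                            n_neighbors = NULL, align = TRUE) {
  stopifnot(inherits(x, "response_matrix"))
  method <- match.arg(method)
  if (response_state(x) != "normalized") {
    abort("aggregate_crowd() expects a normalized matrix; call normalize_responses() first.")
  }
  v <- rm_values(x)
  res <- switch(method,
    pca = agg_pca(v),
    factor_analysis = agg_factor(v),
    mds_classical = list(scores = drop(cmdscale(dist(v), k = 1)), weights = NULL),
    mean = list(scores = rowMeans(v), weights = rep(1 / ncol(v), ncol(v))),
    median = list(scores = apply(v, 1, median), weights = NULL),
    # manifold family
    {
      if (is.null(n_neighbors)) abort(sprintf("Method '%s' requires `n_neighbors`.", method))
      manifold_embed(v, method, n_neighbors)
    }
  )
  # fix the arbitrary embedding sign deterministically; mean/median have a
  # well-defined sign already and are left alone
  s <- if (method %in% c("mean", "median")) 1 else sign_convention(res$scores)
  scores <- s * res$scores
  if (!is.null(res$weights)) res$weights <- s * res$weights
  out <- structure(list(
    method = method,
    n_neighbors = if (method %in% manifold_methods) n_neighbors else NULL,
    scores = setNames(scores, questions(x)),
    weights = if (!is.null(res$weights)) setNames(res$weights, individuals(x)),
    orientation = 1,
    converged = res$converged %||% TRUE,
    n_iterations = res$n_iterations %||% NA_integer_
  ), class = "crowd_agg")
  if (align) out <- align_sign(out, x)
  out
}

manifold_methods <- c("lle", "hessian_lle", "ltsa", "isomap", "spectral")

# deterministic sign convention: entry of largest |value| made positive
sign_convention <- function(scores) {
  if (scores[which.max(abs(scores))] < 0) -1 else 1
}

agg_pca <- function(v) {
  # columns are already centred by normalization; leading right-singular
  # direction of v = leading eigenvector of the k x k covariance
  sv <- svd(v, nu = 1, nv = 1)
  list(scores = drop(v %*% sv$v[, 1]), weights = sv$v[, 1])
}

# one-factor analysis by EM: x_i = lambda z + eps, eps ~ N(0, diag(psi));
# deterministic init (psi = 1, lambda from PC1), scores = posterior E[z | x];
# convergence on the per-question log-likelihood change
agg_factor <- function(v, tol = 1e-6, max_iter = 1000L) {
  n <- nrow(v); k <- ncol(v)
  S <- crossprod(v) / n
  sv <- svd(v, nu = 0, nv = 1)
  lambda <- sv$v[, 1] * (sv$d[1] / sqrt(n))
  psi <- rep(1, k)
  loglik <- function(lambda, psi) {
    li <- lambda / psi
    denom <- 1 + sum(lambda * li)
    logdet <- log(denom) + sum(log(psi))
    trace <- sum(diag(S) / psi) - drop(li %*% S %*% li) / denom
    -0.5 * (k * log(2 * pi) + logdet + trace)
  }
  ll_old <- loglik(lambda, psi)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # 1-factor Woodbury: beta = lambda' (lambda lambda' + Psi)^{-1}
    li <- lambda / psi
    denom <- 1 + sum(lambda * li)
    beta <- li / denom                      # length k
    m <- drop(S %*% beta)                   # E[x z]
    ezz <- 1 - sum(beta * lambda) + sum(beta * m)
    lambda <- m / ezz
    psi <- pmax(diag(S) - lambda * m, 1e-8)
    ll <- loglik(lambda, psi)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (!converged) {
    warn(sprintf("Factor-analysis EM did not converge in %d iterations; returning best iterate.", max_iter))
  }
  li <- lambda / psi
  beta <- li / (1 + sum(lambda * li))
  list(scores = drop(v %*% beta), weights = NULL,
       converged = converged, n_iterations = iter)
}

#' Orient a consensus with the majority of the crowd
#'
#' Resolves the global sign indeterminacy of a one-dimensional embedding by
#' assuming more than half of the individuals answer better than random: if
#' the number of individuals whose (normalized) responses correlate
#' positively with the scores exceeds k/2 the orientation is +1, if fewer
#' than k/2 it is -1, and an exact tie is broken by the sign of the summed
#' correlations (a zero sum keeps +1).
#'
#' @param result A `crowd_agg` from [aggregate_crowd()].
#' @param x The normalized [response_matrix()] the result was computed from.
#' @return The result with `orientation` set and scores (not weights)
#'   multiplied accordingly.
#' @export
align_sign <- function(result, x) {
  stopifnot(inherits(result, "crowd_agg"), inherits(x, "response_matrix"))
  scores <- result$scores * result$orientation  # undo any previous flip
  if (diff(range(scores)) == 0) {
    abort("Scores are constant; majority alignment is undefined.")
  }
  r <- drop(cor(rm_values(x), scores))
  k <- length(r)
  n_pos <- sum(r > 0)
  orientation <- if (n_pos > k / 2) 1
    else if (n_pos < k / 2) -1
    else if (sum(r) >= 0) 1 else -1
  result$orientation <- orientation
  result$scores <- scores * orientation
  result
}

#' @exportS3Method base::print
print.crowd_agg <- function(x, ...) {
  cat(sprintf("Crowd consensus by %s%s: %d questions, orientation %+d%s\n",
              x$method,
              if (!is.null(x$n_neighbors)) sprintf(" (%d neighbours)", x$n_neighbors) else "",
              length(x$scores), x$orientation,
              if (!isTRUE(x$converged)) " [not converged]" else ""))
  invisible(x)
}

#' @export
tidy.crowd_agg <- function(x, ...) {
  tibble::tibble(question = names(x$scores), score = unname(x$scores))
}

#' @export
glance.crowd_agg <- function(x, ...) {
  tibble::tibble(method = x$method,
                 n_neighbors = x$n_neighbors %||% NA_integer_,
                 n_questions = length(x$scores),
                 orientation = x$orientation,
                 converged = x$converged)
}

#' @export
augment.crowd_agg <- function(x, data, ...) {
  dplyr::left_join(tibble::as_tibble(as.data.frame(data)), tidy(x), by = "question")
}
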
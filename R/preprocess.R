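#' Normalize responses per individual
#'
#' Puts every individual's answers on a common scale before aggregation.
#' Continuous responses are first converted to rankings within each individual
#' (ascending, ties averaged — so any strictly increasing transform of an
#' individual's confidences yields the same result), then each column is
#' shifted to mean 0 and scaled to unit *population* variance (divide by n).
#' Binary 0/1 votes skip the rank conversion and are z-scored directly.
#'
#' @param x A [response_matrix()] in state `raw_continuous`, `raw_binary` or
#'   `binarized` (binary states take the z-score path).
#' @return A [response_matrix()] in state `normalized`.
#' @examples
#' m <- response_matrix(tibble::tibble(
#'   question = paste0("q", 1:4),
#'   a = c(0.1, 0.5, 0.9, 0.9), b = c(2, 1, 4, 3)
#' ))
#' normalize_responses(m)
#' @export
normalize_responses <- function(x) {
  stopifnot(inherits(x, "response_matrix"))
  state <- response_state(x)
  if (state == "normalized") {
    abort("Matrix is already normalized.")
  }
  v <- rm_values(x)
  const <- apply(v, 2, function(col) diff(range(col)) == 0)
  if (any(const)) {
    abort(sprintf("Constant responses for individual(s) %s: cannot scale to unit variance.",
                  paste(individuals(x)[const], collapse = ", ")))
  }
  if (state == "raw_continuous") {
    v <- apply(v, 2, rank, ties.method = "average")
  }
  n <- nrow(v)
  mu <- colMeans(v)
  v <- sweep(v, 2, mu)
  sdev <- sqrt(colMeans(v^2))  # population sd
  v <- sweep(v, 2, sdev, "/")
  rm_rebuild(v, x, "normalized")
}

#' Perfect binarization of confidence scores
#'
#' Converts continuous confidences to yes/no votes under the idealized
#' assumption that every individual knows the true number of positives: each
#' individual marks exactly their `n_positive` most confident questions as
#' yes. Ties at the yes/no boundary are resolved by a seeded uniform draw
#' among the tied questions, so the column sums are always exactly
#' `n_positive`.
#'
#' @param x A [response_matrix()] in state `raw_continuous`.
#' @param n_positive Number of yes votes per individual, `0 < n_positive < n`.
#' @param seed Integer seed for the boundary-tie draw.
#' @return A [response_matrix()] in state `binarized`.
#' @export
perfect_binarize <- function(x, n_positive, seed = 1L) {
  stopifnot(inherits(x, "response_matrix"))
  if (response_state(x) != "raw_continuous") {
    abort("perfect_binarize() expects state 'raw_continuous'.")
  }
  v <- rm_values(x)
  n <- nrow(v)
  if (n_positive <= 0 || n_positive >= n) {
    abort(sprintf("`n_positive` must satisfy 0 < n_positive < %d; got %s.",
                  n, format(n_positive)))
  }
  out <- withr::with_seed(seed, apply(v, 2, function(col) {
    thr <- sort(col, decreasing = TRUE)[n_positive]
    b <- as.numeric(col > thr)
    need <- n_positive - sum(b)
    tied <- which(col == thr)
    if (need > 0) {
      pick <- if (length(tied) == 1) tied else sample(tied, need)
      b[pick[seq_len(need)]] <- 1
    }
    b
  }))
  rm_rebuild(out, x, "binarized")
}
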
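#' Response matrices: questions by individuals
#'
#' A `response_matrix` is the central container of the package: a tibble whose
#' first column, `question`, holds unique question identifiers and whose
#' remaining columns hold one numeric response per individual. Rows are
#' questions, columns are individuals, everywhere in the package — the same
#' orientation as a gene-by-individual expression matrix. The object carries a
#' `state` attribute recording where it sits in the pipeline:
#'
#' * `raw_continuous` — confidence scores as supplied;
#' * `raw_binary` — 0/1 votes as supplied;
#' * `normalized` — per-individual rank-transformed (continuous input only)
#'   and z-scored columns (mean 0, population variance 1);
#' * `binarized` — 0/1 votes produced by [perfect_binarize()].
#'
#' Missing values are rejected outright: the aggregation model assumes every
#' individual answered every question.
#'
#' @param x A data frame whose first column holds question ids (coerced to
#'   character) and whose remaining columns are numeric responses, or a
#'   numeric matrix with rownames as question ids and colnames as individual
#'   ids.
#' @param state Optional state override, one of `"raw_continuous"`,
#'   `"raw_binary"`, `"normalized"`, `"binarized"`. When `NULL`, a matrix
#'   whose values are all 0/1 (with both present) is tagged `raw_binary`,
#'   anything else `raw_continuous`.
#'
#' @return A `response_matrix` tibble with attribute `state`.
#' @examples
#' votes <- tibble::tibble(
#'   question = c("q1", "q2", "q3"),
#'   alice = c(1, 0, 1), bob = c(1, 1, 0)
#' )
#' rm <- response_matrix(votes)
#' response_state(rm)
#' @export
response_matrix <- function(x, state = NULL) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("q", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("ind", seq_len(ncol(x)))
    x <- tibble::as_tibble(as.data.frame(x), rownames = "question")
  }
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort("`x` must be a data frame with a question-id column plus at least one individual column.")
  }
  x <- tibble::as_tibble(x)
  names(x)[1] <- "question"
  x$question <- as.character(x$question)
  out <- new_response_matrix(x, state = state %||% "raw_continuous")
  if (is.null(state)) {
    v <- rm_values(out)
    if (all(v %in% c(0, 1)) && any(v == 0) && any(v == 1)) {
      attr(out, "state") <- "raw_binary"
    }
  }
  validate_response_matrix(out)
}

new_response_matrix <- function(x, state) {
  structure(x, state = state,
            class = c("response_matrix", "tbl_df", "tbl", "data.frame"))
}

response_states <- c("raw_continuous", "raw_binary", "normalized", "binarized")

validate_response_matrix <- function(x) {
  state <- attr(x, "state")
  if (!state %in% response_states) {
    abort(paste0("Unknown response-matrix state: ", state))
  }
  qs <- x$question
  if (anyDuplicated(qs)) {
    abort(paste0("Duplicate question ids: ",
                 paste(unique(qs[duplicated(qs)]), collapse = ", ")))
  }
  inds <- individuals(x)
  if (anyDuplicated(inds)) {
    abort(paste0("Duplicate individual ids: ",
                 paste(unique(inds[duplicated(inds)]), collapse = ", ")))
  }
  v <- rm_values(x)
  if (nrow(v) < 2 || ncol(v) < 2) {
    abort("A response matrix needs at least 2 questions and 2 individuals.")
  }
  if (!is.numeric(v)) abort("Responses must be numeric.")
  if (anyNA(v) || any(!is.finite(v))) {
    bad <- which(is.na(v) | !is.finite(v), arr.ind = TRUE)[1, ]
    abort(sprintf("missing value at (%s, %s)", qs[bad[1]], inds[bad[2]]))
  }
  if (state %in% c("raw_binary", "binarized") && !all(v %in% c(0, 1))) {
    abort(sprintf("State '%s' requires all values in {0, 1}.", state))
  }
  if (state == "normalized") {
    mu <- colMeans(v)
    s2 <- colMeans(sweep(v, 2, mu)^2)
    if (any(abs(mu) >= 1e-9) || any(abs(s2 - 1) >= 1e-9)) {
      abort("State 'normalized' requires every column to have mean 0 and population variance 1.")
    }
  }
  x
}

#' @rdname response_matrix
#' @export
response_state <- function(x) attr(x, "state")

#' @rdname response_matrix
#' @export
questions <- function(x) x$question

#' @rdname response_matrix
#' @export
individuals <- function(x) setdiff(names(x), "question")

# numeric body as an n x k base matrix (questions x individuals)
rm_values <- function(x) {
  m <- as.matrix(as.data.frame(x)[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$question
  m
}

# rebuild a response_matrix from a values matrix, reusing ids
rm_rebuild <- function(values, template, state) {
  df <- tibble::as_tibble(as.data.frame(values))
  names(df) <- individuals(template)
  df <- dplyr::bind_cols(tibble::tibble(question = questions(template)), df)
  validate_response_matrix(new_response_matrix(df, state = state))
}

#' @exportS3Method base::print
print.response_matrix <- function(x, ...) {
  cat(sprintf("# A response matrix: %d questions x %d individuals [state: %s]\n",
              nrow(x), length(individuals(x)), response_state(x)))
  NextMethod()
  invisible(x)
}

#' Ground-truth labels for a set of questions
#'
#' Binary labels (1 = yes/positive) used only by evaluation and by the
#' supervised baselines of the cross-validation harness; the unsupervised
#' aggregators never see them.
#'
#' @param x A data frame whose first two columns are question id and label in
#'   \{0, 1\}, or a named 0/1 vector.
#' @return A `ground_truth` tibble with columns `question` and `label`.
#' @examples
#' ground_truth(tibble::tibble(question = c("q1", "q2"), label = c(1, 0)))
#' @export
ground_truth <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- tibble::tibble(question = names(x), label = unname(x))
  }
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort("`x` must be a data frame with question-id and label columns.")
  }
  x <- tibble::as_tibble(x[, 1:2])
  names(x) <- c("question", "label")
  x$question <- as.character(x$question)
  lab <- x$label
  if (is.character(lab)) lab <- suppressWarnings(as.numeric(lab))
  if (anyNA(lab) || !all(lab %in% c(0, 1))) {
    bad <- x$label[is.na(lab) | !lab %in% c(0, 1)][1]
    abort(sprintf("Labels must be 0 or 1; found '%s'.", as.character(bad)))
  }
  x$label <- as.numeric(lab)
  if (anyDuplicated(x$question)) {
    abort("Duplicate question ids in ground truth.")
  }
  structure(x, class = c("ground_truth", "tbl_df", "tbl", "data.frame"))
}

#' Align a response matrix and ground truth on question order
#'
#' Reorders the truth labels to the matrix's question order. The two must
#' cover exactly the same question-id set.
#'
#' @param matrix A [response_matrix()].
#' @param truth A [ground_truth()].
#' @return A list with elements `matrix` (unchanged) and `truth` (reordered).
#' @export
align_truth <- function(matrix, truth) {
  qm <- questions(matrix)
  qt <- truth$question
  if (!setequal(qm, qt) || length(qm) != length(qt)) {
    missing_t <- setdiff(qm, qt)
    missing_m <- setdiff(qt, qm)
    abort(paste0(
      "Question-id sets differ.",
      if (length(missing_t)) paste0(" Absent from truth: ", paste(missing_t, collapse = ", "), "."),
      if (length(missing_m)) paste0(" Absent from matrix: ", paste(missing_m, collapse = ", "), ".")
    ))
  }
  truth <- truth[match(qm, qt), ]
  list(matrix = matrix, truth = truth)
}

# internal: truth labels aligned to a matrix, as a plain 0/1 vector
truth_vector <- function(matrix, truth) {
  if (inherits(truth, "ground_truth") || is.data.frame(truth)) {
    align_truth(matrix, ground_truth(truth))$truth$label
  } else {
    as.numeric(truth)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
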
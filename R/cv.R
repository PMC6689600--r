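#' Stratified train/test split of questions
#'
#' Draws a training set of `round(fraction * n)` questions whose class
#' proportions match the full set to within one question, with the rest as
#' test set. The split must leave more training questions than individuals
#' when used by [run_cv()], so supervised models are never under-determined.
#'
#' @param truth A [ground_truth()] or 0/1 vector.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(truth, fraction, seed = 1L) {
  y <- if (is.data.frame(truth)) ground_truth(truth)$label else as.numeric(truth)
  n <- length(y)
  n_train <- round(fraction * n)
  if (n_train < 1 || n_train >= n) abort("`fraction` yields an empty train or test set.")
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  n1_train <- round(fraction * length(idx1))
  n0_train <- n_train - n1_train
  if (n1_train < 1 || n0_train < 1) {
    abort("A class would have no training members at this fraction.")
  }
  if (n0_train > length(idx0)) abort("Not enough negative questions for this fraction.")
  train <- withr::with_seed(seed, c(sample(idx1, n1_train), sample(idx0, n0_train)))
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Default supervised baseline roster
#'
#' Supervised classifiers sit behind a minimal contract: a list with a
#' `name`, `fit(X, y)` returning any model object, and `score(model, X)`
#' returning one real score per row. All are ordinary fits delegated to
#' established packages; they are baselines, not contributions. The roster
#' covers linear regression, lasso and elastic-net (`glmnet`, internally
#' cross-validated lambda), logistic regression, linear discriminant
#' analysis, random forest, and k-nearest-neighbours over a neighbour grid.
#'
#' @param knn_neighbors Neighbour grid for the kNN members; entries that
#'   reach the training-set size are dropped at fit time.
#' @return A named list of classifier contracts for [run_cv()].
#' @export
default_classifiers <- function(knn_neighbors = c(5, 7, 10, 15, 25, 40, 60, 90)) {
  cls <- list(
    linear = list(
      fit = function(X, y) stats::lm.fit(cbind(1, X), y),
      score = function(m, X) drop(cbind(1, X) %*% m$coefficients)
    ),
    lasso = list(
      fit = function(X, y) glmnet::cv.glmnet(X, y, alpha = 1, nfolds = 5),
      score = function(m, X) drop(predict(m, X, s = "lambda.min"))
    ),
    elastic_net = list(
      fit = function(X, y) glmnet::cv.glmnet(X, y, alpha = 0.5, nfolds = 5),
      score = function(m, X) drop(predict(m, X, s = "lambda.min"))
    ),
    logistic = list(
      fit = function(X, y) {
        df <- data.frame(y = y, X)
        suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      },
      score = function(m, X) {
        suppressWarnings(predict(m, newdata = data.frame(X), type = "link"))
      }
    ),
    lda = list(
      fit = function(X, y) MASS::lda(X, grouping = factor(y, levels = c(0, 1))),
      score = function(m, X) predict(m, X)$posterior[, "1"]
    ),
    random_forest = list(
      fit = function(X, y) randomForest::randomForest(X, factor(y, levels = c(0, 1))),
      score = function(m, X) predict(m, X, type = "prob")[, "1"]
    )
  )
  for (nn in knn_neighbors) {
    cls[[paste0("knn_", nn)]] <- local({
      nn_local <- nn
      list(
        fit = function(X, y) {
          if (nn_local >= nrow(X)) {
            abort(sprintf("kNN with %d neighbours needs a larger training set.", nn_local))
          }
          list(X = X, y = factor(y, levels = c(0, 1)))
        },
        score = function(m, X) {
          pred <- class::knn(m$X, X, m$y, k = nn_local, prob = TRUE)
          p <- attr(pred, "prob")
          ifelse(pred == "1", p, 1 - p)
        }
      )
    })
  }
  for (nm in names(cls)) cls[[nm]]$name <- nm
  cls
}

#' Cross-validation benchmark of crowd wisdom against supervised learning
#'
#' For every repeat and training fraction, questions are split by
#' [stratified_split()]; supervised classifiers are fit on the training rows
#' of the normalized matrix against the training labels and scored on the
#' test rows. Unsupervised aggregators never see any label: they are run
#' once on the full matrix and their test-row scores extracted — the setting
#' where crowd wisdom can exploit the whole dataset while supervised models
#' are confined to their training subset. All methods are evaluated with the
#' orientation-maximized AUROC/AUPR of [evaluate_oriented()] on the test
#' questions only.
#'
#' Repeats whose test set ends up single-class are redrawn with the next
#' derived seed (and a message), so the record count is always
#' `repeats x (methods + classifiers)` per fraction.
#'
#' @param x A [response_matrix()] (raw states are normalized internally).
#' @param truth A [ground_truth()] covering the same questions.
#' @param fractions Training fractions, subset of (0, 1).
#' @param n_repeats Random splits per fraction.
#' @param methods List of unsupervised aggregation specs, each a list with
#'   `method` and optionally `n_neighbors` (see [aggregate_crowd()]).
#' @param classifiers Supervised roster, see [default_classifiers()].
#' @param seed Integer seed; every split and stochastic classifier receives
#'   a seed derived from it.
#' @return A `crowd_cv` tibble of records: `repeat_id`, `fraction`, `method`,
#'   `supervised`, `auroc`, `aupr`. Summarize with [summarize_cv()].
#' @export
run_cv <- function(x, truth, fractions = 0.25, n_repeats = 50,
                   methods = list(list(method = "pca")),
                   classifiers = default_classifiers(),
                   seed = 1L) {
  stopifnot(inherits(x, "response_matrix"))
  truth <- align_truth(x, ground_truth(truth))$truth
  y <- truth$label
  norm <- if (response_state(x) == "normalized") x else normalize_responses(x)
  v <- rm_values(norm)
  n <- nrow(v); k <- ncol(v)

  method_name <- function(m) {
    if (!is.null(m$n_neighbors)) paste0(m$method, "_", m$n_neighbors) else m$method
  }
  # unsupervised consensus: full data, labels unseen, computed once
  unsup_scores <- purrr::map(methods, function(m) {
    aggregate_crowd(norm, method = m$method, n_neighbors = m$n_neighbors)$scores
  })
  names(unsup_scores) <- purrr::map_chr(methods, method_name)

  records <- list()
  for (frac in fractions) {
    if (round(frac * n) <= k) {
      abort(sprintf("Training fraction %g gives %d questions but there are %d individuals; the training set must be larger than the crowd.",
                    frac, round(frac * n), k))
    }
    for (rep_i in seq_len(n_repeats)) {
      split_seed <- seed + 1000L * rep_i
      repeat {
        sp <- stratified_split(y, frac, seed = split_seed)
        if (length(unique(y[sp$test])) == 2) break
        inform(sprintf("Repeat %d: single-class test set, redrawing.", rep_i))
        split_seed <- split_seed + 1L
      }
      Xtr <- v[sp$train, , drop = FALSE]; ytr <- y[sp$train]
      Xte <- v[sp$test, , drop = FALSE]; yte <- y[sp$test]
      for (nm in names(unsup_scores)) {
        ev <- evaluate_oriented(unsup_scores[[nm]][sp$test], yte)
        records[[length(records) + 1L]] <- tibble::tibble(
          repeat_id = rep_i, fraction = frac, method = nm, supervised = FALSE,
          auroc = ev$auroc_oriented, aupr = ev$aupr_oriented)
      }
      for (cl in classifiers) {
        s <- withr::with_seed(seed + 7000L * rep_i + match(cl$name, names(classifiers)), {
          model <- cl$fit(Xtr, ytr)
          as.numeric(cl$score(model, Xte))
        })
        ev <- evaluate_oriented(s, yte)
        records[[length(records) + 1L]] <- tibble::tibble(
          repeat_id = rep_i, fraction = frac, method = cl$name, supervised = TRUE,
          auroc = ev$auroc_oriented, aupr = ev$aupr_oriented)
      }
    }
  }
  out <- dplyr::bind_rows(records)
  class(out) <- c("crowd_cv", class(out))
  out
}

#' Summarize cross-validation records per method
#'
#' @param records A `crowd_cv` tibble from [run_cv()].
#' @return One row per method and fraction: median AUROC/AUPR and the
#'   method's rank (1 = best) by median AUROC within the fraction.
#' @export
summarize_cv <- function(records) {
  records |>
    dplyr::group_by(.data$fraction, .data$method, .data$supervised) |>
    dplyr::summarise(median_auroc = median(.data$auroc),
                     median_aupr = median(.data$aupr),
                     n_repeats = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$fraction) |>
    dplyr::mutate(rank_auroc = rank(-.data$median_auroc, ties.method = "min")) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$fraction, .data$rank_auroc)
}
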
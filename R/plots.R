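#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures: the oriented ROC or
#' PR curve of a `crowd_eval`, the consensus-score distribution (coloured by
#' truth when supplied) of a `crowd_agg`, and per-method AUROC/AUPR
#' distributions of a `crowd_cv` benchmark.
#'
#' @param object The object to plot.
#' @param curve `"roc"` or `"pr"` for `crowd_eval`.
#' @param truth Optional [ground_truth()] / 0/1 vector for `crowd_agg`.
#' @param metric `"auroc"` or `"aupr"` for `crowd_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-crowdwisdom
NULL

#' @rdname autoplot-crowdwisdom
#' @export
autoplot.crowd_eval <- function(object, curve = c("roc", "pr"), ...) {
  curve <- match.arg(curve)
  if (curve == "roc") {
    ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("ROC (oriented AUROC = %.3f)", object$auroc_oriented)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = sprintf("Precision-recall (AUPR = %.3f)", object$aupr_oriented)) +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot-crowdwisdom
#' @export
autoplot.crowd_agg <- function(object, truth = NULL, ...) {
  df <- tidy(object)
  if (!is.null(truth)) {
    y <- if (is.data.frame(truth)) ground_truth(truth)$label else as.numeric(truth)
    df$class <- factor(y, levels = c(0, 1), labels = c("no", "yes"))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$class)) +
      ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
      ggplot2::geom_histogram(bins = 40)
  }
  p + ggplot2::labs(x = sprintf("%s consensus score", object$method), y = "Questions") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-crowdwisdom
#' @export
autoplot.crowd_cv <- function(object, metric = c("auroc", "aupr"), ...) {
  metric <- match.arg(metric)
  df <- dplyr::mutate(object,
                      kind = ifelse(.data$supervised, "supervised", "crowd wisdom"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$method, .data[[metric]], median),
                                   y = .data[[metric]], fill = .data$kind)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~fraction, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = toupper(metric), fill = NULL) +
    ggplot2::theme_minimal()
}
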
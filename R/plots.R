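#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-family repeated-holdout AUC distributions
#'
#' Boxplots of the per-round validation AUC for each classifier family,
#' ordered by mean AUC; the held-out test AUC of the chosen family is drawn
#' as a dashed reference line when available.
#'
#' @param object A `benchmark_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot benchmark_report
#' @export
autoplot.benchmark_report <- function(object, ...) {
  d <- tidy(object)
  d$family <- factor(d$family, levels = object$ranking)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$family, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "validation AUC",
                  title = "Repeated-holdout benchmark",
                  subtitle = paste("chosen:", object$chosen)) +
    ggplot2::theme_minimal()
  if (!is.na(object$test_auc)) {
    p <- p + ggplot2::geom_hline(yintercept = object$test_auc,
                                 linetype = "dashed")
  }
  p
}

#' Plot composite functional scores with the median cutoff
#'
#' Ranked bar chart of per-strain composite scores coloured by class label,
#' with the median cutoff as a dashed line.
#'
#' @param scores Labelled score tibble from [score_phenotypes()] /
#'   [assign_labels()].
#' @return A ggplot object.
#' @export
plot_composite_scores <- function(scores) {
  stopifnot(all(c("strain_id", "composite", "label") %in% names(scores)))
  d <- dplyr::arrange(scores, .data$composite)
  d$strain_id <- factor(d$strain_id, levels = d$strain_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$strain_id, y = .data$composite,
                                  fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(scores, "cutoff"),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "composite functional score", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Plot the averaged fused-score profile of the fusion-stage survivors
#'
#' @param object A `selected_features` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selected_features
#' @export
autoplot.selected_features <- function(object, ...) {
  d <- object$scores
  ggplot2::ggplot(d, ggplot2::aes(x = rank(-.data$s_bar, ties.method = "first"),
                                  y = .data$s_bar,
                                  colour = .data$selected)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "feature rank", y = "averaged fused score",
                  colour = "selected") +
    ggplot2::theme_minimal()
}
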
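# ggplot2 visualisations of the pipeline's result objects.

#' Plot ANOVA F scores per feature
#'
#' Bar chart of the one-way F statistic of every feature, with the
#' `drop_count` lowest-scoring features highlighted.
#'
#' @param object an [anova_f_scores()] report.
#' @param drop_count how many lowest-F features to highlight (default 3).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.anova_report <- function(object, drop_count = 3L, ...) {
  d <- as_tibble(object)
  ord <- order(d$f_score, seq_len(nrow(d)))
  d$excluded <- seq_len(nrow(d)) %in% ord[seq_len(drop_count)]
  ggplot(d, aes(x = stats::reorder(.data$feature, -.data$f_score),
                y = .data$f_score, fill = .data$excluded)) +
    geom_col() +
    scale_fill_manual(values = c(`FALSE` = "grey35", `TRUE` = "firebrick"),
                      name = "excluded") +
    labs(x = NULL, y = "ANOVA F score") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot the cross-validation comparison
#'
#' Mean fold accuracy with +-1 sd bars for every candidate algorithm.
#'
#' @param object a [crossvalidate_algorithms()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.glioma_cv <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = stats::reorder(.data$algorithm, .data$mean_accuracy),
                y = .data$mean_accuracy, colour = .data$winner)) +
    geom_pointrange(aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                        ymax = .data$mean_accuracy + .data$sd_accuracy)) +
    scale_colour_manual(values = c(`FALSE` = "grey35", `TRUE` = "firebrick"),
                        guide = "none") +
    coord_flip() +
    labs(x = NULL, y = sprintf("mean %d-fold CV accuracy (+- sd)",
                               object$K)) +
    theme_minimal()
}

# Empirical one-vs-rest ROC points for one class score column.
roc_points <- function(truth_pos, score) {
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(truth_pos[ord])
  fp <- cumsum(!truth_pos[ord])
  tibble(fpr = c(0, fp / sum(!truth_pos)), tpr = c(0, tp / sum(truth_pos)))
}

#' Plot a model evaluation report
#'
#' `type = "confusion"` renders the confusion-matrix heatmap (rows = true
#' class, columns = predicted); `type = "roc"` renders the one-vs-rest ROC
#' curve of every class from the stored test-set probabilities, with the
#' AUC in the legend.
#'
#' @param object an [evaluate_model()] result.
#' @param type `"confusion"` or `"roc"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.model_report <- function(object, type = c("confusion", "roc"),
                                  ...) {
  type <- match.arg(type)
  if (type == "confusion") {
    d <- as.data.frame(as.table(object$confusion)) |> as_tibble()
    names(d) <- c("truth", "predicted", "count")
    return(
      ggplot(d, aes(x = .data$predicted, y = .data$truth,
                    fill = .data$count)) +
        geom_tile() +
        geom_text(aes(label = .data$count), colour = "white") +
        scale_y_discrete(limits = rev) +
        scale_fill_gradient(low = "grey70", high = "firebrick",
                            guide = "none") +
        labs(x = "predicted class", y = "true class") +
        theme_minimal())
  }
  probs <- object$probabilities
  classes <- setdiff(names(probs), "truth")
  d <- purrr::map(classes, function(cl) {
    auc <- object$ovr_auc$auc[object$ovr_auc$class == cl]
    roc_points(probs$truth == cl, probs[[cl]]) |>
      mutate(class = sprintf("%s vs rest (AUC %.4f)", cl, auc))
  }) |> purrr::list_rbind()
  ggplot(d, aes(x = .data$fpr, y = .data$tpr, colour = .data$class)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_step() +
    labs(x = "false positive rate", y = "true positive rate",
         colour = NULL) +
    theme_minimal() +
    theme(legend.position = "bottom")
}

#' Plot an ADC slice with its ROI outline
#'
#' @param adc an `adc_map` or matrix (mm^2/s).
#' @param roi optional logical mask overlaid as a contour.
#' @return a ggplot.
#' @export
plot_adc_slice <- function(adc, roi = NULL) {
  adc <- as_adc_map(adc)
  d <- expand.grid(row = seq_len(nrow(adc$values)),
                   col = seq_len(ncol(adc$values)))
  d$adc <- as.vector(adc$values)
  p <- ggplot(d, aes(x = .data$col, y = .data$row, fill = .data$adc)) +
    geom_raster() +
    scale_y_reverse() +
    scale_fill_viridis_c(name = "ADC (mm²/s)") +
    coord_equal() +
    theme_void()
  if (!is.null(roi)) {
    d$roi <- as.vector(roi * 1.0)
    p <- p + geom_contour(data = d,
                          mapping = aes(x = .data$col, y = .data$row,
                                        z = .data$roi),
                          breaks = 0.5, colour = "red", linewidth = 0.4,
                          inherit.aes = FALSE)
  }
  p
}
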
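#' Confusion heatmap for cohort metrics
#'
#' Depth-1 (major category) confusion counts over called samples.
#'
#' @param object A `too_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.too_metrics <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(.data$truth_major, .data$pred_major,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white",
                       size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Truth major category", y = "Predicted major category",
                  fill = "Samples") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot one sample's propagated score tree
#'
#' Bars per hierarchy label (major categories and subcategories faceted by
#' depth), with the call threshold marked: every label at or above the line
#' on the greedy path is part of the reported call.
#'
#' @param pred A `too_predictions` object.
#' @param sample_id Which sample to show (default: the first).
#' @param threshold Threshold line (default: the prediction threshold).
#' @return A ggplot object.
#' @export
plot_score_tree <- function(pred, sample_id = NULL,
                            threshold = pred$threshold) {
  stopifnot(inherits(pred, "too_predictions"))
  sample_id <- sample_id %||% rownames(pred$trees)[1]
  h <- pred$hierarchy
  df <- tibble::tibble(code = colnames(pred$trees),
                       score = pred$trees[sample_id, ]) |>
    dplyr::left_join(h$nodes, by = "code") |>
    dplyr::filter(.data$depth > 0)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$code, -.data$score),
                                   .data$score)) +
    ggplot2::geom_col(fill = "#377eb8") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~depth, scales = "free_x",
                        labeller = ggplot2::labeller(
                          depth = function(d) paste("depth", d))) +
    ggplot2::labs(x = NULL, y = "Propagated score", title = sample_id) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1,
                                                       size = 6))
}
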
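#' Plot recall versus retrieval depth for both methods
#'
#' Visual comparison of direct and indirect recall for one group across a
#' range of `k`, in the style of per-group recall curves.
#'
#' @param curve Output of [recall_curve()] (columns `k`, `method`,
#'   `recall`).
#' @return A ggplot object.
#' @export
plot_recall_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$recall,
                                      colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "retrieval depth k", y = "recall (same-class instances)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a similarity matrix
#'
#' @param object A `ks_matrix` or `i2r_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sim_matrix
#' @export
autoplot.sim_matrix <- function(object, ...) {
  long <- tidy.sim_matrix(object)
  long$query_id <- factor(long$query_id, levels = rownames(object))
  long$target_id <- factor(long$target_id, levels = colnames(object))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$target_id, y = .data$query_id,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = "target", y = "query",
                  fill = paste0(attr(object, "method"), "\nscore")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' ROC comparison of direct and indirect retrieval
#'
#' Builds the pooled pair-rank ROC curves of two similarity matrices over
#' the same labelled instances and overlays them.
#'
#' @param direct,indirect Similarity matrices.
#' @param labels Class labels (named vector or metadata tibble).
#' @return A ggplot object; the computed AUCs are in the subtitle.
#' @export
plot_roc_comparison <- function(direct, indirect, labels) {
  roc_points <- function(sim, method) {
    pairs <- pair_rank_scores(sim, labels)
    r <- pROC::roc(response = pairs$same_class, predictor = pairs$score,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    tibble::tibble(method = method,
                   fpr = rev(1 - r$specificities),
                   tpr = rev(r$sensitivities),
                   auc = as.numeric(pROC::auc(r)))
  }
  dat <- dplyr::bind_rows(roc_points(direct, "direct"),
                          roc_points(indirect, "indirect"))
  aucs <- dplyr::distinct(dat, .data$method, .data$auc)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate", colour = NULL,
      subtitle = paste(sprintf("AUC %s = %.3f", aucs$method, aucs$auc),
                       collapse = ", ")
    ) +
    ggplot2::theme_minimal()
}
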
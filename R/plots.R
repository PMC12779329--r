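# ggplot2 visualizations of the result objects.

#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("ROC curve (AUC = %.2f)",
                                  attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Plot per-group Mahalanobis abnormality distributions
#'
#' Box-plus-jitter view of the Mahalanobis score by response group.
#'
#' @param report An `hm_report`.
#' @param demographics Demographics tibble with group labels.
#' @return A ggplot object.
#' @export
plot_abnormality <- function(report, demographics) {
  stopifnot(inherits(report, "hm_report"))
  d <- dplyr::inner_join(report$abnormality,
                         demographics[c("subject_id", "group")],
                         by = "subject_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mahalanobis,
                                  colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1.2) +
    ggplot2::labs(x = NULL, y = "Mahalanobis distance",
                  title = "Multivariate hippocampal abnormality by group") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Plot effect sizes for every measure and comparison
#'
#' Rank-biserial effect sizes (bars) per measure, mirroring the contrast
#' between the multivariate score and the univariate volume measures.
#'
#' @param report An `hm_report`.
#' @return A ggplot object.
#' @export
plot_effect_sizes <- function(report) {
  stopifnot(inherits(report, "hm_report"))
  d <- report$comparisons |>
    dplyr::filter(.data$group_a == "non_responder",
                  .data$group_b == "responder") |>
    dplyr::mutate(abs_r = abs(.data$r_rank_biserial),
                  measure = stats::reorder(.data$measure, .data$abs_r))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$measure, y = .data$abs_r,
                                  fill = .data$measure == "mahalanobis")) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::scale_fill_manual(values = c("grey65", "#2166AC"),
                               guide = "none") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "|rank-biserial r| (non-responder vs responder)",
                  title = "Multivariate vs univariate group separation") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hm_report <- function(object, demographics = NULL, ...) {
  if (is.null(demographics)) return(plot_effect_sizes(object))
  plot_abnormality(object, demographics)
}
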
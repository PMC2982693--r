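#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot ROC or precision-recall curve for a cross-validation result
#'
#' Draws the curve from the pooled test-pair scores of a [run_cv()] result.
#'
#' @param object a `dti_cv`.
#' @param type `"roc"` or `"pr"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dti_cv <- function(object, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  curve <- ranking_curve(object$scores, object$labels)
  if (type == "roc") {
    p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0,
                           linetype = "dashed", colour = "grey60") +
      ggplot2::geom_step() +
      ggplot2::labs(
        x = "False positive rate", y = "True positive rate",
        title = sprintf("ROC, %s (%s CV), AUC = %.3f",
                        object$method, object$scheme, object$pooled$auc)
      )
  } else {
    p <- ggplot2::ggplot(curve,
                         ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(
        x = "Recall", y = "Precision",
        title = sprintf("Precision-recall, %s (%s CV), AUPR = %.3f",
                        object$method, object$scheme, object$pooled$aupr)
      )
  }
  p + ggplot2::theme_minimal()
}

#' Heatmap of predicted interaction scores
#'
#' @param object a `dti_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dti_fit <- function(object, ...) {
  edges <- tidy(object)
  ggplot2::ggplot(edges, ggplot2::aes(x = .data$protein_id, y = .data$drug_id,
                                      fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Protein", y = "Drug", fill = "Score",
                  title = sprintf("Predicted interaction scores (%s)",
                                  object$method)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

# FPR/TPR and precision/recall coordinates at every unique threshold.
ranking_curve <- function(scores, labels) {
  lab <- as.logical(labels)
  o <- order(scores, decreasing = TRUE)
  l <- lab[o]
  s <- scores[o]
  tp <- cumsum(l)
  fp <- cumsum(!l)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- c(0, tp[last_of_tie])
  fp <- c(0, fp[last_of_tie])
  tibble::tibble(
    tpr = tp / sum(lab),
    fpr = fp / sum(!lab),
    recall = tp / sum(lab),
    precision = ifelse(tp + fp > 0, tp / (tp + fp), 1)
  )
}
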
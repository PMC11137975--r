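#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object An `ncp_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ncp_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2C7FB8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot extractor training curves
#'
#' @param object A trained `ncp_gru`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch.
#' @export
autoplot.ncp_gru <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, c("train_loss", "val_loss"),
                              names_to = "series", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Epoch", y = "Binary cross-entropy",
                  colour = NULL, title = "Extractor training") +
    ggplot2::theme_minimal()
}

#' Plot feature-selection scores
#'
#' @param object An `ncp_selection` with scores.
#' @param top Show at most this many features (by score).
#' @param ... Unused.
#' @return A ggplot bar chart of scores, selected features highlighted.
#' @export
autoplot.ncp_selection <- function(object, top = 30, ...) {
  d <- tidy(object)
  d <- d[is.finite(d$score) | d$selected, , drop = FALSE]
  d <- d[order(-replace(d$score, !is.finite(d$score), Inf)), , drop = FALSE]
  d <- utils::head(d, top)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$feature,
                                  fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = paste0("score (", object$method, ")"), y = NULL,
                  fill = "selected") +
    ggplot2::theme_minimal()
}

#' Plot per-class transcript length distributions
#'
#' @param data Labeled dataset tibble.
#' @return A ggplot of length densities by class (log10 x axis).
#' @export
plot_length_distribution <- function(data) {
  check_dataset(data)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$length,
                                     fill = .data$label)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Transcript length (nt)", y = "Density",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
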
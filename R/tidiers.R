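#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a feature selection
#'
#' @param x An `ncp_selection`.
#' @param ... Unused.
#' @return Tibble with `feature`, `score` (variance or F statistic, `NA`
#'   for presets) and `selected`.
#' @export
tidy.ncp_selection <- function(x, ...) {
  all_names <- union(names(x$scores), x$selected_names)
  tibble::tibble(feature = all_names,
                 score = unname(x$scores[all_names]),
                 selected = all_names %in% x$selected_names)
}

#' @export
glance.ncp_selection <- function(x, ...) {
  tibble::tibble(method = x$method, n_selected = length(x$selected_names),
                 fitted_on_n = x$fitted_on_n)
}

#' Tidy a paired classifier comparison
#'
#' @param x An `ncp_paired`.
#' @param ... Unused.
#' @return One-row tibble with `f12`, `f21`, `z`, `p`.
#' @export
tidy.ncp_paired <- function(x, ...) {
  tibble::tibble(f12 = x$f12, f21 = x$f21, z = x$z, p = x$p)
}

#' @export
glance.ncp_paired <- tidy.ncp_paired

#' Tidy an ROC curve
#'
#' @param x An `ncp_roc`.
#' @param ... Unused.
#' @return The ROC `points` tibble (`threshold`, `tpr`, `fpr`).
#' @export
tidy.ncp_roc <- function(x, ...) x$points

#' @export
glance.ncp_roc <- function(x, ...) tibble::tibble(auc = x$auc)

#' Tidy an evaluation report (metrics in long form)
#'
#' @param x An `ncp_eval`.
#' @param ... Unused.
#' @return Tibble with `metric`, `value`.
#' @export
tidy.ncp_eval <- function(x, ...) {
  wide <- dplyr::bind_cols(x$metrics, tibble::tibble(auc = x$auc))
  tidyr::pivot_longer(wide, dplyr::everything(), names_to = "metric",
                      values_to = "value")
}

#' @export
glance.ncp_eval <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
                   tibble::tibble(auc = x$auc, TP = x$cm$TP, TN = x$cm$TN,
                                  FP = x$cm$FP, FN = x$cm$FN))
}

#' Tidy an extractor's training history
#'
#' @param x An `ncp_gru`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `train_loss`,
#'   `val_loss`); empty for an untrained model.
#' @export
tidy.ncp_gru <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), train_loss = numeric(),
                                val_loss = numeric())
}

#' @export
glance.ncp_gru <- function(x, ...) {
  h <- tidy(x)
  tibble::tibble(bidirectional = x$config$bidirectional,
                 feature_dim = x$config$seq_length,
                 trained = x$trained, epochs_run = nrow(h),
                 final_train_loss = if (nrow(h)) h$train_loss[nrow(h)]
                 else NA_real_,
                 best_val_loss = if (nrow(h)) min(h$val_loss) else NA_real_)
}

#' @export
glance.ncp_classifier <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_features = length(x$schema),
                 threshold = x$threshold, seed = x$seed)
}

#' @export
glance.ncp_pipeline <- function(x, ...) {
  dplyr::bind_cols(glance(x$classifier),
                   glance(x$report)[, c("acc", "mcc", "f1", "auc")])
}
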
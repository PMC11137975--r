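#' Confusion matrix with ncRNA as the positive class
#'
#' @param truth,prediction Class vectors (`ncRNA`/`mRNA`) of equal length.
#' @return An `ncp_confusion` list with counts `TP`, `TN`, `FP`, `FN`
#'   (TP = ncRNA called ncRNA, TN = mRNA called mRNA).
#' @export
confusion <- function(truth, prediction) {
  truth <- factor(truth, levels = class_levels())
  prediction <- factor(prediction, levels = class_levels())
  if (length(truth) != length(prediction)) {
    stop("truth and prediction lengths differ (", length(truth), " vs ",
         length(prediction), ")")
  }
  if (length(truth) == 0L) stop("empty vectors")
  if (anyNA(truth) || anyNA(prediction)) stop("labels must be mRNA/ncRNA")
  structure(list(TP = sum(truth == "ncRNA" & prediction == "ncRNA"),
                 TN = sum(truth == "mRNA" & prediction == "mRNA"),
                 FP = sum(truth == "mRNA" & prediction == "ncRNA"),
                 FN = sum(truth == "ncRNA" & prediction == "mRNA")),
            class = "ncp_confusion")
}

#' Confusion-matrix performance metrics
#'
#' The seven standard binary metrics with ncRNA positive:
#' ACC = (TP+TN)/(TP+TN+FP+FN), MCC, SE = TP/(TP+FN), SPC = TN/(TN+FP),
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN), F1 = 2TP/(2TP+FP+FN). Any 0/0 is
#' reported as `NA` (undefined) rather than silently as 0.
#'
#' @param cm An `ncp_confusion` (or a list with TP/TN/FP/FN counts).
#' @return One-row tibble: `acc`, `mcc`, `se`, `spc`, `ppv`, `npv`, `f1`.
#' @examples
#' compute_metrics(confusion(c("ncRNA", "mRNA"), c("ncRNA", "mRNA")))
#' @export
compute_metrics <- function(cm) {
  tp <- cm$TP; tn <- cm$TN; fp <- cm$FP; fn <- cm$FN
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) stop("all-zero confusion matrix")
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(tp + fn, tp + fp, tn + fp, tn + fn)))
  tibble::tibble(
    acc = (tp + tn) / total,
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den,
    se = frac(tp, tp + fn),
    spc = frac(tn, tn + fp),
    ppv = frac(tp, tp + fp),
    npv = frac(tn, tn + fn),
    f1 = frac(2 * tp, 2 * tp + fp + fn))
}

#' ROC curve and AUC
#'
#' AUC is computed by the rank (Mann-Whitney) formulation, which handles
#' tied scores by midranks and equals the trapezoidal area under the
#' empirical ROC; the ROC points themselves are returned for plotting.
#'
#' @param truth Class vector (`ncRNA` positive); both classes required.
#' @param scores Numeric scores, larger = more ncRNA-like.
#' @return An `ncp_roc` list: `auc` and a `points` tibble
#'   (`threshold`, `fpr`, `tpr`). [autoplot()] draws the curve.
#' @export
roc_auc <- function(truth, scores) {
  truth <- factor(truth, levels = class_levels())
  stopifnot(length(truth) == length(scores), !anyNA(truth), !anyNA(scores))
  pos <- truth == "ncRNA"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  points <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1)))
  structure(list(auc = auc, points = points), class = "ncp_roc")
}

#' Paired z-test on discordant ncRNA classifications
#'
#' Compares two classifiers on the same instances, restricted (by
#' definition) to those whose truth is ncRNA: `f12` counts instances
#' classified correctly by method A but not B, `f21` the converse, and
#' `z = (f12 - f21) / sqrt(f12 + f21)` with one-tailed
#' `p = 1 - pnorm(z)`. `z > 1.64` is the conventional decision threshold
#' (the one-tailed standard-normal 95% quantile to two decimals; the
#' exact one-tailed p at z = 1.645 is 0.05). With no discordant instances
#' z is reported as 0 with p = 0.5.
#'
#' @param truth True classes.
#' @param pred_a,pred_b Predicted classes from the two methods.
#' @return An `ncp_paired` list: `f12`, `f21`, `z`, `p`.
#' @examples
#' paired_z_test(rep("ncRNA", 15),
#'               rep(c("ncRNA", "mRNA"), c(10, 5)),
#'               rep(c("mRNA", "ncRNA"), c(10, 5)))
#' @export
paired_z_test <- function(truth, pred_a, pred_b) {
  n <- length(truth)
  if (length(pred_a) != n || length(pred_b) != n) {
    stop("truth and prediction lengths differ")
  }
  truth <- factor(truth, levels = class_levels())
  pred_a <- factor(pred_a, levels = class_levels())
  pred_b <- factor(pred_b, levels = class_levels())
  nc <- truth == "ncRNA"
  a_ok <- pred_a[nc] == "ncRNA"
  b_ok <- pred_b[nc] == "ncRNA"
  f12 <- sum(a_ok & !b_ok)
  f21 <- sum(!a_ok & b_ok)
  if (f12 + f21 == 0) {
    z <- 0
    p <- 0.5
  } else {
    z <- (f12 - f21) / sqrt(f12 + f21)
    p <- 1 - stats::pnorm(z)
  }
  structure(list(f12 = f12, f21 = f21, z = z, p = p), class = "ncp_paired")
}

#' Evaluate a classifier bundle on labeled data
#'
#' @param bundle An `ncp_classifier`.
#' @param newdata Feature input matching the bundle schema.
#' @param truth True class vector.
#' @return An `ncp_eval` list: `metrics` (one-row tibble), `cm`
#'   (`ncp_confusion`), `auc`, `roc` (`ncp_roc`) and the `predictions`
#'   tibble.
#' @export
evaluate_classifier <- function(bundle, newdata, truth) {
  pred <- stats::predict(bundle, newdata)
  cm <- confusion(truth, pred$label)
  roc <- roc_auc(truth, pred$prob_ncRNA)
  structure(list(metrics = compute_metrics(cm), cm = cm, auc = roc$auc,
                 roc = roc, predictions = pred),
            class = "ncp_eval")
}

#' @export
print.ncp_confusion <- function(x, ...) {
  cat("<ncp_confusion> TP:", x$TP, "TN:", x$TN, "FP:", x$FP, "FN:", x$FN,
      "\n")
  invisible(x)
}

#' @export
print.ncp_paired <- function(x, ...) {
  cat("<ncp_paired> f12:", x$f12, "f21:", x$f21,
      sprintf("z: %.4f one-tailed p: %.4g", x$z, x$p), "\n")
  invisible(x)
}

#' @export
print.ncp_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<ncp_eval> ACC %.4f | MCC %.4f | SE %.4f | SPC %.4f | F1 %.4f | AUC %.4f\n",
    m$acc, m$mcc, m$se, m$spc, m$f1, x$auc))
  invisible(x)
}

#' Write an evaluation report to JSON and a text table
#'
#' @param eval An `ncp_eval`.
#' @param json_path,text_path Optional output paths (skipped when `NULL`).
#' @return `eval`, invisibly.
#' @export
write_report <- function(eval, json_path = NULL, text_path = NULL) {
  stopifnot(inherits(eval, "ncp_eval"))
  if (!is.null(json_path)) {
    jsonlite::write_json(c(as.list(eval$metrics), list(auc = eval$auc),
                           eval$cm[c("TP", "TN", "FP", "FN")]),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(text_path)) {
    m <- dplyr::bind_cols(eval$metrics, tibble::tibble(auc = eval$auc))
    writeLines(c(paste(sprintf("%6s", toupper(names(m))), collapse = " "),
                 paste(sprintf("%6.4f", unlist(m)), collapse = " ")),
               text_path)
  }
  invisible(eval)
}
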
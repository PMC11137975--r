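#' Fuse handcrafted and deep feature tables
#'
#' Column-binds the handcrafted block (first) and the deep block, then
#' z-score standardizes every column using mean/sd fitted on the training
#' rows only and applied to all rows (validation/test rows never influence
#' the scaler). Zero-variance columns are centered and left unscaled.
#'
#' @param handcrafted Feature table (e.g. from [featurize_dataset()];
#'   `id`/`label` columns are dropped).
#' @param deep Deep feature table ([extract_deep_features_batch()]), same
#'   rows in the same order; may have zero columns.
#' @param train Logical vector marking training rows (default: all rows).
#' @return An `ncp_fused` object: standardized matrix `values`,
#'   `column_names`, scaler `center`/`scale`, and the `train` mask.
#' @export
fuse_features <- function(handcrafted, deep, train = NULL) {
  h <- as.matrix(feature_matrix(handcrafted))
  d <- as.matrix(feature_matrix(deep))
  if (nrow(h) != nrow(d) && ncol(d) > 0) {
    stop("row mismatch: handcrafted has ", nrow(h), ", deep has ", nrow(d))
  }
  m <- if (ncol(d) > 0) cbind(h, d) else h
  if (is.null(train)) train <- rep(TRUE, nrow(m))
  stopifnot(length(train) == nrow(m), any(train))
  center <- colMeans(m[train, , drop = FALSE])
  scale <- apply(m[train, , drop = FALSE], 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  values <- sweep(sweep(m, 2, center), 2, scale, "/")
  structure(list(values = values, column_names = colnames(m),
                 center = center, scale = scale, train = train),
            class = "ncp_fused")
}

#' Train the final classifier on (fused) features
#'
#' Fits one of the three classifier families on the training rows:
#' `"rfc"` a random forest (500 trees, the primary model), `"svm"` an
#' RBF-kernel support vector machine with probability outputs, `"nb"` a
#' Gaussian naive Bayes. `ncRNA` is the positive class throughout.
#'
#' @param x An `ncp_fused` object, or a plain feature table/matrix.
#' @param class_labels Class vector aligned with the rows of `x`. When `x`
#'   is an `ncp_fused`, only its training rows are used for fitting.
#' @param kind One of `"rfc"`, `"svm"`, `"nb"`.
#' @param seed Integer seed for the stochastic fits.
#' @param ntree Number of trees for the forest.
#' @param threshold Decision threshold on P(ncRNA) (default 0.5;
#'   probability >= threshold predicts ncRNA).
#' @return An `ncp_classifier` bundle usable with [predict()].
#' @export
train_classifier <- function(x, class_labels, kind = c("rfc", "svm", "nb"),
                             seed = 1, ntree = 500, threshold = 0.5) {
  kind <- match.arg(kind)
  stopifnot(threshold > 0, threshold < 1)
  m <- classifier_matrix(x)
  train <- if (inherits(x, "ncp_fused")) x$train else rep(TRUE, nrow(m))
  y <- factor(class_labels, levels = class_levels())
  if (anyNA(y)) stop("labels must be mRNA/ncRNA")
  ytr <- droplevels(y[train])
  if (nlevels(ytr) < 2L) stop("both classes must be present for training")
  mtr <- m[train, , drop = FALSE]
  if (nrow(mtr) < 10L) stop("need at least 10 training rows")
  fitted <- withr::with_seed(seed, switch(
    kind,
    rfc = randomForest::randomForest(x = mtr, y = y[train], ntree = ntree),
    svm = e1071::svm(x = mtr, y = y[train], kernel = "radial",
                     probability = TRUE),
    nb = e1071::naiveBayes(x = as.data.frame(mtr), y = y[train])
  ))
  structure(list(kind = kind, fitted_model = fitted,
                 schema = colnames(m), seed = seed, threshold = threshold),
            class = "ncp_classifier")
}

#' Predict ncRNA probability and class
#'
#' @param object An `ncp_classifier` bundle.
#' @param newdata An `ncp_fused`, feature table or matrix whose columns
#'   match the training schema.
#' @param ... Unused.
#' @return Tibble with `prob_ncRNA` and `label` (ncRNA when
#'   `prob_ncRNA >= threshold`).
#' @export
predict.ncp_classifier <- function(object, newdata, ...) {
  m <- classifier_matrix(newdata)
  if (!identical(colnames(m), object$schema)) {
    missing <- setdiff(object$schema, colnames(m))
    extra <- setdiff(colnames(m), object$schema)
    stop("feature schema mismatch; missing: [",
         paste(missing, collapse = ", "), "], unexpected: [",
         paste(extra, collapse = ", "), "]")
  }
  if (nrow(m) == 0L) {
    return(tibble::tibble(prob_ncRNA = numeric(0),
                          label = factor(character(0),
                                         levels = class_levels())))
  }
  prob <- unname(switch(object$kind,
    rfc = stats::predict(object$fitted_model, m, type = "prob")[, "ncRNA"],
    svm = {
      p <- stats::predict(object$fitted_model, m, probability = TRUE)
      attr(p, "probabilities")[, "ncRNA"]
    },
    nb = stats::predict(object$fitted_model, as.data.frame(m),
                        type = "raw")[, "ncRNA"]))
  tibble::tibble(prob_ncRNA = prob,
                 label = factor(ifelse(prob >= object$threshold,
                                       "ncRNA", "mRNA"),
                                levels = class_levels()))
}

#' Run the full training pipeline on a labeled dataset
#'
#' Orchestrates the end-to-end method: stratified 70/30 split, handcrafted
#' featurization (91 features), extractor training on the training split,
#' deep feature extraction (1200 features), fusion with a train-fitted
#' scaler, classifier fit, and evaluation on the validation split.
#'
#' @param data Labeled dataset tibble (e.g. [read_fasta()] per class +
#'   `dplyr::bind_rows()`, or [generate_dataset()]).
#' @param extractor An [extractor_config()].
#' @param classifier Classifier kind (`"rfc"`, `"svm"`, `"nb"`).
#' @param train_fraction Training share of the stratified split.
#' @param seed Integer seed driving the split and the classifier fit (the
#'   extractor uses its own config seed).
#' @param selection Optional `ncp_selection` applied to the handcrafted
#'   block before fusion (e.g. [pinc10_preset()]).
#' @param verbose Log per-stage progress via `message()`.
#' @return An `ncp_pipeline` list: `classifier` bundle, `extractor`,
#'   `report` (validation metrics, see [evaluate_classifier()]),
#'   `selection`, the `split`, and the validation predictions.
#' @export
run_training_pipeline <- function(data, extractor = extractor_config(),
                                  classifier = "rfc", train_fraction = 0.7,
                                  seed = 1, selection = NULL,
                                  verbose = TRUE) {
  check_dataset(data)
  if (anyNA(data$label)) stop("pipeline requires labels on every record")
  say <- function(...) if (verbose) message("[ncpred] ", ...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    say(name, " done in ",
        sprintf("%.1fs", as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  split <- stage("split", split_dataset(data, train_fraction, seed))
  n_tr <- nrow(split$train)
  all_data <- dplyr::bind_rows(split$train, split$validation)
  train_mask <- seq_len(nrow(all_data)) <= n_tr

  hand <- stage("handcrafted featurization", featurize_dataset(all_data))
  if (!is.null(selection)) hand <- apply_selection(hand, selection)

  encoded <- stage("encoding", encode_dataset(all_data, extractor$seq_length))
  model <- stage("extractor training", {
    m <- build_extractor(extractor)
    train_extractor(m, encoded[, train_mask, drop = FALSE],
                    all_data$label[train_mask])
  })
  deep <- stage("deep extraction", extract_deep_features_batch(model, encoded))

  fused <- stage("fusion", fuse_features(hand, deep, train = train_mask))
  bundle <- stage("classifier fit",
                  train_classifier(fused, all_data$label, classifier,
                                   seed = seed))
  report <- stage("validation evaluation", {
    val <- fused$values[!train_mask, , drop = FALSE]
    evaluate_classifier(bundle, val, all_data$label[!train_mask])
  })
  say("validation accuracy ", sprintf("%.4f", report$metrics$acc))
  structure(list(classifier = bundle, extractor = model, report = report,
                 selection = selection, split = split, fused = fused,
                 train_mask = train_mask,
                 validation_predictions = report$predictions),
            class = "ncp_pipeline")
}

#' @export
print.ncp_pipeline <- function(x, ...) {
  cat("<ncp_pipeline> classifier:", x$classifier$kind,
      "| validation ACC:", sprintf("%.4f", x$report$metrics$acc),
      "AUC:", sprintf("%.4f", x$report$auc), "\n")
  invisible(x)
}

# ---- internal ---------------------------------------------------------

classifier_matrix <- function(x) {
  if (inherits(x, "ncp_fused")) return(x$values)
  if (is.matrix(x)) return(x)
  as.matrix(feature_matrix(x))
}
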
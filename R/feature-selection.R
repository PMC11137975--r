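#' Variance-above-mean feature selection
#'
#' Computes the sample variance (denominator n - 1) of every feature
#' column and keeps those whose variance is strictly greater than the mean
#' of all column variances. On the 91 handcrafted features this is the
#' first, unsupervised reduction stage of the selection pipeline.
#'
#' @param features Feature table (tibble/data frame; `id`/`label` columns
#'   are ignored if present).
#' @return A selection object (class `ncp_selection`) with the chosen
#'   feature names in original column order and the per-feature variances
#'   as scores. Use [apply_selection()] to subset a table, [tidy()] for a
#'   tabular view.
#' @export
variance_above_mean <- function(features) {
  m <- as.matrix(feature_matrix(features))
  if (nrow(m) < 2L) stop("need at least 2 rows to estimate variances")
  v <- apply(m, 2, stats::var)
  keep <- names(v)[v > mean(v)]
  new_selection("variance_above_mean", keep, v, nrow(m))
}

#' Per-feature one-way ANOVA F statistics
#'
#' Scores the association between each feature and a two-class label with
#' the one-way ANOVA F statistic (between-group over within-group mean
#' squares). A feature with zero within-class variance but distinct class
#' means scores `Inf`; a constant feature scores 0.
#'
#' @param features Feature table (`id`/`label` columns ignored).
#' @param labels Class vector (two classes, each with >= 2 rows).
#' @return Named numeric vector of F statistics, one per feature.
#' @export
f_test_scores <- function(features, labels) {
  m <- as.matrix(feature_matrix(features))
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2L) {
    stop("need exactly 2 classes, got ", nlevels(labels))
  }
  if (any(table(labels) < 2L)) stop("each class needs >= 2 rows")
  n <- nrow(m)
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n2 <- n - n1
  mu1 <- colMeans(m[g1, , drop = FALSE])
  mu2 <- colMeans(m[!g1, , drop = FALSE])
  mu <- colMeans(m)
  ssb <- n1 * (mu1 - mu)^2 + n2 * (mu2 - mu)^2
  ssw <- colSums((m[g1, , drop = FALSE] -
                    matrix(mu1, n1, ncol(m), byrow = TRUE))^2) +
    colSums((m[!g1, , drop = FALSE] -
               matrix(mu2, n2, ncol(m), byrow = TRUE))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssb == 0] <- 0  # constant features (0/0) score zero
  f
}

#' Combined variance + F-test selection of the top-k features
#'
#' The two-stage reduction: first [variance_above_mean()], then the
#' survivors are ranked by ANOVA F statistic (descending, ties broken by
#' original column order) and the top `k` are kept. With the default
#' `k = 10` this is the compact feature set used by the lightweight
#' classifier pathway.
#'
#' @inheritParams f_test_scores
#' @param k Number of features to keep (default 10).
#' @return A selection object (class `ncp_selection`) listing exactly `k`
#'   feature names, ranked by F statistic.
#' @export
select_pinc10 <- function(features, labels, k = 10) {
  var_sel <- variance_above_mean(features)
  if (length(var_sel$selected_names) < k) {
    stop("only ", length(var_sel$selected_names),
         " features survive the variance threshold; cannot keep ", k)
  }
  surv <- apply_selection(features, var_sel)
  f <- f_test_scores(surv, resolve_labels(features, labels))
  ord <- order(-f, match(names(f), var_sel$selected_names))
  keep <- names(f)[ord][seq_len(k)]
  new_selection("pinc_combined", keep, f, var_sel$fitted_on_n)
}

#' Restrict a feature table to a selection
#'
#' @param features Feature table; any `id`/`label` columns pass through
#'   untouched.
#' @param selection An `ncp_selection` (or a character vector of feature
#'   names).
#' @return The table with feature columns restricted and reordered to the
#'   selection; row order unchanged.
#' @export
apply_selection <- function(features, selection) {
  keep <- if (inherits(selection, "ncp_selection")) {
    selection$selected_names
  } else {
    as.character(selection)
  }
  missing <- setdiff(keep, names(features))
  if (length(missing) > 0) {
    stop("feature(s) not present in table: ", paste(missing, collapse = ", "))
  }
  extras <- intersect(c("id", "label"), names(features))
  features[, c(intersect(extras, "id"), keep, intersect(extras, "label")),
           drop = FALSE]
}

#' The documented 10-feature preset
#'
#' The fixed compact feature set reported for the combined
#' variance + F-test pathway on the original plant training data: GC
#' content, the ORF score, cdsStop and cdsSize, and the T, C, GT, GC, ACG
#' and TAT k-mer frequencies. Usable with [apply_selection()] without
#' refitting; a selection fitted on your own data may differ.
#'
#' @return An `ncp_selection` with the 10 preset names (no scores).
#' @export
pinc10_preset <- function() {
  new_selection("pinc_combined",
                c("gc_content", "Score", "cdsStop", "cdsSize",
                  "T", "C", "GT", "GC", "ACG", "TAT"),
                stats::setNames(numeric(0), character(0)), 0L)
}

#' Serialize / restore a selection
#'
#' Selections round-trip through JSON so a fit on training data can be
#' reused at predict time.
#'
#' @param selection An `ncp_selection`.
#' @param path Output (input) JSON path.
#' @return `path` invisibly; `read_selection()` returns the selection.
#' @export
write_selection <- function(selection, path) {
  stopifnot(inherits(selection, "ncp_selection"))
  jsonlite::write_json(list(method = selection$method,
                            selected_names = selection$selected_names,
                            scores = as.list(selection$scores),
                            fitted_on_n = selection$fitted_on_n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_selection(x$method, as.character(x$selected_names),
                unlist(x$scores) %||% stats::setNames(numeric(0), character(0)),
                as.integer(x$fitted_on_n))
}

#' @export
print.ncp_selection <- function(x, ...) {
  cat("<ncp_selection> method:", x$method, "-", length(x$selected_names),
      "features (fitted on n =", x$fitted_on_n, "rows)\n")
  cat(paste(x$selected_names, collapse = ", "), "\n")
  invisible(x)
}

# ---- internal ---------------------------------------------------------

new_selection <- function(method, selected_names, scores, fitted_on_n) {
  stopifnot(!anyDuplicated(selected_names))
  structure(list(method = method, selected_names = selected_names,
                 scores = scores, fitted_on_n = fitted_on_n),
            class = "ncp_selection")
}

# align a label vector with a possibly id/label-carrying feature table
resolve_labels <- function(features, labels) {
  if (is.null(labels) && "label" %in% names(features)) features$label
  else labels
}
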
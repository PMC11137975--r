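#' Read transcript sequences from a FASTA file
#'
#' Loads a (possibly line-wrapped) FASTA file into a one-row-per-transcript
#' tibble and normalizes every sequence to the working alphabet
#' \{A,C,G,T,N\}: lowercase bases are uppercased, `U` becomes `T`, and any
#' other character (IUPAC ambiguity codes included) becomes `N`.
#'
#' @param path Path to a FASTA file.
#' @param label Optional class label (`"ncRNA"` or `"mRNA"`) attached to
#'   every record, for the common one-file-per-class layout.
#' @return A tibble with columns `id`, `seq`, `label` (factor, `NA` when no
#'   label was supplied) and `length` (nucleotides).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1", "acgu", ">t2", "TTNT"), fa)
#' read_fasta(fa, label = "mRNA")
#' @export
read_fasta <- function(path, label = NULL) {
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    stop("no sequences found in '", path, "'")
  }
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- normalize_sequence(as.character(raw))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  lbl <- if (is.null(label)) NA_character_ else match_label(label)
  new_dataset(ids, seqs, rep(lbl, length(ids)))
}

#' Write a transcript dataset to FASTA
#'
#' @param data Dataset tibble as returned by [read_fasta()].
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, wrap = 60) {
  check_dataset(data)
  stopifnot(wrap >= 1)
  chunks <- purrr::map2(data$id, data$seq, function(id, s) {
    starts <- seq(1L, nchar(s), by = wrap)
    c(paste0(">", id), substring(s, starts, pmin(starts + wrap - 1L, nchar(s))))
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}

#' Read a two-column id/label table
#'
#' Accepts a TSV with columns `id` and `label` (header optional); labels
#' must be `ncRNA` or `mRNA`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id` and `label`.
#' @export
read_label_table <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  has_header <- grepl("^id\t", first) || identical(first, "id\tlabel")
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (!has_header) names(tab)[1:2] <- c("id", "label")
  tibble::tibble(id = as.character(tab$id),
                 label = unname(vapply(tab$label, match_label,
                                       character(1))))
}

#' Attach labels from a label table to a dataset
#'
#' @param data Dataset tibble.
#' @param labels Tibble with columns `id`, `label` (see
#'   [read_label_table()]).
#' @return `data` with its `label` column filled from `labels`.
#' @export
attach_labels <- function(data, labels) {
  check_dataset(data)
  idx <- match(data$id, labels$id)
  if (anyNA(idx)) {
    stop("no label for id(s): ",
         paste(data$id[is.na(idx)], collapse = ", "))
  }
  data$label <- factor(labels$label[idx], levels = class_levels())
  data
}

#' Stratified train/validation split
#'
#' Splits a labeled dataset into training and validation partitions,
#' stratified by class: within each class, `floor(train_fraction * n)`
#' records are drawn (without replacement, driven solely by `seed`) into
#' the training set and the remainder go to validation.
#'
#' @param data Labeled dataset tibble; every record must carry a label and
#'   both classes must be present.
#' @param train_fraction Fraction of each class assigned to training, in
#'   (0, 1]. Default 0.7 (a 70/30 split).
#' @param seed Integer seed controlling the shuffle.
#' @return A list with elements `train` and `validation`, each a dataset
#'   tibble.
#' @examples
#' d <- generate_dataset(generator_params(n_per_class = 10, seed = 1))
#' sp <- split_dataset(d, train_fraction = 0.7, seed = 1)
#' nrow(sp$train); nrow(sp$validation)
#' @export
split_dataset <- function(data, train_fraction = 0.7, seed) {
  check_dataset(data)
  stopifnot(train_fraction > 0, train_fraction <= 1)
  if (anyNA(data$label)) stop("all records must be labeled before splitting")
  counts <- table(droplevels(data$label))
  if (length(counts) < 2L) stop("both classes must be present")
  if (any(counts < 2L)) {
    stop("each class needs at least 2 records (got ",
         paste(counts, collapse = ", "), ")")
  }
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(levels(droplevels(data$label)), function(cl) {
      rows <- which(data$label == cl)
      n_tr <- floor(train_fraction * length(rows))
      sample(rows, n_tr)
    }))
  })
  train_idx <- sort(train_idx)
  list(train = data[train_idx, , drop = FALSE],
       validation = data[setdiff(seq_len(nrow(data)), train_idx), ,
                         drop = FALSE])
}

#' Per-class sequence length summary
#'
#' @param data Labeled dataset tibble.
#' @return A tibble with one row per class: `label`, `n`, `median`, `min`,
#'   `max` (lengths in nucleotides; the median is the standard order
#'   statistic, i.e. the mean of the two middle values for even n).
#' @export
length_summary <- function(data) {
  check_dataset(data)
  if (nrow(data) == 0L) stop("empty dataset")
  data |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(),
                     median = stats::median(.data$length),
                     min = min(.data$length),
                     max = max(.data$length),
                     .groups = "drop")
}

# ---- internal helpers -------------------------------------------------

class_levels <- function() c("mRNA", "ncRNA")  # ncRNA = positive class

match_label <- function(label) {
  label <- as.character(label)
  if (!label %in% class_levels()) {
    stop("label must be one of ", paste(class_levels(), collapse = ", "),
         " (got '", label, "')")
  }
  label
}

normalize_sequence <- function(seq) {
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  gsub("[^ACGT]", "N", seq)
}

new_dataset <- function(id, seq, label) {
  tibble::tibble(id = as.character(id), seq = as.character(seq),
                 label = factor(label, levels = class_levels()),
                 length = nchar(seq))
}

check_dataset <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("id", "seq", "label", "length") %in% names(data)))
  invisible(data)
}
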
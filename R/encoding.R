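#' One-hot encode a sequence to a fixed length
#'
#' Encodes each base as a four-dimensional binary vector (columns ordered
#' A, C, G, T). Sequences longer than `length_out` are truncated at the 3'
#' end (the 5' prefix is kept, since the ORF-derived features are
#' 5'-anchored); shorter sequences are zero-padded at the tail. `N` and
#' padding positions are all-zero rows.
#'
#' @param seq A single sequence over \{A,C,G,T,N\}.
#' @param length_out Target length L (>= 1).
#' @return An `length_out` x 4 binary matrix with attribute
#'   `effective_length` (number of real, pre-padding positions).
#' @examples
#' encode_onehot("ACGT", 6)
#' @export
encode_onehot <- function(seq, length_out) {
  idx <- encode_indices(seq, length_out)
  m <- matrix(0L, nrow = length_out, ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  hit <- which(idx >= 1L & idx <= 4L)
  m[cbind(hit, idx[hit])] <- 1L
  attr(m, "effective_length") <- attr(idx, "effective_length")
  m
}

#' Integer-index encode a sequence for an embedding layer
#'
#' Maps A,C,G,T,N to 1..5 with 0 reserved for tail padding; truncation and
#' padding follow [encode_onehot()]. These indices feed the learned
#' 50-dimensional nucleotide embedding of the deep extractor.
#'
#' @inheritParams encode_onehot
#' @return Integer vector of length `length_out` over \{0..5\} with
#'   attribute `effective_length`.
#' @examples
#' encode_indices("ACGT", 6)
#' @export
encode_indices <- function(seq, length_out) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (length_out < 1) stop("length_out must be >= 1")
  if (!nzchar(seq)) stop("cannot encode an empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(idx)) {
    stop("unexpected character(s) in sequence; normalize with read_fasta()")
  }
  eff <- min(length(idx), length_out)
  out <- integer(length_out)
  out[seq_len(eff)] <- idx[seq_len(eff)]
  attr(out, "effective_length") <- eff
  out
}

#' Index-encode every record of a dataset
#'
#' @param data Dataset tibble (see [read_fasta()]).
#' @param length_out Target length per sequence.
#' @return An `length_out` x n integer matrix, one column per record, with
#'   column names the record ids.
#' @export
encode_dataset <- function(data, length_out) {
  check_dataset(data)
  m <- vapply(data$seq, function(s) as.integer(encode_indices(s, length_out)),
              integer(length_out), USE.NAMES = FALSE)
  m <- matrix(m, nrow = length_out, ncol = nrow(data))
  colnames(m) <- data$id
  m
}
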
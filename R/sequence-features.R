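#' Names of the 91 handcrafted sequence features
#'
#' Fixed order: 4 mononucleotide, 16 dinucleotide and 64 trinucleotide
#' frequencies (lexicographic over A < C < G < T), then the five
#' ORF/CDS-derived quantities (`Score`, `cdsStart`, `cdsStop`, `cdsSize`,
#' `cdsPercent`), sequence `length` and `gc_content`.
#'
#' @return Character vector of length 91.
#' @export
feature_names <- function() {
  kmers <- unlist(lapply(1:3, function(k) {
    apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1, drop = FALSE],
          1, paste, collapse = "")
  }))
  c(kmers, "Score", "cdsStart", "cdsStop", "cdsSize", "cdsPercent",
    "length", "gc_content")
}

#' k-mer frequency profile of a sequence
#'
#' Counts every length-k window composed solely of \{A,C,G,T\} (windows
#' containing `N` are skipped) and divides by the number of valid windows;
#' if the sequence has no valid window the profile is all zero.
#'
#' @param seq A single sequence over \{A,C,G,T,N\}.
#' @param k Window size, one of 1, 2, 3.
#' @return Named numeric vector of length `4^k` (k-mers in lexicographic
#'   order over A < C < G < T) summing to 1 (or 0 when degenerate).
#' @examples
#' kmer_frequencies("ACGT", 2)
#' @export
kmer_frequencies <- function(seq, k) {
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  total <- sum(counts)
  if (total == 0) counts * 0 else counts / total
}

#' GC content of a sequence
#'
#' `(#C + #G) / (#A + #C + #G + #T)`; `N` is excluded from both numerator
#' and denominator.
#'
#' @param seq A single sequence over \{A,C,G,T,N\}.
#' @return GC fraction in \[0, 1\].
#' @examples
#' gc_content("ATGC")
#' @export
gc_content <- function(seq) {
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                        c("A", "C", "G", "T"))
  total <- sum(counts)
  if (total == 0) stop("sequence has no unambiguous base")
  unname((counts[["C"]] + counts[["G"]]) / total)
}

#' Locate the best open reading frame and score its coding potential
#'
#' Scans the three forward reading frames for ORFs (`ATG` ... in-frame
#' stop, stop codon included in the span; an ORF with no downstream stop
#' runs to the last complete codon) and selects the longest, breaking ties
#' by smallest start. The protein-likeness score is
#' `2 * cdsSize + 50` if an in-frame stop terminates the ORF `+ 50` if the
#' start-codon context has A or G three bases upstream of the `ATG` (a
#' Kozak-like bonus), so that ORFs of ~400 nt and above score >= 800, the
#' conventional "likely protein" threshold.
#'
#' @param seq A single sequence over \{A,C,G,T,N\}.
#' @param both_strands Also scan the reverse complement (off by default;
#'   transcript input is orientation-resolved). When the best ORF lies on
#'   the reverse strand its coordinates refer to the reverse-complemented
#'   sequence and `strand` is `"-"`.
#' @return One-row tibble: `score`, `cdsStart` (0-based inclusive),
#'   `cdsStop` (0-based exclusive), `cdsSize` (`cdsStop - cdsStart`),
#'   `cdsPercent` (`cdsSize / length`), `strand`. All numeric fields are 0
#'   when no ORF exists.
#' @examples
#' predict_cds("ATGAAATAG")
#' @export
predict_cds <- function(seq, both_strands = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  best <- best_orf(seq)
  strand <- "+"
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    best_rc <- best_orf(rc)
    if (best_rc$size > best$size ||
        (best_rc$size == best$size && best_rc$size > 0 &&
         best_rc$start < best$start)) {
      best <- best_rc
      strand <- "-"
    }
  }
  n <- nchar(seq)
  if (best$size == 0) {
    return(tibble::tibble(score = 0, cdsStart = 0, cdsStop = 0, cdsSize = 0,
                          cdsPercent = 0, strand = "+"))
  }
  scanned <- if (strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  } else {
    seq
  }
  kozak <- best$start >= 3 &&
    substr(scanned, best$start - 2, best$start - 2) %in% c("A", "G")
  tibble::tibble(score = 2 * best$size + 50 * best$terminated + 50 * kozak,
                 cdsStart = best$start, cdsStop = best$start + best$size,
                 cdsSize = best$size, cdsPercent = best$size / n,
                 strand = strand)
}

#' Compute the full 91-feature vector for one sequence
#'
#' Concatenates the k = 1, 2, 3 k-mer frequency profiles (84 values), the
#' five CDS quantities from [predict_cds()], sequence length and GC
#' content, in the order of [feature_names()].
#'
#' @param seq A single sequence over \{A,C,G,T,N\}.
#' @return Named numeric vector of length 91.
#' @export
extract_sequence_features <- function(seq) {
  stopifnot(nzchar(seq))
  cds <- predict_cds(seq)
  out <- c(kmer_frequencies(seq, 1), kmer_frequencies(seq, 2),
           kmer_frequencies(seq, 3),
           cds$score, cds$cdsStart, cds$cdsStop, cds$cdsSize, cds$cdsPercent,
           nchar(seq), gc_content(seq))
  names(out) <- feature_names()
  out
}

#' Handcrafted feature table for a whole dataset
#'
#' @param data Dataset tibble (see [read_fasta()]).
#' @return A tibble with columns `id`, the 91 features of
#'   [feature_names()], and `label`; rows preserve dataset order.
#' @examples
#' d <- generate_dataset(generator_params(n_per_class = 5, seed = 1))
#' featurize_dataset(d)
#' @export
featurize_dataset <- function(data) {
  check_dataset(data)
  if (nrow(data) == 0L) stop("empty dataset")
  set <- Biostrings::DNAStringSet(data$seq)
  kmer_block <- do.call(cbind, lapply(1:3, function(k) {
    counts <- Biostrings::oligonucleotideFrequency(set, width = k)
    tot <- rowSums(counts)
    counts / ifelse(tot == 0, 1, tot)
  }))
  cds <- purrr::imap(data$seq, function(s, i) {
    tryCatch(predict_cds(s),
             error = function(e) stop("featurization failed for record '",
                                      data$id[i], "': ", conditionMessage(e)))
  })
  cds <- dplyr::bind_rows(cds)
  gc <- purrr::imap_dbl(data$seq, function(s, i) {
    tryCatch(gc_content(s),
             error = function(e) stop("featurization failed for record '",
                                      data$id[i], "': ", conditionMessage(e)))
  })
  m <- cbind(kmer_block, Score = cds$score, cdsStart = cds$cdsStart,
             cdsStop = cds$cdsStop, cdsSize = cds$cdsSize,
             cdsPercent = cds$cdsPercent, length = data$length,
             gc_content = gc)
  colnames(m) <- feature_names()
  dplyr::bind_cols(tibble::tibble(id = data$id),
                   tibble::as_tibble(m),
                   tibble::tibble(label = data$label))
}

#' Strip bookkeeping columns from a feature table
#'
#' @param features Feature tibble from [featurize_dataset()] (or any table
#'   with optional `id`/`label` columns).
#' @return Numeric tibble of feature columns only.
#' @export
feature_matrix <- function(features) {
  features[, setdiff(names(features), c("id", "label")), drop = FALSE]
}

# ---- internal ---------------------------------------------------------

# All per-ATG ORFs of the three forward frames.
# Returns a data.frame with 0-based `start`, `size` (nt, multiple of 3,
# stop codon included) and `terminated`.
scan_orfs <- function(seq) {
  n <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3
    if (ncod < 1) next
    starts <- f + 3 * (seq_len(ncod) - 1) + 1  # 1-based codon starts
    codons <- substring(seq, starts, starts + 2)
    atg <- which(codons == "ATG")
    if (length(atg) == 0) next
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    nxt <- if (length(stops)) stops[findInterval(atg, stops) + 1L] else
      rep(NA_integer_, length(atg))
    term <- !is.na(nxt)
    end <- ifelse(term, nxt, ncod)
    out[[f + 1]] <- data.frame(start = starts[atg] - 1L,
                               size = (end - atg + 1L) * 3L,
                               terminated = term)
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), size = integer(),
                      terminated = logical()))
  }
  do.call(rbind, out)
}

best_orf <- function(seq) {
  orfs <- scan_orfs(seq)
  if (nrow(orfs) == 0) {
    return(list(start = 0L, size = 0L, terminated = FALSE))
  }
  orfs <- orfs[order(-orfs$size, orfs$start), , drop = FALSE]
  as.list(orfs[1, ])
}
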
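# Independent oracles and fixture builders shared across the suite.

# Brute-force ORF finder: enumerate every ATG, walk codon by codon to the
# next in-frame stop (or the last complete codon), keep the longest span
# with smallest-start tie-break.  Deliberately simple and independent of
# the package's scanner.
oracle_cds <- function(seq) {
  n <- nchar(seq)
  best <- list(start = 0L, size = 0L, terminated = FALSE)
  i <- 1L
  while (i + 2L <= n) {
    if (substr(seq, i, i + 2L) == "ATG") {
      j <- i + 3L
      terminated <- FALSE
      end <- i - 1L + 3L * ((n - i + 1L) %/% 3L)
      while (j + 2L <= n) {
        if (substr(seq, j, j + 2L) %in% c("TAA", "TAG", "TGA")) {
          terminated <- TRUE
          end <- j + 2L
          break
        }
        j <- j + 3L
      }
      size <- end - i + 1L
      if (size > best$size) {
        best <- list(start = i - 1L, size = size, terminated = terminated)
      }
    }
    i <- i + 1L
  }
  best$score <- if (best$size == 0) 0 else {
    kozak <- best$start >= 3 &&
      substr(seq, best$start - 2L, best$start - 2L) %in% c("A", "G")
    2 * best$size + 50 * best$terminated + 50 * kozak
  }
  best
}

# Pairwise-comparison AUC oracle (probability a positive outscores a
# negative, ties counted half).
oracle_auc <- function(truth, scores) {
  sp <- scores[truth == "ncRNA"]
  sn <- scores[truth == "mRNA"]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

random_seq <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)),
        collapse = "")
}

# A deterministic tiny labeled dataset for table-level tests.
toy_dataset <- function(n_per_class = 5, seed = 1) {
  generate_dataset(generator_params(n_per_class = n_per_class, seed = seed))
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

# A quick extractor config for unit tests (full-size training lives in
# the acceptance suite only).
tiny_config <- function(...) {
  args <- utils::modifyList(list(seq_length = 60, embedding_dim = 8,
                                 hidden_units = 6, batch_size = 8,
                                 epochs = 4, patience = Inf, seed = 7),
                            list(...))
  do.call(extractor_config, args)
}
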
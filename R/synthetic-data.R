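#' Parameters of the synthetic transcript generator
#'
#' Defaults emulate the structure of the curated plant training data the
#' method assumes: balanced classes, coding transcripts with median length
#' 1029 nt carrying a single long ORF, non-coding transcripts with median
#' length 321 nt of which a 0.1 share are short (60-200 nt) small ncRNAs
#' and the rest lncRNA-like, and a mild GC gap between classes. Lengths
#' are log-normal; the default dispersion (sigma 0.5 on the log scale)
#' places ~95% of coding lengths below 2000 nt.
#'
#' @param n_per_class Records per class.
#' @param coding_length_median,noncoding_length_median Median lengths (nt).
#' @param length_dispersion Log-normal sigma of the length draws.
#' @param coding_orf_fraction Fraction of a coding transcript occupied by
#'   its planted ORF (rounded down to a codon multiple).
#' @param gc_coding,gc_noncoding Target GC composition per class.
#' @param sncRNA_fraction Share of short ncRNAs among positives.
#' @param seed Integer seed; all draws are fully determined by it.
#' @return A `GeneratorParams`-style list (class `ncp_generator_params`).
#' @export
generator_params <- function(n_per_class = 200, coding_length_median = 1029,
                             noncoding_length_median = 321,
                             length_dispersion = 0.5,
                             coding_orf_fraction = 0.7, gc_coding = 0.45,
                             gc_noncoding = 0.40, sncRNA_fraction = 0.1,
                             seed = 42) {
  p <- list(n_per_class = as.integer(n_per_class),
            coding_length_median = as.integer(coding_length_median),
            noncoding_length_median = as.integer(noncoding_length_median),
            length_dispersion = length_dispersion,
            coding_orf_fraction = coding_orf_fraction,
            gc_coding = gc_coding, gc_noncoding = gc_noncoding,
            sncRNA_fraction = sncRNA_fraction, seed = as.integer(seed))
  stopifnot(p$n_per_class >= 1,
            p$coding_length_median >= 30, p$noncoding_length_median >= 30,
            p$length_dispersion > 0,
            p$coding_orf_fraction > 0, p$coding_orf_fraction <= 1,
            p$gc_coding > 0, p$gc_coding < 1,
            p$gc_noncoding > 0, p$gc_noncoding < 1,
            p$sncRNA_fraction > 0, p$sncRNA_fraction <= 1)
  structure(p, class = "ncp_generator_params")
}

#' Generate coding-like transcripts
#'
#' Each record draws its length from a log-normal around the coding
#' median, embeds a single ORF (ATG, biased sense codons free of in-frame
#' stops, one stop codon) covering `coding_orf_fraction` of the length,
#' and flanks it with random UTR sequence at the coding GC composition.
#' Codon weights combine the base composition with a GC bias at the
#' wobble (third) position and are calibrated so the expected overall GC
#' equals `gc_coding`.
#'
#' @param params A [generator_params()].
#' @return Dataset tibble labeled `mRNA`.
#' @export
generate_coding <- function(params) {
  stopifnot(inherits(params, "ncp_generator_params"))
  codons <- codon_table(params$gc_coding)
  withr::with_seed(params$seed, {
    seqs <- vapply(seq_len(params$n_per_class), function(i) {
      len <- 0L
      while (len < 33L) {
        len <- as.integer(round(stats::rlnorm(
          1, log(params$coding_length_median), params$length_dispersion)))
      }
      orf_nt <- max(9L, 3L * (floor(params$coding_orf_fraction * len / 3)))
      orf_nt <- min(orf_nt, 3L * (len %/% 3L))
      n_inner <- orf_nt / 3L - 2L
      inner <- sample(codons$codon, n_inner, replace = TRUE,
                      prob = codons$weight)
      stop_codon <- sample(c("TAA", "TAG", "TGA"), 1)
      utr_total <- len - orf_nt
      utr5 <- sample.int(utr_total + 1L, 1L) - 1L
      paste0(random_bases(utr5, params$gc_coding), "ATG",
             paste(inner, collapse = ""), stop_codon,
             random_bases(utr_total - utr5, params$gc_coding))
    }, character(1))
    new_dataset(sprintf("mrna_%05d", seq_along(seqs)), seqs, "mRNA")
  })
}

#' Generate non-coding-like transcripts
#'
#' A `1 - sncRNA_fraction` share of lncRNA-like records (log-normal around
#' the non-coding median) plus an `sncRNA_fraction` share of short records
#' (uniform 60-200 nt), all i.i.d. at the non-coding GC composition, with
#' ORF suppression: any in-frame ATG-to-stop span longer than 150 nt is
#' disrupted by overwriting its midpoint codon with a stop, until no such
#' span remains.
#'
#' @param params A [generator_params()].
#' @return Dataset tibble labeled `ncRNA`.
#' @export
generate_noncoding <- function(params) {
  stopifnot(inherits(params, "ncp_generator_params"))
  n <- params$n_per_class
  n_snc <- max(1L, round(params$sncRNA_fraction * n))
  withr::with_seed(params$seed + 1L, {
    is_snc <- seq_len(n) <= n_snc
    seqs <- vapply(seq_len(n), function(i) {
      len <- if (is_snc[i]) {
        sample(60:200, 1)
      } else {
        l <- 0L
        while (l < 60L) {
          l <- as.integer(round(stats::rlnorm(
            1, log(params$noncoding_length_median),
            params$length_dispersion)))
        }
        l
      }
      suppress_orfs(random_bases(len, params$gc_noncoding), 150L)
    }, character(1))
    d <- new_dataset(sprintf("ncrna_%05d", seq_len(n)), seqs, "ncRNA")
    d$sncRNA <- is_snc
    d
  })
}

#' Generate a balanced, shuffled labeled dataset
#'
#' Exactly `n_per_class` records of each class, shuffled deterministically
#' by the seed. This is the standard input for end-to-end testing of the
#' pipeline without external downloads.
#'
#' @param params A [generator_params()].
#' @return Dataset tibble with both classes.
#' @examples
#' d <- generate_dataset(generator_params(n_per_class = 20, seed = 42))
#' length_summary(d)
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "ncp_generator_params"))
  pos <- generate_noncoding(params)
  pos$sncRNA <- NULL
  neg <- generate_coding(params)
  all_data <- dplyr::bind_rows(pos, neg)
  withr::with_seed(params$seed + 2L,
                   all_data[sample.int(nrow(all_data)), , drop = FALSE])
}

#' Write a generated dataset as paired FASTA files plus a label table
#'
#' @param data Labeled dataset tibble.
#' @param dir Output directory (created if needed).
#' @return Invisible named paths (`positives`, `negatives`, `labels`).
#' @export
write_dataset_files <- function(data, dir) {
  check_dataset(data)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(positives = file.path(dir, "positives.fa"),
             negatives = file.path(dir, "negatives.fa"),
             labels = file.path(dir, "labels.tsv"))
  write_fasta(data[data$label == "ncRNA", ], paths[["positives"]])
  write_fasta(data[data$label == "mRNA", ], paths[["negatives"]])
  utils::write.table(data.frame(id = data$id, label = data$label),
                     paths[["labels"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

# ---- internal ---------------------------------------------------------

random_bases <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# 61 sense codons weighted by base composition at gc_base with a GC bias
# at the wobble position; gc_base is solved so the expected GC of a drawn
# codon equals the target.
codon_table <- function(gc_target, wobble_bias = 1.5) {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases,
                      stringsAsFactors = FALSE)
  codon <- paste0(grid$b1, grid$b2, grid$b3)
  sense <- !codon %in% c("TAA", "TAG", "TGA")
  gc_count <- (grid$b1 %in% c("G", "C")) + (grid$b2 %in% c("G", "C")) +
    (grid$b3 %in% c("G", "C"))
  weights_for <- function(g) {
    p <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    q <- p * c(1, wobble_bias, wobble_bias, 1)
    q <- q / sum(q)
    w <- p[grid$b1] * p[grid$b2] * q[grid$b3]
    w[!sense] <- 0
    w / sum(w)
  }
  expected_gc <- function(g) sum(weights_for(g) * gc_count / 3) - gc_target
  g <- stats::uniroot(expected_gc, c(0.05, 0.95))$root
  w <- weights_for(g)
  data.frame(codon = codon[sense], weight = w[sense])
}

# Overwrite the midpoint codon of any ORF span longer than max_orf nt
# with TAA until none remains (TAA cannot create a new ATG, so this
# terminates).
suppress_orfs <- function(seq, max_orf = 150L) {
  repeat {
    orfs <- scan_orfs(seq)
    big <- orfs[orfs$size > max_orf, , drop = FALSE]
    if (nrow(big) == 0) return(seq)
    o <- big[which.max(big$size), ]
    mid_codon <- o$size %/% 6L  # 0-based codon index near the span middle
    pos <- o$start + 3L * mid_codon + 1L
    substr(seq, pos, pos + 2L) <- "TAA"
  }
}
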
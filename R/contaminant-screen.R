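#' Per-scaffold GC and average k-mer coverage signatures
#'
#' For every scaffold of at least `min_length` bp, computes its GC % (over
#' ACGT only) and the mean multiplicity of its canonical k-mers in the
#' read spectrum of the same sample (windows containing N skipped). On a
#' GC-by-coverage plot, host scaffolds form one cluster; microbial
#' contaminants, sequenced from a different underlying abundance, form
#' separate clusters that can be gated rectangularly.
#'
#' @param assembly An assembly `tibble(name, seq)`.
#' @param spectrum A `kmer_spectrum` of the sample's reads, built with
#'   `keep_kmers = TRUE`.
#' @param min_length Minimum scaffold length considered (default 1 kb).
#' @return A tibble: `name`, `gc_percent`, `avg_kmer_coverage`, `length`.
#' @seealso [classify_candidates()], [plot_gc_coverage()]
#' @export
scaffold_signatures <- function(assembly, spectrum, min_length = 1000L) {
  assembly <- as_seq_tbl(assembly, "assembly")
  kmers <- attr(spectrum, "kmer_counts")
  if (is.null(kmers)) {
    stop("spectrum lacks k-mer counts; rebuild with keep_kmers = TRUE",
         call. = FALSE)
  }
  k <- attr(spectrum, "k")
  keep <- assembly[nchar(assembly$seq) >= min_length, ]
  if (any(nchar(keep$seq) < k)) {
    stop("scaffold shorter than k = ", k, call. = FALSE)
  }
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(keep$seq))
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  tibble(
    name = keep$name,
    gc_percent = 100 * rowSums(freq[, c("C", "G"), drop = FALSE]) / acgt,
    avg_kmer_coverage = cpp_scaffold_kmer_coverage(keep$seq, kmers$kmer,
                                                   kmers$count, k),
    length = nchar(keep$seq)
  )
}

#' Gate candidate contaminant scaffolds on GC and coverage
#'
#' Flags scaffolds falling inside a rectangular gate on the GC-by-coverage
#' plane (both bounds inclusive). Gates are sample-specific: they are read
#' off the observed contaminant cluster, not fixed constants. Candidates
#' are meant to be confirmed against sequence databases before excision;
#' pass the confirmed subset to [excise_contaminant_span()] or drop whole
#' scaffolds.
#'
#' @param signatures A signature tibble from [scaffold_signatures()].
#' @param gc_range `c(lo, hi)` GC % gate.
#' @param cov_range `c(lo, hi)` average k-mer coverage gate.
#' @return The signatures tibble with a logical `candidate` column.
#' @export
classify_candidates <- function(signatures, gc_range, cov_range) {
  stopifnot(length(gc_range) == 2, length(cov_range) == 2,
            gc_range[1] <= gc_range[2], cov_range[1] <= cov_range[2])
  dplyr::mutate(
    signatures,
    candidate = .data$gc_percent >= gc_range[1] &
      .data$gc_percent <= gc_range[2] &
      .data$avg_kmer_coverage >= cov_range[1] &
      .data$avg_kmer_coverage <= cov_range[2]
  )
}
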
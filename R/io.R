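#' Read and write sequence and interval files
#'
#' Thin wrappers around Biostrings and readr that move between the package's
#' tibble representations and the standard on-disk formats: FASTA (60-column
#' wrap), FASTQ (Phred+33, paired files), BED6 and phased VCF v4.2.
#'
#' @param path,r1_path,r2_path File paths.
#' @param x For `write_fasta()`, a genome/assembly as `tibble(name, seq)`
#'   (or named character vector).
#' @param pairs A paired-read tibble with columns `id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`.
#' @param width Line wrap width for FASTA output.
#' @return Readers return tibbles; writers return their input invisibly.
#' @name seq_io
NULL

#' @rdname seq_io
#' @export
read_fasta <- function(path) {
  as_seq_tbl(Biostrings::readDNAStringSet(path))
}

#' @rdname seq_io
#' @export
write_fasta <- function(x, path, width = 60L) {
  x <- as_seq_tbl(x)
  set <- Biostrings::DNAStringSet(setNames(x$seq, x$name))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(x)
}

#' @rdname seq_io
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- Biostrings::readQualityScaledDNAStringSet(r1_path)
  r2 <- Biostrings::readQualityScaledDNAStringSet(r2_path)
  stopifnot(length(r1) == length(r2))
  tibble(
    id = sub("/[12]$", "", sub(" .*$", "", names(r1))),
    seq1 = as.character(r1), qual1 = as.character(Biostrings::quality(r1)),
    seq2 = as.character(r2), qual2 = as.character(Biostrings::quality(r2))
  )
}

#' @rdname seq_io
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  mate <- function(seqs, quals, ids) {
    set <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(seqs, ids)),
      Biostrings::PhredQuality(quals)
    )
    set
  }
  Biostrings::writeQualityScaledXStringSet(
    mate(pairs$seq1, pairs$qual1, paste0(pairs$id, "/1")), r1_path)
  Biostrings::writeQualityScaledXStringSet(
    mate(pairs$seq2, pairs$qual2, paste0(pairs$id, "/2")), r2_path)
  invisible(pairs)
}

#' Read and write BED6 interval files
#'
#' Coordinates are 0-based half-open, as in the BED standard.
#'
#' @param path File path.
#' @param bed A tibble with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @return `read_bed()` returns a BED6 tibble; `write_bed()` its input,
#'   invisibly.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  names(bed) <- cols[seq_len(ncol(bed))]
  bed
}

#' @rdname read_bed
#' @export
write_bed <- function(bed, path) {
  out <- bed
  if (is.null(out$name)) out$name <- paste0("feature_", seq_len(nrow(out)))
  if (is.null(out$score)) out$score <- 0L
  if (is.null(out$strand)) out$strand <- "+"
  readr::write_tsv(out[, c("chrom", "start", "end", "name", "score", "strand")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(bed)
}

#' Read a phased VCF into the package's variant tibble
#'
#' Parses a VCF v4.2 file (via vcfR) honoring the `GT` (with `|` marking
#' phased genotypes), `PS` (phase set) and `AD` (per-allele depth) fields,
#' the layout produced by read-based phasing tools. Multi-allelic records
#' are not supported; the first sample column is used.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @return A variant tibble with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `kind` (`SNP`/`INS`/`DEL`/`SV`), `a1`, `a2` (allele index of
#'   haplotype A and B), `phased`, `phase_set`, `ad_ref`, `ad_alt`.
#' @seealso [write_phased_vcf()], [score_phase_sets()]
#' @export
read_phased_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_phased_vcf() requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  ps <- suppressWarnings(vcfR::extract.gt(v, element = "PS", as.numeric = TRUE)[, 1])
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  ad_parts <- stringr::str_split_fixed(ad, ",", 2)
  phased <- stringr::str_detect(gt, stringr::fixed("|"))
  alleles <- stringr::str_split_fixed(gt, "[|/]", 2)
  tibble(
    chrom = as.character(v@fix[, "CHROM"]),
    pos = as.integer(v@fix[, "POS"]),
    ref = as.character(v@fix[, "REF"]),
    alt = as.character(v@fix[, "ALT"]),
    a1 = as.integer(alleles[, 1]),
    a2 = as.integer(alleles[, 2]),
    phased = phased,
    phase_set = ifelse(phased, as.integer(ps), NA_integer_),
    ad_ref = as.integer(ad_parts[, 1]),
    ad_alt = as.integer(ad_parts[, 2])
  ) |>
    dplyr::mutate(kind = variant_kind(.data$ref, .data$alt),
                  .after = "alt")
}

#' Write a variant tibble as a phased VCF v4.2 file
#'
#' Emits `GT:PS:AD` sample fields: `|`-separated genotypes with an integer
#' `PS` tag for phased variants, `/`-separated genotypes without `PS` for
#' unphased ones. The output is plain text so it round-trips through any
#' VCF reader.
#'
#' @param variants A variant tibble (see [read_phased_vcf()] for columns).
#' @param path Output path.
#' @param sample Sample name for the single genotype column.
#' @return The variant tibble, invisibly.
#' @export
write_phased_vcf <- function(variants, path, sample = "sample1") {
  sep <- ifelse(variants$phased, "|", "/")
  gt <- paste0(variants$a1, sep, variants$a2)
  fmt <- ifelse(variants$phased, "GT:PS:AD", "GT:AD")
  smp <- ifelse(
    variants$phased,
    paste0(gt, ":", variants$phase_set, ":", variants$ad_ref, ",", variants$ad_alt),
    paste0(gt, ":", variants$ad_ref, ",", variants$ad_alt)
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", "PASS", ".", fmt, smp, sep = "\t")
  writeLines(c(header, body), path)
  invisible(variants)
}
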
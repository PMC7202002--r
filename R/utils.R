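# Internal helpers shared across modules.

# Reverse complement of plain character sequences. Goes through Biostrings
# so IUPAC ambiguity codes complement correctly.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Coerce a genome/assembly argument to the canonical tibble(name, seq) form.
as_seq_tbl <- function(x, arg = "x") {
  if (inherits(x, "DNAStringSet")) {
    return(tibble(name = names(x), seq = as.character(x)))
  }
  if (is.character(x)) {
    nm <- names(x)
    if (is.null(nm)) nm <- paste0("seq_", seq_along(x))
    return(tibble(name = nm, seq = unname(x)))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("name", "seq") %in% names(x)))
    return(as_tibble(x)[, union(c("name", "seq"), names(x))])
  }
  stop("cannot interpret `", arg, "` as a set of sequences", call. = FALSE)
}

# Pull all sequence strings out of a reads argument: a character vector, a
# tibble with a `seq` column, or a paired tibble with seq1/seq2 columns.
read_seqs <- function(reads) {
  if (is.character(reads)) return(reads)
  if (is.data.frame(reads)) {
    cols <- intersect(c("seq", "seq1", "seq2"), names(reads))
    if (length(cols) > 0) return(unlist(reads[cols], use.names = FALSE))
  }
  stop("cannot interpret `reads`: expected sequences or a tibble with ",
       "seq or seq1/seq2 columns", call. = FALSE)
}

# Deterministic per-stage child seeds derived from one global seed, so
# stages re-run independently stay reproducible. Kept below 2^31.
child_seed <- function(seed, stage) {
  as.integer((as.double(seed) %% 2147483647L) * 48271 + stage) %% 2147483647L
}

phred_to_int <- function(qual) utf8ToInt(qual) - 33L
int_to_phred <- function(q) intToUtf8(q + 33L)

# Maximal runs of N in one sequence: tibble(start, end), 0-based half-open.
n_runs <- function(seq) {
  m <- gregexpr("N+", seq)[[1]]
  if (m[1] == -1L) return(tibble(start = integer(), end = integer()))
  tibble(start = as.integer(m) - 1L,
         end = as.integer(m) - 1L + attr(m, "match.length"))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Substitute bases at positions `pos` (1-based) of `seq` with a uniformly
# chosen different base; returns the mutated string.
mutate_bases <- function(seq, pos) {
  if (length(pos) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  alt <- vapply(chars[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  chars[pos] <- alt
  paste(chars, collapse = "")
}
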
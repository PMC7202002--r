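#' Force-trim reads to a fixed length
#'
#' Truncates every read (and its quality string) to the first
#' `keep_length` positions, the remedy for runs that emit an extra cycle
#' (101 bases instead of 100). Reads already at or below the limit are
#' unchanged.
#'
#' @param reads A read tibble with `seq`/`qual` columns, or a paired tibble
#'   with `seq1`/`qual1`/`seq2`/`qual2` (both mates are trimmed).
#' @param keep_length Number of leading positions to keep (>= 1).
#' @return The tibble with trimmed sequences and qualities.
#' @export
force_trim <- function(reads, keep_length) {
  if (keep_length < 1) stop("keep_length must be >= 1")
  for (suffix in c("", "1", "2")) {
    sc <- paste0("seq", suffix); qc <- paste0("qual", suffix)
    if (all(c(sc, qc) %in% names(reads))) {
      reads[[sc]] <- substr(reads[[sc]], 1L, keep_length)
      reads[[qc]] <- substr(reads[[qc]], 1L, keep_length)
    }
  }
  reads
}

#' Quality-trim reads with the Phred (Mott) algorithm
#'
#' Two-sided trimming as in BBDuk's `qtrim=rl`: from each end, the prefix
#' (suffix) maximising the cumulative sum of `q_threshold - q_i` is removed
#' when that maximum is positive, which is equivalent to keeping the
#' contiguous window maximising the sum of `q_i - q_threshold` over cut
#' points at the ends. Reads shorter than `min_length` after trimming are
#' discarded; for paired input the pair is dropped when either mate falls
#' below the threshold.
#'
#' @inheritParams force_trim
#' @param q_threshold Phred quality threshold (BBDuk `trimq`).
#' @param min_length Minimum surviving read length (BBDuk `minlength`).
#' @return The tibble with trimmed reads, surviving rows only.
#' @export
quality_trim <- function(reads, q_threshold = 10, min_length = 51) {
  stopifnot(q_threshold >= 0)
  trim_one <- function(seq, qual) {
    q <- phred_to_int(qual)
    n <- length(q)
    if (n == 0) return(c(1L, 0L))
    deficit <- q_threshold - q
    left_cum <- cumsum(deficit)
    left_cut <- if (max(left_cum) > 0) which.max(left_cum) else 0L
    right_cum <- rev(cumsum(rev(deficit)))
    right_cut <- if (max(right_cum) > 0) n + 1L - which.max(rev(right_cum)) else n + 1L
    # which.max on the reversed cumulative keeps the cut closest to the end
    c(left_cut + 1L, right_cut - 1L)
  }
  apply_trim <- function(seqs, quals) {
    cuts <- t(mapply(trim_one, seqs, quals))
    list(seq = substr(seqs, cuts[, 1], cuts[, 2]),
         qual = substr(quals, cuts[, 1], cuts[, 2]))
  }
  keep <- rep(TRUE, nrow(reads))
  for (suffix in c("", "1", "2")) {
    sc <- paste0("seq", suffix); qc <- paste0("qual", suffix)
    if (all(c(sc, qc) %in% names(reads))) {
      trimmed <- apply_trim(reads[[sc]], reads[[qc]])
      reads[[sc]] <- trimmed$seq
      reads[[qc]] <- trimmed$qual
      keep <- keep & nchar(trimmed$seq) >= min_length
    }
  }
  reads[keep, ]
}

#' GC percentage of unassembled reads
#'
#' `100 * (G + C) / (A + C + G + T)`; N bases are excluded from both the
#' numerator and the denominator. Computing GC from reads rather than the
#' assembly avoids the depletion of large repeat copies in short-read
#' assemblies.
#'
#' @param reads Sequences: a character vector, or a tibble with `seq` or
#'   `seq1`/`seq2` columns.
#' @return GC percentage (scalar).
#' @examples
#' read_gc_percent(c("ACGT", "ANGT"))
#' @export
read_gc_percent <- function(reads) {
  seqs <- read_seqs(reads)
  counts <- colSums(Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs)))
  acgt <- counts[c("A", "C", "G", "T")]
  if (sum(acgt) == 0) stop("no non-N bases in input", call. = FALSE)
  unname(100 * sum(acgt[c("C", "G")]) / sum(acgt))
}

#' Detect simple-sequence-repeat contaminant read pairs
#'
#' Flags read pairs in which both mates are dominated by the same 8 bp or
#' 10 bp simple sequence repeat (SSR) — the signature of the highly
#' abundant contaminant fragments that appear as spikes in per-sequence GC
#' plots. A read is SSR-dominated when a single period-`p` motif (any
#' rotation, either strand) covers at least `dominance` of its length;
#' motifs are canonicalised to the lexicographically smallest rotation of
#' the unit and its reverse complement, so the test is strand- and
#' rotation-invariant.
#'
#' @param pairs A paired-read tibble (`id`, `seq1`, `seq2`).
#' @param periods SSR unit lengths to consider.
#' @param dominance Minimum fraction of the read a motif must cover.
#' @return A tibble of flagged pairs: `id`, `motif` (canonical unit).
#' @export
detect_ssr_contaminants <- function(pairs, periods = c(8L, 10L),
                                    dominance = 0.8) {
  stopifnot(all(periods %in% c(8L, 10L)), dominance > 0, dominance <= 1)
  motif1 <- dominant_ssr_motifs(pairs$seq1, periods, dominance)
  motif2 <- dominant_ssr_motifs(pairs$seq2, periods, dominance)
  flagged <- !is.na(motif1) & !is.na(motif2) & motif1 == motif2
  tibble(id = pairs$id[flagged], motif = motif1[flagged])
}

# Canonical motif of the dominant period-p repeat of each read, or NA.
# Periods are tried in order; the first one reaching dominance wins.
dominant_ssr_motifs <- function(seqs, periods, dominance) {
  out <- rep(NA_character_, length(seqs))
  for (p in periods) {
    todo <- which(is.na(out) & nchar(seqs) >= p)
    if (length(todo) == 0) next
    wins <- lapply(seqs[todo], function(s) {
      n <- nchar(s)
      substring(s, 1:(n - p + 1L), p:n)
    })
    uniq <- unique(unlist(wins, use.names = FALSE))
    canon_uniq <- canonical_rotation(uniq, p)
    for (j in seq_along(todo)) {
      canon <- canon_uniq[match(wins[[j]], uniq)]
      counts <- table(canon)
      best <- names(counts)[which.max(counts)]
      covered <- (max(counts) + p - 1L) / nchar(seqs[todo[j]])
      if (covered >= dominance && !grepl("N", best, fixed = TRUE)) {
        out[todo[j]] <- best
      }
    }
  }
  out
}

# Lexicographic minimum over all rotations of each unit and its reverse
# complement; fully vectorised over units of equal length p.
canonical_rotation <- function(units, p) {
  n <- length(units)
  both <- c(units, revcomp(units))
  doubled <- paste0(both, both)
  rots <- lapply(0:(p - 1L), function(k) substr(doubled, k + 1L, k + p))
  m <- do.call(pmin, rots)
  pmin(m[seq_len(n)], m[n + seq_len(n)])
}

#' Remove read pairs matching contaminant k-mers
#'
#' A pair is removed when either mate contains any length-`k` window
#' within Hamming distance `hdist` of any length-`k` window of a
#' contaminant sequence, on either strand (BBDuk `k`/`hdist` semantics).
#' Non-ACGT characters mismatch everything. Survivors are returned
#' unchanged.
#'
#' @param pairs A paired-read tibble.
#' @param contaminants Contaminant sequences (character vector or
#'   `tibble(name, seq)`).
#' @param k Window length (default 75).
#' @param hdist Maximum Hamming distance (default 1).
#' @return The surviving pairs.
#' @export
filter_reads_by_kmer <- function(pairs, contaminants, k = 75L, hdist = 1L) {
  if (is.data.frame(contaminants)) contaminants <- contaminants$seq
  if (length(contaminants) == 0) return(pairs)
  if (k > max(nchar(c(pairs$seq1, pairs$seq2)))) {
    warning("k exceeds read length; nothing removed")
    return(pairs)
  }
  hit1 <- cpp_kmer_contaminant_match(pairs$seq1, contaminants, k, hdist)
  hit2 <- cpp_kmer_contaminant_match(pairs$seq2, contaminants, k, hdist)
  pairs[!(hit1 | hit2), ]
}

#' Subsample read pairs
#'
#' Keeps each pair independently with probability `rate` (Reformat
#' `samplerate` semantics), deterministically under `seed`.
#'
#' @param pairs A paired-read tibble.
#' @param rate Keep probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The sampled pairs.
#' @export
subsample_pairs <- function(pairs, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  set.seed(child_seed(seed, 5L))
  pairs[runif(nrow(pairs)) < rate, ]
}
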
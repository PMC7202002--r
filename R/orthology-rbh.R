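#' Seeded local alignment with BLASTN-style scoring
#'
#' Smith-Waterman local alignment with affine gaps under the nucleotide
#' scoring scheme `reward`/`penalty`/`gap_open`/`gap_extend` (a gap of
#' length L costs `gap_open + gap_extend * L`), searched on both strands.
#' Genome-sized subjects are first screened with exact `word_size`-mers
#' and aligned within the seeded windows; pairs small enough for full
#' dynamic programming (`query * subject <= dp_limit` cells) are aligned
#' exhaustively, so on such pairs the top hit provably attains the
#' Smith-Waterman optimum. Additional non-overlapping (on the query) HSPs
#' are found by masking and realigning. E-values follow the
#' Karlin-Altschul form `K * m * n * exp(-lambda * S)`; `lambda` and `K`
#' are configuration for the scoring scheme, and hits beyond `e_max` are
#' discarded.
#'
#' @param query,subject Sequences: character scalars or one-row
#'   `tibble(name, seq)`; `subject` may hold several scaffolds.
#' @param reward Match reward (default 2).
#' @param penalty Mismatch penalty, negative (default -3).
#' @param gap_open,gap_extend Affine gap costs (defaults 5 and 2).
#' @param word_size Seed word length for genome-scale subjects.
#' @param e_max Maximum reported E-value (see [evalue_threshold()]).
#' @param lambda,K Karlin-Altschul constants for the scoring scheme.
#' @param min_score Minimum reported raw score.
#' @param max_hits Maximum HSPs per query/subject/strand.
#' @param dp_limit Cell budget below which full DP replaces seeding.
#' @return A hit tibble: `query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length` (query-side bases), `mismatches`, `gap_opens`,
#'   `q_start`, `q_end` (0-based half-open, forward query strand),
#'   `s_start`, `s_end`, `strand`, `score`, `e_value`.
#' @export
local_align <- function(query, subject, reward = 2L, penalty = -3L,
                        gap_open = 5L, gap_extend = 2L, word_size = 11L,
                        e_max = Inf, lambda = 0.625, K = 0.41,
                        min_score = 20L, max_hits = 20L, dp_limit = 4.5e6) {
  q <- as_seq_tbl(query, "query")
  s <- as_seq_tbl(subject, "subject")
  stopifnot(nrow(q) == 1, nrow(s) >= 1, nchar(q$seq) > 0, all(nchar(s$seq) > 0))
  qlen <- nchar(q$seq)
  space <- as.double(qlen) * sum(as.double(nchar(s$seq)))

  one_strand <- function(qseq, sseq, strand) {
    hits <- cpp_local_align(qseq, sseq, reward, abs(penalty), gap_open,
                            gap_extend, word_size, min_score, max_hits,
                            dp_limit)
    hits <- as_tibble(hits)
    hits$strand <- strand
    if (strand == "-" && nrow(hits) > 0) {
      qs <- qlen - hits$q_end
      hits$q_end <- qlen - hits$q_start
      hits$q_start <- qs
    }
    hits
  }
  out <- purrr::map_dfr(seq_len(nrow(s)), function(i) {
    res <- dplyr::bind_rows(
      one_strand(q$seq, s$seq[i], "+"),
      one_strand(revcomp(q$seq), s$seq[i], "-")
    )
    res$subject_id <- s$name[i]
    res
  })
  if (nrow(out) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  percent_identity = numeric(), alignment_length = integer(),
                  mismatches = integer(), gap_opens = integer(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(), strand = character(),
                  score = integer(), e_value = numeric()))
  }
  out |>
    dplyr::mutate(
      query_id = q$name,
      percent_identity = 100 * .data$matches / .data$aln_cols,
      alignment_length = .data$q_end - .data$q_start,
      e_value = K * space * exp(-lambda * .data$score)
    ) |>
    dplyr::filter(.data$e_value <= e_max) |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::select("query_id", "subject_id", "percent_identity",
                  "alignment_length", "mismatches", "gap_opens", "q_start",
                  "q_end", "s_start", "s_end", "strand", "score", "e_value")
}

#' Reciprocal E-value threshold
#'
#' The E-value cutoff used for orthology searches is the reciprocal of the
#' number of query fragments — at most one spurious hit expected across
#' the whole fragment set — reported to two significant figures (e.g.
#' 1/3457 = 0.00029).
#'
#' @param n_fragments Number of fragments searched (>= 1).
#' @return The threshold, 2 significant figures.
#' @export
evalue_threshold <- function(n_fragments) {
  if (n_fragments < 1) stop("n_fragments must be >= 1")
  signif(1 / n_fragments, 2)
}

#' Highest-scoring hit
#'
#' Maximal raw score; ties resolved by greater alignment length, then the
#' smallest `(subject_id, s_start)`.
#'
#' @param hits A hit tibble from [local_align()].
#' @return A one-row tibble.
#' @export
best_hit <- function(hits) {
  if (nrow(hits) == 0) stop("empty hit list", call. = FALSE)
  hits |>
    dplyr::arrange(dplyr::desc(.data$score),
                   dplyr::desc(.data$alignment_length),
                   .data$subject_id, .data$s_start) |>
    dplyr::slice(1)
}

#' Classify a fragment as a reciprocal best hit
#'
#' The forward criterion asks whether the best hit of the lifted
#' counterpart sequence, aligned back onto genome 1, overlaps (by at least
#' 1 bp) the fragment's original coordinates; the reverse criterion asks
#' whether the best hit of the genome-1 fragment on genome 2 overlaps the
#' lifted interval. A fragment meeting both is a reciprocal best hit —
#' the operational orthology test.
#'
#' @param fragment A one-row interval (`chrom`, `start`, `end`) on
#'   genome 1.
#' @param lifted A one-row interval (`chrom`, `start`, `end`) on genome 2.
#' @param best_back Best hit of the lifted sequence on genome 1 (subject
#'   coordinates on genome 1), or `NULL`.
#' @param best_fwd Best hit of the fragment on genome 2, or `NULL`.
#' @return A one-row tibble: `forward_best_overlaps`,
#'   `reverse_best_overlaps`, `is_rbh`.
#' @export
classify_rbh <- function(fragment, lifted, best_back, best_fwd) {
  overlaps <- function(hit, interval) {
    !is.null(hit) && nrow(hit) == 1 &&
      hit$subject_id == interval$chrom &&
      hit$s_start < interval$end && hit$s_end > interval$start
  }
  fwd <- overlaps(best_back, fragment)
  rev <- overlaps(best_fwd, lifted)
  tibble(forward_best_overlaps = fwd, reverse_best_overlaps = rev,
         is_rbh = fwd && rev)
}

#' Remove or trim lower-scoring overlapping hits
#'
#' Processes one fragment pair's hits in descending score order over a set
#' of occupied query positions: a hit nested inside already-occupied
#' positions is removed; a partially overlapping hit is trimmed (on query
#' coordinates) to its unoccupied portion — one row per contiguous
#' surviving segment — with `alignment_length` reduced, identity kept
#' as-is, and subject coordinates adjusted proportionally (flagged
#' `approx_subject`). The output's query intervals are pairwise disjoint,
#' as required by [alignment_summary()].
#'
#' @param hits A hit tibble sharing one query.
#' @return The trimmed hit tibble.
#' @export
trim_overlapping_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score))
  occupied <- rep(FALSE, max(hits$q_end))
  out <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    span <- seq(h$q_start + 1L, h$q_end)     # 1-based positions
    free <- span[!occupied[span]]
    if (length(free) == 0) next
    occupied[span] <- TRUE
    # contiguous surviving segments
    brk <- c(0L, which(diff(free) > 1L), length(free))
    segs <- purrr::map_dfr(seq_len(length(brk) - 1L), function(j) {
      seg <- free[(brk[j] + 1L):brk[j + 1L]]
      piece <- h
      piece$q_start <- seg[1] - 1L
      piece$q_end <- seg[length(seg)]
      piece
    })
    trimmed <- nrow(segs) > 1 ||
      segs$q_end[1] - segs$q_start[1] < h$q_end - h$q_start
    segs$approx_subject <- trimmed
    if (trimmed) {
      scale <- (h$s_end - h$s_start) / (h$q_end - h$q_start)
      segs$s_end <- h$s_start +
        as.integer(round((segs$q_end - h$q_start) * scale))
      segs$s_start <- h$s_start +
        as.integer(round((segs$q_start - h$q_start) * scale))
    }
    segs$alignment_length <- segs$q_end - segs$q_start
    out[[i]] <- segs
  }
  dplyr::bind_rows(out)
}

#' Query coverage and length-weighted identity of an alignment
#'
#' Over the trimmed, query-disjoint hits of one fragment: coverage is the
#' percentage of query positions covered by any hit, and the weighted
#' identity is `sum(length_i * identity_i) / sum(length_i)` — the summary
#' pair used to characterise fragment-to-ortholog similarity.
#'
#' @param hits A trimmed hit tibble (see [trim_overlapping_hits()]).
#' @param query_length Fragment length in bp.
#' @return A one-row tibble: `query_coverage`, `weighted_identity` (both
#'   %; identity is `NA` when there are no hits).
#' @export
alignment_summary <- function(hits, query_length) {
  stopifnot(query_length > 0)
  if (nrow(hits) == 0) {
    return(tibble(query_coverage = 0, weighted_identity = NA_real_))
  }
  covered <- rep(FALSE, query_length)
  for (i in seq_len(nrow(hits))) {
    covered[seq(hits$q_start[i] + 1L, hits$q_end[i])] <- TRUE
  }
  len <- hits$q_end - hits$q_start
  tibble(
    query_coverage = 100 * sum(covered) / query_length,
    weighted_identity = sum(len * hits$percent_identity) / sum(len)
  )
}

#' Read and write 12-column tabular alignment hits
#'
#' Adapter for externally produced BLAST-style tabular output (`qseqid
#' sseqid pident length mismatch gapopen qstart qend sstart send evalue
#' bitscore`, 1-based inclusive coordinates), converted to and from the
#' package's 0-based half-open hit tibbles so external aligners can stand
#' in for [local_align()].
#'
#' @param path File path.
#' @param hits A hit tibble.
#' @return `read_tabular_hits()` returns a hit tibble (with `score` set
#'   from the bitscore column); `write_tabular_hits()` its input,
#'   invisibly.
#' @export
read_tabular_hits <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "e_value", "score")
  raw <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                         progress = FALSE)
  minus <- raw$s_start > raw$s_end
  raw |>
    dplyr::mutate(
      strand = ifelse(minus, "-", "+"),
      q_start = .data$q_start - 1L,
      s_start = ifelse(minus, .data$s_end, .data$s_start) - 1L,
      s_end = ifelse(minus, raw$s_start, .data$s_end)
    )
}

#' @rdname read_tabular_hits
#' @export
write_tabular_hits <- function(hits, path) {
  out <- hits |>
    dplyr::mutate(
      qstart = .data$q_start + 1L,
      sstart = ifelse(.data$strand == "-", .data$s_end, .data$s_start + 1L),
      send = ifelse(.data$strand == "-", .data$s_start + 1L, .data$s_end)
    )
  readr::write_tsv(
    out[, c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "qstart", "q_end", "sstart", "send",
            "e_value", "score")],
    path, col_names = FALSE, progress = FALSE)
  invisible(hits)
}
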
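#' End-to-end enhancer-orthology pipeline on two aligned genomes
#'
#' For each reference fragment (tile): remap its coordinates onto the
#' second genome through the alignment chains (largest span retained when
#' several chains qualify), extract the candidate ortholog sequence, and
#' test the reciprocal-best-hit criteria — the candidate's best local
#' alignment back onto the reference genome must overlap the original
#' fragment, and the fragment's best alignment onto the second genome must
#' overlap the remapped interval. For classified fragments the candidate
#' pair is also aligned directly, hits trimmed of overlaps, and query
#' coverage plus length-weighted identity reported.
#'
#' @param reference,second Genomes as `tibble(name, seq)`.
#' @param tiles BED tibble of fragment intervals on the reference.
#' @param chains Chain tibble mapping reference coordinates onto the
#'   second genome.
#' @param min_match liftOver minimum mapped fraction.
#' @param e_max E-value cutoff for the RBH searches; defaults to the
#'   reciprocal of the number of fragments ([evalue_threshold()]).
#' @param ... Further arguments passed to [local_align()].
#' @return A tibble with one row per tile: remapped coordinates
#'   (`q_name`, `q_start`, `q_end`), `remapped`, `forward_best_overlaps`,
#'   `reverse_best_overlaps`, `is_rbh`, `query_coverage`,
#'   `weighted_identity`.
#' @export
rbh_pipeline <- function(reference, second, tiles, chains, min_match = 0.1,
                         e_max = NULL, ...) {
  reference <- as_seq_tbl(reference, "reference")
  second <- as_seq_tbl(second, "second")
  if (is.null(e_max)) e_max <- evalue_threshold(nrow(tiles))
  lifted <- lift_bed(tiles, chains, min_match = min_match, multiple = TRUE)

  purrr::map_dfr(seq_len(nrow(lifted)), function(i) {
    row <- lifted[i, ]
    base <- tibble(name = row$name, chrom = row$chrom, start = row$start,
                   end = row$end, q_name = row$q_name, q_start = row$q_start,
                   q_end = row$q_end, remapped = row$remapped)
    if (!row$remapped) {
      return(dplyr::bind_cols(base,
        tibble(forward_best_overlaps = NA, reverse_best_overlaps = NA,
               is_rbh = NA, query_coverage = NA_real_,
               weighted_identity = NA_real_)))
    }
    frag_seq <- substr(reference$seq[match(row$chrom, reference$name)],
                       row$start + 1L, row$end)
    cand_seq <- substr(second$seq[match(row$q_name, second$name)],
                       row$q_start + 1L, row$q_end)
    back <- local_align(tibble(name = row$name, seq = cand_seq), reference,
                        e_max = e_max, max_hits = 3L, ...)
    fwd <- local_align(tibble(name = row$name, seq = frag_seq), second,
                       e_max = e_max, max_hits = 3L, ...)
    verdict <- classify_rbh(
      fragment = tibble(chrom = row$chrom, start = row$start, end = row$end),
      lifted = tibble(chrom = row$q_name, start = row$q_start,
                      end = row$q_end),
      best_back = if (nrow(back) > 0) best_hit(back) else NULL,
      best_fwd = if (nrow(fwd) > 0) best_hit(fwd) else NULL
    )
    pair_hits <- local_align(tibble(name = row$name, seq = frag_seq),
                             tibble(name = row$name, seq = cand_seq),
                             e_max = e_max, max_hits = 12L, ...)
    summary <- alignment_summary(trim_overlapping_hits(pair_hits),
                                 nchar(frag_seq))
    dplyr::bind_cols(base, verdict, summary)
  })
}
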
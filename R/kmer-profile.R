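#' Build a canonical k-mer frequency spectrum from reads
#'
#' Counts canonical k-mers (lexicographic minimum of each k-mer and its
#' reverse complement) over all read windows, skipping windows containing
#' N, and tabulates how many distinct k-mers occur at each multiplicity.
#' The spectrum underlies genome-size estimation and the de Bruijn
#' variant/repeat branch frequencies; `k = 41` matches the profiling the
#' downstream sample tables are built on.
#'
#' @param reads Sequences: character vector, read tibble or paired tibble.
#' @param k Odd k-mer length (41 by default; 15-63 recommended).
#' @param keep_kmers Keep the per-k-mer count table as an attribute (needed
#'   by [branch_frequencies()] and [scaffold_signatures()]).
#' @return A `kmer_spectrum` tibble with columns `multiplicity` and
#'   `n_kmers`, and attributes `k`, `total_windows` and (optionally)
#'   `kmer_counts`. The conservation identity
#'   `sum(multiplicity * n_kmers) == total_windows` holds exactly.
#' @examples
#' build_spectrum(c("ACGTACGTACGTACGTAC"), k = 15)
#' @export
build_spectrum <- function(reads, k = 41L, keep_kmers = TRUE) {
  seqs <- read_seqs(reads)
  if (length(seqs) == 0) stop("no reads supplied")
  if (k %% 2L == 0L) warning("even k cannot distinguish palindromic k-mers")
  if (k > max(nchar(seqs))) stop("k exceeds the read length")
  counted <- cpp_count_kmers(seqs, as.integer(k))
  spec <- tibble(count = counted$count) |>
    dplyr::count(.data$count, name = "n_kmers") |>
    dplyr::rename(multiplicity = "count") |>
    dplyr::arrange(.data$multiplicity)
  attr(spec, "k") <- as.integer(k)
  attr(spec, "total_windows") <- counted$windows
  if (keep_kmers) {
    attr(spec, "kmer_counts") <- tibble(kmer = counted$kmer,
                                        count = counted$count)
  }
  class(spec) <- c("kmer_spectrum", class(spec))
  spec
}

# Locate the error trough and coverage mode of a spectrum. The coverage
# mode is the (3-bin moving-median smoothed) argmax over multiplicities
# >= 2 — the error pile sits at multiplicity 1 — and the trough is the
# multiplicity with the fewest distinct k-mers before that peak (the
# first such multiplicity on ties, which lands on 1 for error-free
# spectra that have no error pile at all). The spectrum is not estimable
# when no multiplicities precede the peak or the peak does not rise above
# the trough.
spectrum_trough_mode <- function(spectrum) {
  m <- spectrum$multiplicity
  not_estimable <- list(trough = NA_integer_, mode = NA_integer_)
  smoothed <- stats::runmed(spectrum$n_kmers, 3L, endrule = "keep")
  cand <- which(m >= 2L)
  if (length(cand) == 0) return(not_estimable)
  mi <- cand[which.max(smoothed[cand])]
  before <- which(m < m[mi])
  if (length(before) == 0) return(not_estimable)
  ti <- before[which.min(spectrum$n_kmers[before])]
  if (spectrum$n_kmers[mi] <= spectrum$n_kmers[ti]) {
    return(not_estimable)
  }
  # Refine the integer argmax to a continuous peak position: the
  # count-weighted mean multiplicity within [0.5, 1.5] x argmax (repeat
  # shoulders at >= 2x the peak are excluded). At 30x coverage the raw
  # argmax is quantised to +-1 bin, a ~5% error the refinement removes.
  win <- which(m >= 0.5 * m[mi] & m <= 1.5 * m[mi] & m >= m[ti])
  peak <- sum(as.double(m[win]) * spectrum$n_kmers[win]) /
    sum(as.double(spectrum$n_kmers[win]))
  list(trough = m[ti], mode = m[mi], peak = peak)
}

#' Estimate genome size from a k-mer spectrum
#'
#' Locates the coverage mode (the smoothed spectrum's peak over
#' multiplicities of at least 2) and the error trough (the multiplicity
#' with the fewest distinct k-mers before that peak), then estimates
#' the genome size as the total k-mer instances at or above the trough
#' divided by the refined coverage peak (the count-weighted mean
#' multiplicity around the argmax, which removes the one-bin quantisation
#' of the raw argmax). Spectra without a detectable trough-and-peak
#' structure — coverage too low — are reported as not estimable, with `NA`
#' fields.
#'
#' @param spectrum A `kmer_spectrum` from [build_spectrum()].
#' @return A one-row tibble: `est_genome_size` (bp), `trough`,
#'   `coverage_mode` (integer argmax), `coverage_peak` (refined) and
#'   `estimable`.
#' @export
estimate_genome_size <- function(spectrum) {
  tm <- spectrum_trough_mode(spectrum)
  if (is.na(tm$trough)) {
    return(tibble(est_genome_size = NA_real_, trough = NA_integer_,
                  coverage_mode = NA_integer_, coverage_peak = NA_real_,
                  estimable = FALSE))
  }
  solid <- spectrum[spectrum$multiplicity >= tm$trough, ]
  size <- sum(as.double(solid$multiplicity) * solid$n_kmers) / tm$peak
  tibble(est_genome_size = size, trough = tm$trough,
         coverage_mode = tm$mode, coverage_peak = tm$peak, estimable = TRUE)
}

#' Variant- and repeat-branch frequencies of the read de Bruijn graph
#'
#' Examines every (k-1)-mer vertex of the de Bruijn graph of solid k-mers
#' (multiplicity at or above the spectrum trough) that has two or more
#' solid single-base extensions on a side. The vertex is a repeat branch
#' when the top two extension counts together exceed `c_rep` times the
#' coverage mode (collapsed repeat copies), and a variant branch when the
#' minor/major count ratio is at least `r_min` at sub-repeat coverage
#' (balanced heterozygous alleles). Frequencies are branch vertices over
#' all solid vertices examined, the read-based proxies for repeat content
#' and heterozygosity used throughout the assembly analyses.
#'
#' @param spectrum A `kmer_spectrum` built with `keep_kmers = TRUE`.
#' @param r_min Minimum minor/major ratio for a variant branch.
#' @param c_rep Repeat-coverage multiplier of the coverage mode.
#' @return A one-row tibble: `variant_branch_freq`, `repeat_branch_freq`,
#'   `n_vertices`, `estimable`.
#' @export
branch_frequencies <- function(spectrum, r_min = 0.25, c_rep = 1.75) {
  kmers <- attr(spectrum, "kmer_counts")
  if (is.null(kmers)) {
    stop("spectrum lacks k-mer counts; rebuild with keep_kmers = TRUE",
         call. = FALSE)
  }
  tm <- spectrum_trough_mode(spectrum)
  if (is.na(tm$trough)) {
    return(tibble(variant_branch_freq = NA_real_,
                  repeat_branch_freq = NA_real_,
                  n_vertices = NA_real_, estimable = FALSE))
  }
  solid <- kmers[kmers$count >= tm$trough, ]
  st <- cpp_branch_stats(solid$kmer, solid$count, attr(spectrum, "k"),
                         tm$peak, r_min, c_rep)
  tibble(variant_branch_freq = st$n_variant / st$n_vertices,
         repeat_branch_freq = st$n_repeat / st$n_vertices,
         n_vertices = st$n_vertices, estimable = TRUE)
}

#' Read-derived genome profile
#'
#' One-stop characterisation of a sample from its unassembled reads:
#' genome size from the k-mer spectrum, read GC %, k-mer coverage mode,
#' fold coverage (total read bases over the estimated genome size), and
#' the de Bruijn variant/repeat branch frequencies.
#'
#' @param reads A paired-read tibble (or any input [build_spectrum()]
#'   accepts).
#' @inheritParams build_spectrum
#' @inheritParams branch_frequencies
#' @return A one-row tibble: `est_genome_size`, `gc_percent`,
#'   `coverage_mode`, `coverage`, `variant_branch_freq`,
#'   `repeat_branch_freq`, `estimable`.
#' @export
genome_profile <- function(reads, k = 41L, r_min = 0.25, c_rep = 1.75) {
  spectrum <- build_spectrum(reads, k = k, keep_kmers = TRUE)
  size <- estimate_genome_size(spectrum)
  branches <- branch_frequencies(spectrum, r_min = r_min, c_rep = c_rep)
  total_bases <- sum(nchar(read_seqs(reads)))
  tibble(
    est_genome_size = size$est_genome_size,
    gc_percent = read_gc_percent(reads),
    coverage_mode = size$coverage_mode,
    coverage = total_bases / size$est_genome_size,
    variant_branch_freq = branches$variant_branch_freq,
    repeat_branch_freq = branches$repeat_branch_freq,
    estimable = size$estimable
  )
}
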
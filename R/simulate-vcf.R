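#' Simulate a phased call set from a diploid truth set
#'
#' Emulates the output of a read-based phaser: truth variants receive
#' genotypes, per-allele read depths drawn around `depth`/2 per haplotype,
#' and phase-set ids partitioning the phased variants into blocks whose
#' lengths are (approximately) geometric with mean `phase_block_mean`.
#' Within a block the phase orientation is correct (haplotype A first)
#' except for whole blocks swapped with probability `swap_rate` — the
#' phasing error mode the downstream majority-haplotype scoring has to
#' survive. Phase-set ids follow the VCF convention of the position of the
#' block's first variant.
#'
#' @param truth A `diploid_truth` from [simulate_diploid()].
#' @param depth Mean total read depth per variant site (fold).
#' @param phase_block_mean Mean phase-block length in bp.
#' @param unphased_fraction Fraction of variants left unphased.
#' @param swap_rate Per-block probability of a phase swap.
#' @param seed Integer seed.
#' @return A variant tibble (columns as in [read_phased_vcf()]); the alt
#'   allele of every truth variant lives on haplotype B, so an unswapped
#'   phased genotype is `0|1`.
#' @export
simulate_phased_vcf <- function(truth, depth = 40, phase_block_mean = 10000,
                                unphased_fraction = 0.05, swap_rate = 0,
                                seed = 1L) {
  stopifnot(inherits(truth, "diploid_truth"))
  if (depth <= 0) stop("depth must be positive")
  v <- truth$variants
  empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), kind = character(), a1 = integer(),
                  a2 = integer(), phased = logical(), phase_set = integer(),
                  ad_ref = integer(), ad_alt = integer())
  if (nrow(v) == 0) return(empty)
  set.seed(child_seed(seed, 3L))
  v <- dplyr::arrange(v, .data$chrom, .data$pos)

  gaps <- c(Inf, diff(v$pos))
  new_block <- runif(nrow(v)) < 1 - exp(-gaps / phase_block_mean)
  new_block[1] <- TRUE
  block <- cumsum(new_block)
  phased <- runif(nrow(v)) >= unphased_fraction
  swapped <- (runif(max(block)) < swap_rate)[block]

  # phase-set id: position of the first *phased* variant in the block
  ps <- rep(NA_integer_, nrow(v))
  for (b in unique(block)) {
    in_b <- which(block == b & phased)
    if (length(in_b) > 0) ps[in_b] <- v$pos[in_b[1]]
  }

  a1 <- ifelse(phased & swapped, 1L, 0L)
  a2 <- ifelse(phased & swapped, 0L, 1L)
  tibble(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt, kind = v$kind,
    a1 = a1, a2 = a2, phased = phased, phase_set = ps,
    ad_ref = rpois(nrow(v), depth / 2), ad_alt = rpois(nrow(v), depth / 2)
  )
}
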
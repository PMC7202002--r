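#' Specify a simulated diploid genome
#'
#' Collects the knobs of the diploid genome generator: overall size and GC,
#' interspersed repeat families, heterozygosity (density of variant sites
#' per bp, the quantity a de Bruijn variant-branch frequency estimates),
#' the SNP:indel mix, and a structural-variant rate. Base composition is
#' i.i.d. at the GC target; indel lengths are geometric with the stated
#' mean, and indels of 50 bp or more count as structural variants.
#'
#' @param length Haploid genome length in bp.
#' @param gc_target Target GC fraction in `[0, 1]`.
#' @param repeat_families List of `c(unit_length, copy_number, divergence)`
#'   triplets: each family implants `copy_number` copies of a random
#'   `unit_length`-bp unit, each copy independently diverged from the unit
#'   at the given per-base substitution fraction.
#' @param het_rate Expected heterozygous variant sites per bp.
#' @param snp_indel_ratio Expected ratio of SNPs to indels among variants.
#' @param indel_length_mean Mean indel length in bp (geometric).
#' @param sv_rate Structural variants (indels >= 50 bp) per Mb.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return A `sim_genome_spec` list.
#' @export
sim_genome_spec <- function(length, gc_target = 0.42, repeat_families = list(),
                            het_rate = 0, snp_indel_ratio = 10,
                            indel_length_mean = 3, sv_rate = 0, seed = 1L) {
  stopifnot(length > 0, gc_target >= 0, gc_target <= 1, het_rate >= 0,
            snp_indel_ratio > 0, indel_length_mean >= 1, sv_rate >= 0)
  if (het_rate > 1) stop("het_rate implies more than one variant per bp")
  structure(
    list(length = as.integer(length), gc_target = gc_target,
         repeat_families = repeat_families, het_rate = het_rate,
         snp_indel_ratio = snp_indel_ratio,
         indel_length_mean = indel_length_mean, sv_rate = sv_rate,
         seed = as.integer(seed)),
    class = "sim_genome_spec"
  )
}

#' Simulate a diploid genome with a truth variant set
#'
#' Generates haplotype A (random sequence at the GC target, with the
#' requested repeat families implanted), draws heterozygous variants along
#' it, and constructs haplotype B by applying them, so the two haplotypes
#' differ exactly at the truth set. Variants are emitted VCF-style: SNPs as
#' single-base substitutions, indels anchored on the preceding reference
#' base. Truth variants never overlap.
#'
#' @param spec A [sim_genome_spec()].
#' @return A `diploid_truth` list with elements `haplotypes` (a
#'   `tibble(name, seq)` with rows `hapA` and `hapB`), `variants` (a truth
#'   variant tibble with `chrom`, `pos`, `ref`, `alt`, `kind`; the alt
#'   allele lives on haplotype B), `repeats` (truth placements of implanted
#'   repeat copies, 1-based start / half-open end on haplotype A) and
#'   `spec`.
#' @examples
#' truth <- simulate_diploid(sim_genome_spec(20000, het_rate = 0.002, seed = 7))
#' nrow(truth$variants)
#' @export
simulate_diploid <- function(spec) {
  stopifnot(inherits(spec, "sim_genome_spec"))
  set.seed(child_seed(spec$seed, 1L))
  hap_a <- random_dna(spec$length, spec$gc_target)

  # implant repeat families (non-overlapping placements, rejection sampled)
  occupied <- tibble(start = integer(), end = integer())
  repeat_truth <- list()
  for (fam in spec$repeat_families) {
    unit_len <- as.integer(fam[[1]]); copies <- as.integer(fam[[2]])
    div <- as.numeric(fam[[3]])
    unit <- random_dna(unit_len, spec$gc_target)
    placed <- 0L; tries <- 0L
    while (placed < copies && tries < copies * 50L) {
      tries <- tries + 1L
      start <- sample.int(spec$length - unit_len + 1L, 1L)
      if (any(start < occupied$end + 1L & start + unit_len > occupied$start + 1L)) next
      nmut <- rbinom(1L, unit_len, div)
      copy <- mutate_bases(unit, sample.int(unit_len, nmut))
      substr(hap_a, start, start + unit_len - 1L) <- copy
      occupied <- dplyr::bind_rows(occupied,
                                   tibble(start = start, end = start + unit_len))
      placed <- placed + 1L
      repeat_truth[[length(repeat_truth) + 1L]] <-
        tibble(family = length(repeat_truth) + 1L, unit_length = unit_len,
               start = start, end = start + unit_len)
    }
    if (placed < copies) {
      warning("placed only ", placed, " of ", copies, " repeat copies")
    }
  }

  variants <- draw_truth_variants(hap_a, spec)
  hap_b <- build_haplotype_b(hap_a, variants)
  structure(
    list(haplotypes = tibble(name = c("hapA", "hapB"), seq = c(hap_a, hap_b)),
         variants = variants,
         repeats = dplyr::bind_rows(tibble(family = integer(),
                                           unit_length = integer(),
                                           start = integer(), end = integer()),
                                    repeat_truth),
         spec = spec),
    class = "diploid_truth"
  )
}

# Draw non-overlapping truth variants along haplotype A.
draw_truth_variants <- function(hap_a, spec) {
  len <- nchar(hap_a)
  empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), kind = character())
  n_small <- rbinom(1L, len, spec$het_rate)
  n_sv <- rpois(1L, spec$sv_rate * len / 1e6)
  if (n_small + n_sv == 0) return(empty)

  p_snp <- spec$snp_indel_ratio / (spec$snp_indel_ratio + 1)
  kinds <- c(
    sample(c("SNP", "indel"), n_small, replace = TRUE,
           prob = c(p_snp, 1 - p_snp)),
    rep("SV", n_sv)
  )
  # anchored indels need pos >= 2 and room for the deleted span
  pos <- sort(sample(seq(2L, max(2L, len - 600L)), length(kinds)))
  kinds <- sample(kinds)  # decouple kind from position rank

  out <- vector("list", length(pos))
  last_end <- 0L
  for (i in seq_along(pos)) {
    p <- pos[i]
    if (p <= last_end + 1L) next
    base <- substr(hap_a, p, p)
    if (kinds[i] == "SNP") {
      out[[i]] <- tibble(chrom = "chr1", pos = p, ref = base,
                         alt = sample(setdiff(c("A", "C", "G", "T"), base), 1L),
                         kind = "SNP")
      last_end <- p
    } else {
      ins_len <- if (kinds[i] == "SV") 50L + rgeom(1L, 1 / 150) else
        1L + rgeom(1L, 1 / spec$indel_length_mean)
      if (runif(1) < 0.5) {  # insertion
        out[[i]] <- tibble(chrom = "chr1", pos = p, ref = base,
                           alt = paste0(base, random_dna(ins_len, spec$gc_target)),
                           kind = if (ins_len >= 50L) "SV" else "INS")
        last_end <- p
      } else {               # deletion
        del_len <- ins_len
        if (p + del_len > nchar(hap_a)) next
        out[[i]] <- tibble(chrom = "chr1", pos = p,
                           ref = substr(hap_a, p, p + del_len),
                           alt = base,
                           kind = if (del_len >= 50L) "SV" else "DEL")
        last_end <- p + del_len
      }
    }
  }
  dplyr::bind_rows(empty, purrr::compact(out))
}

# Independent (non-apply_variants) construction of haplotype B, so the
# generator round trip is a real invariant rather than a tautology.
build_haplotype_b <- function(hap_a, variants) {
  if (nrow(variants) == 0) return(hap_a)
  v <- dplyr::arrange(variants, .data$pos)
  pieces <- character(2L * nrow(v) + 1L)
  cursor <- 1L
  for (i in seq_len(nrow(v))) {
    pieces[2L * i - 1L] <- substr(hap_a, cursor, v$pos[i] - 1L)
    pieces[2L * i] <- v$alt[i]
    cursor <- v$pos[i] + nchar(v$ref[i])
  }
  pieces[2L * nrow(v) + 1L] <- substr(hap_a, cursor, nchar(hap_a))
  paste(pieces, collapse = "")
}
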
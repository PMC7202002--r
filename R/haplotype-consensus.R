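#' Classify variant kind from its alleles
#'
#' SNP for equal-length single-base alleles, INS/DEL for length changes,
#' SV for indels whose larger allele reaches `sv_min` bp or symbolic
#' (`<...>`) alts.
#'
#' @param ref,alt Reference and alternate allele strings.
#' @param sv_min Structural-variant size threshold in bp.
#' @return Character vector of `"SNP"`, `"INS"`, `"DEL"`, `"SV"`.
#' @export
variant_kind <- function(ref, alt, sv_min = 50L) {
  kind <- dplyr::case_when(
    grepl("^<", alt) ~ "SV",
    pmax(nchar(ref), nchar(alt)) >= sv_min ~ "SV",
    nchar(alt) > nchar(ref) ~ "INS",
    nchar(alt) < nchar(ref) ~ "DEL",
    .default = "SNP"
  )
  kind
}

#' Resolve overlapping variants
#'
#' Highly heterozygous samples yield overlapping calls — variants sharing
#' a start position, or a large deletion overlapping SNPs and smaller
#' indels — which derail read-based phasing. Within each connected cluster
#' of variants whose reference spans intersect, exactly one is retained:
#' the structural variant if one is present (two SVs: the greater alt
#' depth, then the longer reference span), otherwise the variant with the
#' greatest supporting alt read depth.
#'
#' @param variants A variant tibble (see [read_phased_vcf()]).
#' @return The filtered variant tibble, sorted by position, with no
#'   intersecting reference spans.
#' @export
resolve_overlaps <- function(variants) {
  if (nrow(variants) == 0) return(variants)
  v <- dplyr::arrange(variants, .data$chrom, .data$pos)
  v <- dplyr::group_by(v, .data$chrom)
  v <- dplyr::mutate(v,
    span_end = .data$pos + nchar(.data$ref),  # half-open on 1-based pos
    cluster = cumsum(.data$pos >= dplyr::lag(cummax(.data$span_end),
                                             default = 0L))
  )
  v <- dplyr::group_by(v, .data$chrom, .data$cluster)
  picked <- dplyr::group_modify(v, function(g, key) {
    if (nrow(g) == 1) return(g)
    sv <- g[g$kind == "SV", ]
    pool <- if (nrow(sv) > 0) sv else g
    pool[order(-pool$ad_alt, -nchar(pool$ref))[1], ]
  })
  dplyr::ungroup(picked) |>
    dplyr::select(-"span_end", -"cluster") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Score phase sets and call majority haplotypes
#'
#' For each phase set, sums the read depth of the allele carried on each
#' haplotype over all its variants, weighting indels (and SVs) half as
#' much as SNPs — indel read counts are less reliable because of alignment
#' ambiguity. The haplotype with the greater weighted cumulative count is
#' the majority haplotype; ties go to haplotype A (the first allele of the
#' genotype ordering).
#'
#' @param variants A variant tibble; only phased rows (with a `phase_set`)
#'   are scored.
#' @param indel_weight Weight of indel/SV read counts relative to SNPs.
#' @return A tibble: `chrom`, `phase_set`, `score_a`, `score_b`,
#'   `majority` (`"A"`/`"B"`).
#' @examples
#' v <- tibble::tibble(chrom = "c", pos = c(10L, 20L, 30L),
#'   ref = c("A", "A", "AT"), alt = c("G", "C", "A"),
#'   kind = c("SNP", "SNP", "DEL"), a1 = c(1L, 1L, 0L), a2 = c(0L, 0L, 1L),
#'   phased = TRUE, phase_set = 10L,
#'   ad_ref = c(5L, 6L, 4L), ad_alt = c(12L, 6L, 10L))
#' score_phase_sets(v)
#' @export
score_phase_sets <- function(variants, indel_weight = 0.5) {
  phased <- variants[variants$phased & !is.na(variants$phase_set), ]
  if (nrow(phased) == 0) {
    return(tibble(chrom = character(), phase_set = integer(),
                  score_a = numeric(), score_b = numeric(),
                  majority = character()))
  }
  missing_ad <- is.na(phased$ad_ref) | is.na(phased$ad_alt)
  if (any(missing_ad)) {
    warning(sum(missing_ad), " phased variant(s) without allele depths ",
            "contribute 0")
  }
  phased |>
    dplyr::mutate(
      w = ifelse(.data$kind == "SNP", 1, indel_weight),
      depth_a = dplyr::coalesce(ifelse(.data$a1 == 1L, .data$ad_alt,
                                       .data$ad_ref), 0L),
      depth_b = dplyr::coalesce(ifelse(.data$a2 == 1L, .data$ad_alt,
                                       .data$ad_ref), 0L)
    ) |>
    dplyr::group_by(.data$chrom, .data$phase_set) |>
    dplyr::summarise(score_a = sum(.data$w * .data$depth_a),
                     score_b = sum(.data$w * .data$depth_b),
                     .groups = "drop") |>
    dplyr::mutate(majority = ifelse(.data$score_a >= .data$score_b, "A", "B"))
}

#' Select the consensus variant set
#'
#' Applies the majority rules that turn a phased call set into one
#' conflict-free consensus: a phased variant is retained when the alt
#' allele lies on its phase set's majority haplotype (and dropped when the
#' majority haplotype carries the reference); an unphased variant is
#' retained when the alt read depth exceeds the reference depth. Overlaps
#' must already be resolved.
#'
#' @param variants A variant tibble.
#' @param indel_weight Passed to [score_phase_sets()].
#' @return The retained variants, to be applied with [apply_variants()].
#' @export
select_consensus_variants <- function(variants, indel_weight = 0.5) {
  if (nrow(variants) == 0) return(variants)
  scores <- score_phase_sets(variants, indel_weight)
  v <- dplyr::left_join(variants,
                        scores[, c("chrom", "phase_set", "majority")],
                        by = c("chrom", "phase_set"))
  keep_phased <- v$phased & !is.na(v$phase_set) &
    ifelse(v$majority == "A", v$a1, v$a2) == 1L
  keep_unphased <- (!v$phased | is.na(v$phase_set)) & v$ad_alt > v$ad_ref
  out <- v[dplyr::coalesce(keep_phased, FALSE) |
             dplyr::coalesce(keep_unphased, FALSE), ]
  dplyr::select(out, -"majority")
}

#' Apply variants to an assembly
#'
#' Produces the consensus ("phased") assembly by substituting each
#' retained variant's alt allele into its scaffold, handling the
#' coordinate shifts of VCF-style anchored insertions and deletions.
#' Variants must be sorted and non-overlapping; a reference-allele
#' mismatch against the assembly is a hard error naming the offending
#' `chrom:pos`.
#'
#' @param assembly An assembly `tibble(name, seq)`.
#' @param variants Retained variants from [select_consensus_variants()]
#'   (or any non-overlapping variant tibble).
#' @return The consensus assembly tibble.
#' @examples
#' apply_variants(tibble::tibble(name = "c", seq = "ACGT"),
#'   tibble::tibble(chrom = "c", pos = 2L, ref = "CG", alt = "C"))
#' @export
apply_variants <- function(assembly, variants) {
  assembly <- as_seq_tbl(assembly, "assembly")
  if (nrow(variants) == 0) return(assembly)
  by_chrom <- split(variants, variants$chrom)
  for (chrom in names(by_chrom)) {
    i <- match(chrom, assembly$name)
    if (is.na(i)) stop("variant on unknown sequence ", chrom, call. = FALSE)
    v <- dplyr::arrange(by_chrom[[chrom]], .data$pos)
    ends <- v$pos + nchar(v$ref) - 1L
    if (any(v$pos[-1] <= ends[-length(ends)])) {
      stop("overlapping variants on ", chrom, call. = FALSE)
    }
    seq <- assembly$seq[i]
    found <- substring(seq, v$pos, ends)
    bad <- which(found != v$ref)
    if (length(bad) > 0) {
      stop("reference mismatch at ", chrom, ":", v$pos[bad[1]],
           " (expected ", v$ref[bad[1]], ", found ", found[bad[1]], ")",
           call. = FALSE)
    }
    pieces <- character(2L * nrow(v) + 1L)
    cursor <- 1L
    for (j in seq_len(nrow(v))) {
      pieces[2L * j - 1L] <- substr(seq, cursor, v$pos[j] - 1L)
      pieces[2L * j] <- v$alt[j]
      cursor <- ends[j] + 1L
    }
    pieces[2L * nrow(v) + 1L] <- substr(seq, cursor, nchar(seq))
    assembly$seq[i] <- paste(pieces, collapse = "")
  }
  assembly
}
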
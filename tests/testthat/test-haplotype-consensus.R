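mk_var <- function(pos, ref, alt, ad_ref = 10L, ad_alt = 10L, a1 = 0L,
                   a2 = 1L, phased = TRUE, phase_set = 1L, chrom = "c1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 kind = variant_kind(ref, alt), a1 = a1, a2 = a2,
                 phased = phased,
                 phase_set = if (phased) as.integer(phase_set) else NA_integer_,
                 ad_ref = as.integer(ad_ref), ad_alt = as.integer(ad_alt))
}

test_that("variant kinds follow the SV size convention", {
  expect_equal(variant_kind("A", "G"), "SNP")
  expect_equal(variant_kind("A", "ACGT"), "INS")
  expect_equal(variant_kind("ACGT", "A"), "DEL")
  expect_equal(variant_kind("A", paste0("A", strrep("T", 49))), "SV")
  expect_equal(variant_kind(strrep("A", 50), "A"), "SV")
  expect_equal(variant_kind("A", "<DEL>"), "SV")
})

test_that("overlap resolution keeps the SV, else the deepest variant", {
  del <- mk_var(80, strrep("A", 51), "A", ad_alt = 3)     # spans 80..130
  snp <- mk_var(100, "A", "G", ad_alt = 8)
  out <- resolve_overlaps(dplyr::bind_rows(snp, del))
  expect_equal(out$kind, "SV")

  same_pos <- dplyr::bind_rows(mk_var(100, "A", "G", ad_alt = 10),
                               mk_var(100, "A", "T", ad_alt = 3))
  out2 <- resolve_overlaps(same_pos)
  expect_equal(out2$alt, "G")

  apart <- dplyr::bind_rows(mk_var(100, "A", "G"), mk_var(200, "C", "T"))
  expect_equal(nrow(resolve_overlaps(apart)), 2)
})

test_that("resolved variants never intersect (interval-scan property)", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    vars <- purrr::map_dfr(seq_len(n), function(i) {
      pos <- sample(1:500, 1)
      len <- sample(c(1, 1, 1, sample(2:60, 1)), 1)
      mk_var(pos, strrep("A", len), "A",
             ad_alt = sample(1:30, 1))
    })
    vars$alt[nchar(vars$ref) == 1] <- "G"
    vars$kind <- variant_kind(vars$ref, vars$alt)
    out <- resolve_overlaps(vars)
    out <- dplyr::arrange(out, pos)
    ends <- out$pos + nchar(out$ref)
    if (nrow(out) > 1) {
      expect_true(all(out$pos[-1] >= ends[-nrow(out)]))
    }
  }
})

test_that("phase-set scoring applies the half indel weight", {
  vars <- dplyr::bind_rows(
    mk_var(10, "A", "G", ad_alt = 12, ad_ref = 9, a1 = 1L, a2 = 0L),
    mk_var(20, "A", "G", ad_alt = 6, ad_ref = 0, a1 = 1L, a2 = 0L),
    mk_var(30, "AT", "A", ad_alt = 4, ad_ref = 10, a1 = 1L, a2 = 0L)
  )
  # haplotype A carries the alts: score_A = 12 + 6 + 0.5*4 = 20
  # haplotype B carries the refs: score_B = 9 + 0 + 0.5*10 = 14
  sc <- score_phase_sets(vars)
  expect_equal(sc$score_a, 20)
  expect_equal(sc$score_b, 14)
  expect_equal(sc$majority, "A")

  single <- mk_var(5, "A", "G", ad_ref = 0, ad_alt = 7)   # alt on B
  expect_equal(score_phase_sets(single)$majority, "B")
  # tie goes to haplotype A
  tie <- mk_var(5, "A", "G", ad_ref = 5, ad_alt = 5)
  expect_equal(score_phase_sets(tie)$majority, "A")
})

test_that("phase-set majorities agree with a direct weighted-sum oracle", {
  set.seed(62)
  vars <- purrr::map_dfr(1:200, function(i) {
    kind_roll <- runif(1)
    ref <- if (kind_roll < 0.7) "A" else strrep("A", sample(2:5, 1))
    alt <- if (kind_roll < 0.7) "G" else "A"
    swap <- runif(1) < 0.5
    mk_var(i * 10, ref, alt, ad_ref = rpois(1, 10), ad_alt = rpois(1, 10),
           a1 = if (swap) 1L else 0L, a2 = if (swap) 0L else 1L,
           phase_set = sample(1:40, 1))
  })
  got <- score_phase_sets(vars)
  for (ps in unique(vars$phase_set)) {
    g <- vars[vars$phase_set == ps, ]
    w <- ifelse(g$kind == "SNP", 1, 0.5)
    sa <- sum(w * ifelse(g$a1 == 1, g$ad_alt, g$ad_ref))
    sb <- sum(w * ifelse(g$a2 == 1, g$ad_alt, g$ad_ref))
    expect_equal(got$majority[got$phase_set == ps],
                 if (sa >= sb) "A" else "B")
  }
})

test_that("consensus selection keeps majority alleles only", {
  # phase set where A is the majority, variant with alt on A -> retained
  vars <- dplyr::bind_rows(
    mk_var(10, "A", "G", ad_alt = 20, a1 = 1L, a2 = 0L),
    mk_var(20, "C", "T", ad_alt = 2, ad_ref = 2, a1 = 0L, a2 = 1L)
  )
  kept <- select_consensus_variants(vars)
  expect_equal(kept$pos, 10L)

  unphased_keep <- mk_var(30, "A", "G", ad_ref = 12, ad_alt = 20,
                          phased = FALSE)
  unphased_drop <- mk_var(40, "A", "G", ad_ref = 20, ad_alt = 12,
                          phased = FALSE)
  out <- select_consensus_variants(dplyr::bind_rows(unphased_keep,
                                                    unphased_drop))
  expect_equal(out$pos, 30L)
})

test_that("apply_variants handles SNPs, anchored indels and bad refs", {
  asm <- tibble::tibble(name = "c1", seq = "ACGT")
  expect_equal(apply_variants(asm, mk_var(2, "C", "T"))$seq, "ATGT")
  expect_equal(apply_variants(asm, mk_var(2, "CG", "C"))$seq, "ACT")
  expect_equal(apply_variants(asm, mk_var(2, "C", "CAA"))$seq, "ACAAGT")
  expect_error(apply_variants(asm, mk_var(2, "G", "T")), "c1:2")
  # output alphabet stays within ACGTN
  out <- apply_variants(asm, mk_var(3, "G", "A"))
  expect_false(grepl("[^ACGTN]", out$seq))
})

test_that("phased VCFs round-trip through disk", {
  truth <- simulate_diploid(sim_genome_spec(30000, het_rate = 0.002, seed = 63))
  vcf <- simulate_phased_vcf(truth, depth = 30, unphased_fraction = 0.2,
                             seed = 64)
  path <- tempfile(fileext = ".vcf")
  write_phased_vcf(vcf, path)
  back <- read_phased_vcf(path)
  expect_equal(nrow(back), nrow(vcf))
  for (col in c("chrom", "pos", "ref", "alt", "kind", "a1", "a2", "phased",
                "phase_set", "ad_ref", "ad_alt")) {
    expect_equal(back[[col]], vcf[[col]], label = col)
  }
})
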
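test_that("zero-rate spec yields identical haplotypes and no variants", {
  truth <- simulate_diploid(sim_genome_spec(20000, het_rate = 0, seed = 3))
  expect_identical(truth$haplotypes$seq[1], truth$haplotypes$seq[2])
  expect_equal(nrow(truth$variants), 0)
})

test_that("truth variants realise the requested density and SNP:indel mix", {
  spec <- sim_genome_spec(100000, het_rate = 0.002, snp_indel_ratio = 10,
                          seed = 1)
  truth <- simulate_diploid(spec)
  v <- truth$variants
  n_snp <- sum(v$kind == "SNP")
  n_indel <- sum(v$kind %in% c("INS", "DEL"))
  # 200 expected sites, +-20%
  expect_gt(nrow(v), 160)
  expect_lt(nrow(v), 240)
  # ratio 10 within binomial sampling error (~18 indels, sd ~4)
  expect_gt(n_snp / n_indel, 5)
  expect_lt(n_snp / n_indel, 20)
  # realised GC within 2 points of target
  gc <- read_gc_percent(truth$haplotypes$seq[1])
  expect_lt(abs(gc - 42), 2)
})

test_that("applying the truth variants reconstructs haplotype B exactly", {
  truth <- simulate_diploid(sim_genome_spec(50000, het_rate = 0.003,
                                            sv_rate = 100, seed = 5))
  expect_gt(sum(truth$variants$kind == "SV"), 0)
  hap_a <- tibble::tibble(name = "chr1", seq = truth$haplotypes$seq[1])
  rebuilt <- apply_variants(hap_a, truth$variants)
  expect_identical(rebuilt$seq, truth$haplotypes$seq[2])
})

test_that("repeat families implant divergent high-identity copies", {
  truth <- simulate_diploid(sim_genome_spec(
    50000, repeat_families = list(c(500, 20, 0.01)), seed = 7))
  genome <- truth$haplotypes$seq[1]
  expect_equal(nrow(truth$repeats), 20)
  # the sequences at the truth placements are pairwise near-identical:
  # two copies each 1% diverged from the unit sit at ~98% identity
  copies <- substring(genome, truth$repeats$start, truth$repeats$end - 1L)
  expect_true(all(nchar(copies) == 500))
  ident <- function(a, b) mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  pairs <- utils::combn(seq_len(nrow(truth$repeats)), 2)
  ids <- apply(pairs, 2, function(p) ident(copies[p[1]], copies[p[2]]))
  expect_gte(sum(ids >= 0.95), 20)
  expect_gt(mean(ids), 0.96)
  # and the repeat signal is visible in the genome's own k-mer spectrum
  spec <- build_spectrum(genome, k = 41)
  kmers <- attr(spec, "kmer_counts")
  expect_gt(sum(kmers$count >= 15), 100)
})

test_that("identical specs and seeds are byte-identical on disk", {
  gen <- function() {
    truth <- simulate_diploid(sim_genome_spec(10000, het_rate = 0.005, seed = 9))
    reads <- simulate_reads(truth, sim_read_spec(coverage = 5, seed = 9))
    vcf <- simulate_phased_vcf(truth, seed = 9)
    sim <- simulate_ortholog_tiles(4, 300, 0.9, scaffold_shuffle = TRUE,
                                   seed = 9)
    dir <- tempfile("simout")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    write_fasta(truth$haplotypes, file.path(dir, "hap.fa"))
    write_fastq_pairs(reads, file.path(dir, "r1.fq"), file.path(dir, "r2.fq"))
    write_phased_vcf(vcf, file.path(dir, "calls.vcf"))
    write_chain(sim$chains, file.path(dir, "truth.chain"))
    write_bed(sim$tiles_ref, file.path(dir, "tiles.bed"))
    lapply(list.files(dir, full.names = TRUE), readLines)
  }
  expect_identical(gen(), gen())
})

test_that("simulated reads hit coverage, pairing and error-rate targets", {
  truth <- simulate_diploid(sim_genome_spec(50000, het_rate = 0, seed = 11))
  reads <- simulate_reads(truth, sim_read_spec(coverage = 30, error_rate = 0,
                                               seed = 11))
  total <- sum(nchar(reads$seq1)) + sum(nchar(reads$seq2))
  expect_gt(total, 0.95 * 30 * 50000)
  expect_lt(total, 1.05 * 30 * 50000)
  # error-free reads are exact substrings at their truth coordinates
  genome <- truth$haplotypes$seq[1]
  idx <- sample(nrow(reads), 50)
  expect_true(all(
    reads$seq1[idx] == substring(genome, reads$frag_start[idx],
                                 reads$frag_start[idx] + 99L)))
  expect_true(all(
    reads$seq2[idx] == rc_chr(substring(genome, reads$frag_end[idx] - 99L,
                                        reads$frag_end[idx]))))
  # both haplotypes sampled roughly evenly
  expect_gt(mean(reads$hap == "hapA"), 0.45)
  expect_lt(mean(reads$hap == "hapA"), 0.55)

  noisy <- simulate_reads(truth, sim_read_spec(coverage = 10,
                                               error_rate = 0.01, seed = 12))
  mism <- mapply(function(r, s, e) {
    truth_r1 <- substring(genome, s, s + 99L)
    mean(strsplit(r, "")[[1]] != strsplit(truth_r1, "")[[1]])
  }, noisy$seq1, noisy$frag_start, noisy$frag_end)
  expect_lt(abs(mean(mism) - 0.01), 0.002)
})

test_that("phased call sets honour phasing knobs and depth", {
  truth <- simulate_diploid(sim_genome_spec(50000, het_rate = 0.002, seed = 13))
  none <- simulate_phased_vcf(truth, unphased_fraction = 1, seed = 13)
  expect_true(all(is.na(none$phase_set)))
  expect_true(all(!none$phased))

  one_block <- simulate_phased_vcf(truth, phase_block_mean = 1e9,
                                   unphased_fraction = 0, swap_rate = 0,
                                   seed = 13)
  expect_equal(dplyr::n_distinct(one_block$phase_set), 1)
  expect_true(all(one_block$a1 == 0L & one_block$a2 == 1L))

  d40 <- simulate_phased_vcf(truth, depth = 40, seed = 14)
  expect_lt(abs(mean(d40$ad_ref + d40$ad_alt) - 40), 3)
})

test_that("ortholog tiles realise the divergence target and truth chain", {
  sim <- simulate_ortholog_tiles(50, 2000, 0.75, scaffold_shuffle = FALSE,
                                 seed = 15)
  ident <- mapply(function(s, e) {
    a <- strsplit(substr(sim$reference$seq, s + 1, e), "")[[1]]
    b <- strsplit(substr(sim$diverged$seq, s + 1, e), "")[[1]]
    mean(a == b)
  }, sim$tiles_ref$start, sim$tiles_ref$end)
  expect_gt(mean(ident), 0.72)
  expect_lt(mean(ident), 0.78)

  perfect <- simulate_ortholog_tiles(5, 400, 1, scaffold_shuffle = FALSE,
                                     seed = 16)
  expect_identical(perfect$reference$seq, perfect$diverged$seq)
  expect_equal(nrow(perfect$chains), 1)
  expect_equal(nrow(perfect$chains$blocks[[1]]), 1)

  shuffled <- simulate_ortholog_tiles(8, 400, 1, scaffold_shuffle = TRUE,
                                      seed = 17, n_pieces = 4,
                                      n_inversions = 1)
  expect_equal(sum(shuffled$chains$q_strand == "-"), 1)
  # lift round trip: truth tiles project exactly through the truth chain
  lifted <- lift_bed(shuffled$tiles_ref, shuffled$chains)
  expect_true(all(lifted$remapped))
  expect_equal(lifted$q_name, shuffled$tiles_div$chrom)
  expect_equal(lifted$q_start, shuffled$tiles_div$start)
  expect_equal(lifted$q_end, shuffled$tiles_div$end)
  # diverged tile sequences match the reference tiles (identity 1)
  div_seq <- shuffled$diverged$seq[match(shuffled$tiles_div$chrom,
                                         shuffled$diverged$name)]
  tile_div <- substring(div_seq, shuffled$tiles_div$start + 1,
                        shuffled$tiles_div$end)
  tile_div <- ifelse(shuffled$tiles_div$strand == "-", rc_chr(tile_div),
                     tile_div)
  tile_ref <- substring(shuffled$reference$seq, shuffled$tiles_ref$start + 1,
                        shuffled$tiles_ref$end)
  expect_identical(tile_div, tile_ref)
})
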
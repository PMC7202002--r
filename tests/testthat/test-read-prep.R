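mk_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  tibble::tibble(id = paste0("r", seq_along(seqs)), seq = seqs, qual = quals)
}

test_that("force_trim keeps the leading positions and handles short reads", {
  r101 <- mk_reads(random_seq(101))
  out <- force_trim(r101, 100)
  expect_equal(nchar(out$seq), 100)
  expect_identical(out$seq, substr(r101$seq, 1, 100))
  expect_identical(out$qual, substr(r101$qual, 1, 100))

  r80 <- mk_reads(random_seq(80))
  expect_identical(force_trim(r80, 100), r80)
  empty <- mk_reads("")
  expect_identical(force_trim(empty, 100)$seq, "")
  expect_error(force_trim(r80, 0), "keep_length")
})

test_that("quality_trim implements two-sided Phred trimming with a floor", {
  q <- function(v) intToUtf8(v + 33)
  good <- mk_reads(random_seq(60), q(rep(40, 60)))
  expect_identical(quality_trim(good, 10, 51), good)

  bad <- mk_reads(random_seq(60), q(rep(2, 60)))
  expect_equal(nrow(quality_trim(bad, 10, 51)), 0)

  mixed <- mk_reads(random_seq(63), q(c(2, 2, rep(40, 60), 2)))
  out <- quality_trim(mixed, 10, 51)
  expect_equal(nchar(out$seq), 60)
  expect_identical(out$seq, substr(mixed$seq, 3, 62))
})

test_that("quality_trim matches the best-window oracle on end-degraded reads", {
  set.seed(42)
  q <- function(v) intToUtf8(v + 33)
  for (i in 1:50) {
    core <- sample(20:60, 1)
    left <- sample(0:10, 1)
    right <- sample(0:10, 1)
    quals <- c(sample(0:8, left, replace = TRUE),
               sample(12:40, core, replace = TRUE),
               sample(0:8, right, replace = TRUE))
    r <- mk_reads(random_seq(length(quals)), q(quals))
    out <- quality_trim(r, 10, 1)
    # oracle: the window maximising sum(q - threshold) over all cut pairs
    best <- -Inf; ba <- 1; bz <- 0
    for (a in seq_along(quals)) for (z in a:length(quals)) {
      s <- sum(quals[a:z] - 10)
      if (s > best) { best <- s; ba <- a; bz <- z }
    }
    expect_identical(out$seq, substr(r$seq, ba, bz))
    # never longer than input, always contiguous
    expect_true(grepl(out$seq, r$seq, fixed = TRUE))
  }
})

test_that("read GC excludes Ns from both numerator and denominator", {
  expect_equal(read_gc_percent("GGCC"), 100)
  expect_equal(read_gc_percent("ATAT"), 0)
  expect_equal(read_gc_percent(c("ACGT", "ANGT")), 100 * 3 / 7)
  expect_error(read_gc_percent("NNN"), "non-N")
})

test_that("SSR pairs are flagged only when both mates share the motif", {
  pure <- substr(strrep("ACGTACGT", 13), 1, 100)
  rnd <- random_seq(100)
  pairs <- tibble::tibble(id = c("both", "one"),
                          seq1 = c(pure, pure),
                          seq2 = c(pure, rnd))
  flagged <- detect_ssr_contaminants(pairs)
  expect_identical(flagged$id, "both")
  expect_identical(flagged$motif, "ACGTACGT")
})

test_that("SSR detection is strand- and rotation-invariant", {
  unit <- "ACGGTCAT"
  rot <- paste0(substr(unit, 4, 8), substr(unit, 1, 3))
  pure1 <- substr(strrep(unit, 14), 1, 100)
  pure2 <- substr(strrep(rot, 14), 1, 100)
  fwd <- tibble::tibble(id = "p", seq1 = pure1, seq2 = pure2)
  rev <- dplyr::mutate(fwd, seq1 = rc_chr(seq1), seq2 = rc_chr(seq2))
  f1 <- detect_ssr_contaminants(fwd)
  f2 <- detect_ssr_contaminants(rev)
  expect_equal(nrow(f1), 1)
  expect_identical(f1$motif, f2$motif)
})

test_that("random read pairs are not flagged as SSRs", {
  set.seed(7)
  pairs <- tibble::tibble(
    id = paste0("p", 1:300),
    seq1 = replicate(300, random_seq(100)),
    seq2 = replicate(300, random_seq(100))
  )
  expect_equal(nrow(detect_ssr_contaminants(pairs)), 0)
})

test_that("k-mer filtering removes pairs within the Hamming budget", {
  set.seed(8)
  contam <- random_seq(200)
  exact <- substr(contam, 50, 124)                    # embedded 75-mer
  one_mm <- exact; substr(one_mm, 30, 30) <-
    setdiff(c("A", "C", "G", "T"), substr(exact, 30, 30))[1]
  two_mm <- one_mm; substr(two_mm, 60, 60) <-
    setdiff(c("A", "C", "G", "T"), substr(one_mm, 60, 60))[1]
  pad <- function(core) paste0(random_seq(10), core, random_seq(15))
  pairs <- tibble::tibble(
    id = c("exact", "one", "two", "none"),
    seq1 = c(pad(exact), pad(one_mm), pad(two_mm), random_seq(100)),
    seq2 = replicate(4, random_seq(100))
  )
  out <- filter_reads_by_kmer(pairs, contam, k = 75, hdist = 1)
  expect_setequal(out$id, c("two", "none"))
  expect_identical(filter_reads_by_kmer(pairs, character(0)), pairs)
  short <- tibble::tibble(id = "s", seq1 = random_seq(50), seq2 = random_seq(50))
  expect_warning(kept <- filter_reads_by_kmer(short, contam, k = 75),
                 "exceeds")
  expect_identical(kept, short)
})

test_that("k-mer filtering agrees with the exhaustive Hamming oracle", {
  set.seed(9)
  contams <- replicate(2, random_seq(60))
  reads <- character(30)
  for (i in 1:30) {
    reads[i] <- if (i %% 3 == 0) {
      mutate_copy(paste0(random_seq(5), substr(contams[1], 10, 49),
                         random_seq(5)), 0.03)
    } else {
      random_seq(50)
    }
  }
  pairs <- tibble::tibble(id = paste0("p", 1:15),
                          seq1 = reads[1:15], seq2 = reads[16:30])
  for (hdist in 0:2) {
    got <- filter_reads_by_kmer(pairs, contams, k = 40, hdist = hdist)
    oracle_hit <- vapply(seq_len(nrow(pairs)), function(i) {
      kmer_match_oracle(pairs$seq1[i], contams, 40, hdist) ||
        kmer_match_oracle(pairs$seq2[i], contams, 40, hdist)
    }, logical(1))
    expect_identical(got$id, pairs$id[!oracle_hit])
  }
})

test_that("subsampling keeps the requested fraction of pairs", {
  pairs <- tibble::tibble(id = paste0("p", 1:10000),
                          seq1 = "ACGT", seq2 = "ACGT")
  expect_identical(subsample_pairs(pairs, 1, seed = 1), pairs)
  expect_equal(nrow(subsample_pairs(pairs, 0, seed = 1)), 0)
  kept <- nrow(subsample_pairs(pairs, 0.6, seed = 2))
  expect_lt(abs(kept - 6000), 3 * sqrt(10000 * 0.6 * 0.4))
  expect_error(subsample_pairs(pairs, 1.2), "rate")
})
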
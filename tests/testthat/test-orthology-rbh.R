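test_that("local alignment scores follow the BLASTN scheme", {
  set.seed(81)
  a <- random_seq(20)
  hits <- local_align(a, a, min_score = 5)
  expect_equal(max(hits$score), 40)
  expect_equal(hits$percent_identity[1], 100)

  b <- a
  substr(b, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(a, 10, 10))[1]
  hits2 <- local_align(a, b, min_score = 5)
  expect_equal(max(hits2$score), 2 * 19 - 3)
})

test_that("top-hit scores equal the Smith-Waterman DP oracle", {
  set.seed(82)
  for (i in 1:30) {
    n <- sample(40:500, 1)
    a <- random_seq(n)
    b <- if (i %% 2 == 0) mutate_copy(a, runif(1, 0.05, 0.4)) else
      random_seq(sample(40:500, 1))
    hits <- local_align(a, b, min_score = 5)
    top <- if (nrow(hits) > 0) max(hits$score) else 0
    oracle <- sw_oracle_score(a, b)
    # the oracle is forward-strand only; ours also searches the minus
    # strand, so compare against the better of the two oracle passes
    oracle <- max(oracle, sw_oracle_score(rc_chr(a), b))
    expect_equal(top, oracle)
  }
})

test_that("E-values are monotone in score and search space", {
  set.seed(83)
  a <- random_seq(300)
  b <- mutate_copy(a, 0.1)
  hits <- local_align(a, b, min_score = 5)
  ord <- order(hits$score)
  expect_true(all(diff(hits$e_value[ord]) <= 0))

  big_hits <- local_align(a, paste0(b, random_seq(3000)), min_score = 5)
  h1 <- hits[which.max(hits$score), ]
  h2 <- big_hits[which.max(big_hits$score), ]
  expect_equal(h1$score, h2$score)
  expect_gt(h2$e_value, h1$e_value)
})

test_that("the reciprocal threshold is two significant figures of 1/n", {
  expect_equal(evalue_threshold(3457), 0.00029)
  expect_equal(evalue_threshold(1), 1)
  expect_equal(evalue_threshold(10), 0.1)
  expect_error(evalue_threshold(0), ">= 1")
})

test_that("best_hit follows score, length and coordinate tie rules", {
  hits <- tibble::tibble(
    query_id = "q", subject_id = c("s1", "s1", "s2"),
    percent_identity = 90, alignment_length = c(20L, 25L, 10L),
    mismatches = 0L, gap_opens = 0L, q_start = 0L, q_end = 20L,
    s_start = c(5L, 9L, 2L), s_end = 30L, strand = "+",
    score = c(40L, 40L, 12L), e_value = 1e-5)
  expect_equal(best_hit(hits)$alignment_length, 25L)

  set.seed(84)
  rnd <- hits[sample(3, 50, replace = TRUE), ]
  rnd$score <- sample(100L, 50, replace = TRUE)
  expect_equal(best_hit(rnd)$score, max(rnd$score))
  expect_error(best_hit(rnd[0, ]), "empty")
})

test_that("RBH classification needs both overlaps", {
  frag <- tibble::tibble(chrom = "mel_1", start = 100L, end = 2100L)
  lifted <- tibble::tibble(chrom = "mon_1", start = 500L, end = 2500L)
  hit_on <- function(chrom, s, e) {
    tibble::tibble(query_id = "q", subject_id = chrom,
                   percent_identity = 95, alignment_length = 1000L,
                   mismatches = 0L, gap_opens = 0L, q_start = 0L,
                   q_end = 1000L, s_start = s, s_end = e, strand = "+",
                   score = 2000L, e_value = 0)
  }
  both <- classify_rbh(frag, lifted, hit_on("mel_1", 150L, 1200L),
                       hit_on("mon_1", 600L, 1500L))
  expect_true(both$is_rbh)

  wrong_scaffold <- classify_rbh(frag, lifted, hit_on("mel_1", 150L, 1200L),
                                 hit_on("mon_2", 600L, 1500L))
  expect_true(wrong_scaffold$forward_best_overlaps)
  expect_false(wrong_scaffold$reverse_best_overlaps)
  expect_false(wrong_scaffold$is_rbh)

  missing <- classify_rbh(frag, lifted, NULL, hit_on("mon_1", 600L, 1500L))
  expect_false(missing$is_rbh)
})

test_that("hit trimming removes nested and trims partial overlaps", {
  mk_hit <- function(qs, qe, score) {
    tibble::tibble(query_id = "q", subject_id = "s", percent_identity = 90,
                   alignment_length = qe - qs, mismatches = 0L,
                   gap_opens = 0L, q_start = qs, q_end = qe,
                   s_start = qs + 1000L, s_end = qe + 1000L, strand = "+",
                   score = score, e_value = 1e-9)
  }
  partial <- trim_overlapping_hits(dplyr::bind_rows(mk_hit(0L, 100L, 100L),
                                                    mk_hit(50L, 150L, 50L)))
  expect_equal(partial$q_start, c(0L, 100L))
  expect_equal(partial$q_end, c(100L, 150L))
  expect_equal(partial$alignment_length, c(100L, 50L))

  nested <- trim_overlapping_hits(dplyr::bind_rows(mk_hit(0L, 100L, 100L),
                                                   mk_hit(20L, 80L, 40L)))
  expect_equal(nrow(nested), 1)

  disjoint <- dplyr::bind_rows(mk_hit(0L, 50L, 60L), mk_hit(80L, 120L, 40L))
  expect_equal(trim_overlapping_hits(disjoint)[, names(disjoint)], disjoint)

  # disjointness property on random hit piles
  set.seed(85)
  for (rep in 1:20) {
    pile <- purrr::map_dfr(1:8, function(i) {
      qs <- sample(0:200, 1)
      mk_hit(qs, qs + sample(10:80, 1), sample(10:100, 1))
    })
    out <- trim_overlapping_hits(pile)
    covered <- integer(0)
    for (i in seq_len(nrow(out))) {
      span <- (out$q_start[i] + 1L):out$q_end[i]
      expect_equal(length(intersect(covered, span)), 0)
      covered <- c(covered, span)
    }
  }
})

test_that("alignment summaries weight identity by hit length", {
  mk <- function(qs, qe, id) {
    tibble::tibble(percent_identity = id, q_start = qs, q_end = qe)
  }
  s1 <- alignment_summary(mk(0L, 500L, 80), 1000)
  expect_equal(s1$query_coverage, 50)
  expect_equal(s1$weighted_identity, 80)

  s2 <- alignment_summary(dplyr::bind_rows(mk(0L, 500L, 90),
                                           mk(500L, 1000L, 70)), 2000)
  expect_equal(s2$query_coverage, 50)
  expect_equal(s2$weighted_identity, 80)

  s0 <- alignment_summary(mk(0L, 0L, 0)[0, ], 2000)
  expect_equal(s0$query_coverage, 0)
  expect_true(is.na(s0$weighted_identity))

  # weighted identity lies between the min and max inputs
  set.seed(86)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    starts <- cumsum(sample(50:200, n))
    hits <- purrr::map_dfr(seq_len(n), function(i) {
      mk(starts[i], starts[i] + sample(20:49, 1), runif(1, 50, 100))
    })
    s <- alignment_summary(hits, 2000)
    expect_gte(s$weighted_identity, min(hits$percent_identity))
    expect_lte(s$weighted_identity, max(hits$percent_identity))
  }
})

test_that("tabular hits round-trip through the 12-column format", {
  set.seed(87)
  a <- random_seq(200)
  b <- mutate_copy(a, 0.1)
  hits <- local_align(a, b, min_score = 10)
  path <- tempfile(fileext = ".tsv")
  write_tabular_hits(hits, path)
  back <- read_tabular_hits(path)
  for (col in c("query_id", "subject_id", "alignment_length", "q_start",
                "q_end", "s_start", "s_end", "strand", "score")) {
    expect_equal(back[[col]], hits[[col]], label = col)
  }
})
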
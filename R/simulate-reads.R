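#' Specify a simulated paired-end sequencing run
#'
#' Mirrors a small-insert Illumina library: 100 bp paired-end reads from
#' ~350 bp fragments, uniform substitution errors, and either a constant
#' quality string or a position ramp.
#'
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Fragment (insert) size distribution in bp.
#' @param coverage Target fold coverage of the mean haplotype length.
#' @param error_rate Per-base substitution error fraction.
#' @param quality_model `"constant"` (Q35 throughout) or `"ramp"` (Q40 at
#'   the 5' end falling to Q20 at the 3' end).
#' @param seed Integer seed.
#' @return A `sim_read_spec` list.
#' @export
sim_read_spec <- function(read_length = 100L, insert_mean = 350L,
                          insert_sd = 30L, coverage = 30, error_rate = 0.001,
                          quality_model = c("constant", "ramp"), seed = 1L) {
  quality_model <- match.arg(quality_model)
  if (insert_mean < read_length) stop("insert_mean < read_length")
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 1)
  structure(
    list(read_length = as.integer(read_length),
         insert_mean = as.integer(insert_mean),
         insert_sd = as.numeric(insert_sd), coverage = coverage,
         error_rate = error_rate, quality_model = quality_model,
         seed = as.integer(seed)),
    class = "sim_read_spec"
  )
}

#' Simulate paired-end reads from a diploid truth set
#'
#' Fragments are drawn uniformly along a haplotype chosen with probability
#' 1/2 per fragment; mate 1 is the forward strand of the fragment start,
#' mate 2 the reverse complement of the fragment end. Reads carry their
#' truth coordinates both in their names and as tibble columns, so error
#' rates and coverage can be audited without a mapper.
#'
#' @param truth A `diploid_truth` from [simulate_diploid()].
#' @param spec A [sim_read_spec()].
#' @return A paired-read tibble: `id`, `seq1`, `qual1`, `seq2`, `qual2`,
#'   plus truth columns `hap`, `frag_start` (1-based), `frag_end`.
#' @export
simulate_reads <- function(truth, spec) {
  stopifnot(inherits(truth, "diploid_truth"), inherits(spec, "sim_read_spec"))
  haps <- truth$haplotypes
  if (any(nchar(haps$seq) == 0)) stop("empty haplotype")
  set.seed(child_seed(spec$seed, 2L))

  rl <- spec$read_length
  mean_len <- mean(nchar(haps$seq))
  n_frag <- round(spec$coverage * mean_len / (2 * rl))
  hap_idx <- sample(c(1L, 2L), n_frag, replace = TRUE)
  hap_len <- nchar(haps$seq)[hap_idx]
  insert <- pmin(hap_len, pmax(rl, round(rnorm(n_frag, spec$insert_mean,
                                               spec$insert_sd))))
  start <- floor(runif(n_frag) * (hap_len - insert + 1)) + 1L
  end <- start + insert - 1L

  seq1 <- substring(haps$seq[hap_idx], start, start + rl - 1L)
  seq2 <- revcomp(substring(haps$seq[hap_idx], end - rl + 1L, end))
  if (spec$error_rate > 0) {
    seq1 <- sprinkle_errors(seq1, spec$error_rate)
    seq2 <- sprinkle_errors(seq2, spec$error_rate)
  }
  qual <- switch(spec$quality_model,
    constant = strrep(int_to_phred(35L), rl),
    ramp = int_to_phred(round(seq(40, 20, length.out = rl)))
  )
  tibble(
    id = sprintf("frag%07d|hap=%s|start=%d|end=%d", seq_len(n_frag),
                 haps$name[hap_idx], start, end),
    seq1 = seq1, qual1 = qual, seq2 = seq2, qual2 = qual,
    hap = haps$name[hap_idx], frag_start = start, frag_end = end
  )
}

# Uniform substitution errors across a vector of equal-length reads.
sprinkle_errors <- function(seqs, rate) {
  rl <- nchar(seqs[1])
  n_err <- rbinom(length(seqs), rl, rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    seqs[i] <- mutate_bases(seqs[i], sample.int(rl, n_err[i]))
  }
  seqs
}
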
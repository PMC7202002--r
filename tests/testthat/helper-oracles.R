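# Shared fixtures and independent oracles used across the suite.

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

mutate_copy <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- sample.int(n, k)
  ch[idx] <- vapply(ch[idx],
                    function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    character(1))
  paste(ch, collapse = "")
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Smith-Waterman oracle: optimal local score under match/mismatch 2/-3 and
# affine gap cost 5 + 2L, computed by an independent full-DP implementation.
sw_oracle_score <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 2)
  max(0, Biostrings::score(pa))
}

# Per-base chain projection oracle: walks the blocks one base at a time.
lift_oracle <- function(chain, start, end) {
  b <- chain$blocks[[1]]
  tb <- chain$t_start
  qb <- chain$q_start
  qpos <- integer(0)
  for (i in seq_len(nrow(b))) {
    for (off in seq_len(b$size[i]) - 1L) {
      t <- tb + off
      if (t >= start && t < end) qpos <- c(qpos, qb + off)
    }
    if (i < nrow(b)) {
      tb <- tb + b$size[i] + b$dt[i]
      qb <- qb + b$size[i] + b$dq[i]
    }
  }
  if (length(qpos) == 0) return(NULL)
  span <- c(min(qpos), max(qpos) + 1L)
  if (chain$q_strand == "-") span <- c(chain$q_size - span[2],
                                       chain$q_size - span[1])
  list(start = span[1], end = span[2], bases_mapped = length(qpos))
}

# Random structurally valid chain for the lift properties.
random_chain <- function(chain_id, seed) {
  set.seed(seed)
  n_blocks <- sample(1:6, 1)
  sizes <- sample(5:60, n_blocks, replace = TRUE)
  dt <- c(sample(0:30, n_blocks - 1, replace = TRUE), NA)
  dq <- c(sample(0:30, n_blocks - 1, replace = TRUE), NA)
  t_span <- sum(sizes) + sum(dt, na.rm = TRUE)
  q_span <- sum(sizes) + sum(dq, na.rm = TRUE)
  t_start <- sample(0:50, 1)
  q_start <- sample(0:50, 1)
  new_chain(score = sum(sizes), t_name = "t1", t_size = t_start + t_span + 50,
            t_start = t_start, t_end = t_start + t_span, q_name = "q1",
            q_size = q_start + q_span + 50, q_strand = sample(c("+", "-"), 1),
            q_start = q_start, q_end = q_start + q_span, chain_id = chain_id,
            blocks = tibble::tibble(size = sizes, dt = dt, dq = dq))
}

# Exhaustive window-by-window Hamming oracle for the contaminant k-mer
# filter (Ns mismatch everything, both strands).
kmer_match_oracle <- function(read, contams, k, hdist) {
  win <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }
  cwin <- unlist(lapply(contams, win))
  hamming <- function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    sum(!(av == bv & av %in% c("A", "C", "G", "T")))
  }
  for (s in c(read, rc_chr(read))) {
    for (w in win(s)) {
      for (cw in cwin) {
        if (hamming(w, cw) <= hdist) return(TRUE)
      }
    }
  }
  FALSE
}

# Cached RBH regimes shared by the acceptance blocks (each regime is
# expensive; computed once per run).
.rbh_cache <- new.env(parent = emptyenv())
rbh_regime <- function(identity, n_tiles, seed) {
  key <- paste0("id", identity, "_n", n_tiles, "_s", seed)
  if (!is.null(.rbh_cache[[key]])) return(.rbh_cache[[key]])
  sim <- simulate_ortholog_tiles(n_tiles, 2000L, identity,
                                 scaffold_shuffle = TRUE, seed = seed)
  res <- rbh_pipeline(sim$reference, sim$diverged, sim$tiles_ref, sim$chains)
  .rbh_cache[[key]] <- list(sim = sim, res = res)
  .rbh_cache[[key]]
}
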
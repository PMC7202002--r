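#' Split scaffolds on oversized gaps
#'
#' N-runs longer than `max_gap` are erroneous relative to a small-insert
#' library (scaffolders occasionally emit gaps of tens of kb against a
#' ~350 bp insert), so the scaffold is split at them and the gap removed;
#' runs of `max_gap` or fewer Ns are retained. Children of a split
#' scaffold are named `id.1`, `id.2`, ... left to right.
#'
#' @param assembly An assembly `tibble(name, seq)`.
#' @param max_gap Largest retained N-run, in bp (inclusive threshold;
#'   200-600 is typical for a 350 bp insert library).
#' @return The assembly tibble after splitting.
#' @export
split_on_oversized_gaps <- function(assembly, max_gap = 600L) {
  stopifnot(max_gap >= 1)
  assembly <- as_seq_tbl(assembly, "assembly")
  purrr::map_dfr(seq_len(nrow(assembly)), function(i) {
    seq <- assembly$seq[i]
    runs <- n_runs(seq)
    big <- runs[runs$end - runs$start > max_gap, ]
    if (nrow(big) == 0) return(assembly[i, ])
    starts <- c(0L, big$end)
    ends <- c(big$start, nchar(seq))
    pieces <- substring(seq, starts + 1L, ends)
    keep <- nchar(pieces) > 0
    tibble(name = paste0(assembly$name[i], ".", seq_len(sum(keep))),
           seq = pieces[keep])
  })
}

#' Extract contigs by splitting scaffolds on every N
#'
#' Contigs are the maximal N-free runs of each scaffold — split on every
#' N, including single Ns, the convention behind contig-level contiguity
#' statistics.
#'
#' @param assembly An assembly `tibble(name, seq)`.
#' @return A tibble with one row per contig: `name` (source scaffold),
#'   `contig` (index within the scaffold), `start` (0-based offset on the
#'   scaffold), `seq`, `length`.
#' @examples
#' extract_contigs(tibble::tibble(name = "s1", seq = "ACGTNNACG"))$length
#' @export
extract_contigs <- function(assembly) {
  assembly <- as_seq_tbl(assembly, "assembly")
  purrr::map_dfr(seq_len(nrow(assembly)), function(i) {
    seq <- assembly$seq[i]
    m <- gregexpr("[^N]+", seq)[[1]]
    if (m[1] == -1L) return(tibble())
    tibble(name = assembly$name[i],
           contig = seq_along(m),
           start = as.integer(m) - 1L,
           seq = substring(seq, m, as.integer(m) + attr(m, "match.length") - 1L),
           length = as.integer(attr(m, "match.length")))
  })
}

#' Hard-mask a region with a fixed-length N run
#'
#' Replaces `[start, end)` of one scaffold with exactly `mask_length` Ns
#' (300 by default, the treatment for single-N tandem-allele seams and
#' their flanks); coordinates right of `end` shift by
#' `mask_length - (end - start)`.
#'
#' @param assembly An assembly `tibble(name, seq)`.
#' @param name Scaffold to mask.
#' @param start,end Region to replace, 0-based half-open.
#' @param mask_length Number of Ns to insert.
#' @return The assembly tibble with the region masked.
#' @export
hard_mask_region <- function(assembly, name, start, end, mask_length = 300L) {
  assembly <- as_seq_tbl(assembly, "assembly")
  i <- match(name, assembly$name)
  if (is.na(i)) stop("no scaffold named ", name, call. = FALSE)
  len <- nchar(assembly$seq[i])
  if (start < 0 || end <= start || end > len) {
    stop("region [", start, ",", end, ") out of bounds for ", name,
         call. = FALSE)
  }
  assembly$seq[i] <- paste0(substr(assembly$seq[i], 1L, start),
                            strrep("N", mask_length),
                            substr(assembly$seq[i], end + 1L, len))
  assembly
}

#' Randomly resolve IUPAC ambiguity codes
#'
#' Each ambiguous base other than N is replaced by a base drawn uniformly
#' from the set it encodes (R becomes A or G, and so on); N is left
#' untouched. Deterministic under `seed`.
#'
#' @param assembly An assembly `tibble(name, seq)`.
#' @param seed Integer seed.
#' @return The assembly tibble with only ACGTN characters.
#' @export
resolve_ambiguities <- function(assembly, seed = 1L) {
  assembly <- as_seq_tbl(assembly, "assembly")
  codes <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = NULL)
  set.seed(child_seed(seed, 6L))
  assembly$seq <- vapply(assembly$seq, function(seq) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    plain <- chars %in% c("A", "C", "G", "T", "N")
    if (all(plain)) return(seq)
    bad <- !plain & !chars %in% names(codes)
    if (any(bad)) {
      stop("non-IUPAC character(s): ", paste(unique(chars[bad]), collapse = " "),
           call. = FALSE)
    }
    idx <- which(!plain)
    chars[idx] <- vapply(chars[idx],
                         function(c) sample(codes[[c]], 1L), character(1))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  assembly
}

#' Drop scaffolds below a minimum length
#'
#' @param assembly An assembly `tibble(name, seq)`.
#' @param min_length Minimum retained scaffold length in bp (>= keeps).
#' @return The filtered assembly tibble.
#' @export
drop_short_scaffolds <- function(assembly, min_length = 1000L) {
  stopifnot(min_length >= 0)
  assembly <- as_seq_tbl(assembly, "assembly")
  assembly[nchar(assembly$seq) >= min_length, ]
}

#' Excise a contaminant span from a scaffold
#'
#' A confirmed contaminant span at a scaffold end is trimmed off; an
#' internal span splits the scaffold into its two flanks (children `.1`
#' and `.2`); a span covering the whole scaffold removes it. The mode is
#' chosen automatically from the span position.
#'
#' @param assembly An assembly `tibble(name, seq)`.
#' @param name Scaffold carrying the span.
#' @param start,end Contaminant span, 0-based half-open.
#' @return The assembly tibble after excision.
#' @export
excise_contaminant_span <- function(assembly, name, start, end) {
  assembly <- as_seq_tbl(assembly, "assembly")
  i <- match(name, assembly$name)
  if (is.na(i)) stop("no scaffold named ", name, call. = FALSE)
  len <- nchar(assembly$seq[i])
  if (start < 0 || end <= start || end > len) {
    stop("span out of bounds", call. = FALSE)
  }
  seq <- assembly$seq[i]
  replacement <-
    if (start == 0L && end == len) {
      tibble(name = character(), seq = character())
    } else if (start == 0L) {
      tibble(name = name, seq = substr(seq, end + 1L, len))
    } else if (end == len) {
      tibble(name = name, seq = substr(seq, 1L, start))
    } else {
      tibble(name = paste0(name, c(".1", ".2")),
             seq = c(substr(seq, 1L, start), substr(seq, end + 1L, len)))
    }
  dplyr::bind_rows(assembly[seq_len(i - 1L), ], replacement,
                   assembly[-seq_len(i), ])
}
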
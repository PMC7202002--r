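#' Construct a chain tibble row
#'
#' Chains are stored as a tibble with one row per chain: the UCSC header
#' fields plus a `blocks` list-column of `tibble(size, dt, dq)` (gapless
#' block sizes and the target/query gaps after each block; `dt`/`dq` are
#' `NA` on the last block). All coordinates are 0-based half-open;
#' minus-strand query coordinates live on the reversed query sequence, as
#' in the UCSC chain format.
#'
#' @param score,t_name,t_size,t_start,t_end,q_name,q_size,q_strand,q_start,q_end,chain_id
#'   Chain header fields.
#' @param blocks A `tibble(size, dt, dq)` of gapless blocks.
#' @return A one-row chain tibble.
#' @export
new_chain <- function(score, t_name, t_size, t_start, t_end, q_name, q_size,
                      q_strand, q_start, q_end, chain_id, blocks) {
  ch <- tibble(score = as.numeric(score), t_name = t_name,
               t_size = as.integer(t_size), t_start = as.integer(t_start),
               t_end = as.integer(t_end), q_name = q_name,
               q_size = as.integer(q_size), q_strand = q_strand,
               q_start = as.integer(q_start), q_end = as.integer(q_end),
               chain_id = as.integer(chain_id), blocks = list(blocks))
  validate_chains(ch)
  ch
}

validate_chains <- function(chains) {
  for (i in seq_len(nrow(chains))) {
    b <- chains$blocks[[i]]
    t_span <- sum(b$size) + sum(b$dt[-nrow(b)])
    q_span <- sum(b$size) + sum(b$dq[-nrow(b)])
    if (nrow(b) == 1) { t_span <- b$size; q_span <- b$size }
    if (is.na(t_span) || is.na(q_span) ||
        t_span != chains$t_end[i] - chains$t_start[i] ||
        q_span != chains$q_end[i] - chains$q_start[i]) {
      stop("chain ", chains$chain_id[i], ": block sums (", t_span, ", ",
           q_span, ") contradict the header spans", call. = FALSE)
    }
    if (!chains$q_strand[i] %in% c("+", "-")) {
      stop("chain ", chains$chain_id[i], ": bad query strand", call. = FALSE)
    }
  }
  invisible(chains)
}

#' Read and write UCSC chain files
#'
#' `read_chain()` parses UCSC chain text into a chain tibble and verifies
#' on load that each chain's block sizes and gaps add up to its header
#' spans (a malformed chain is a parse error naming the chain id).
#' `write_chain()` serialises a chain tibble back to the format.
#'
#' @param path Path to a chain file (`read_chain()` also accepts a
#'   character vector of chain-format lines).
#' @param chains A chain tibble.
#' @return `read_chain()` returns a chain tibble (see [new_chain()]);
#'   `write_chain()` returns its input invisibly.
#' @export
read_chain <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  hdr_idx <- grep("^chain\\b", lines)
  if (length(hdr_idx) == 0) stop("no chain records found", call. = FALSE)
  bounds <- c(hdr_idx, length(lines) + 1L)
  out <- vector("list", length(hdr_idx))
  for (i in seq_along(hdr_idx)) {
    h <- strsplit(lines[hdr_idx[i]], "\\s+")[[1]]
    if (length(h) != 13) {
      stop("malformed chain header at line ", hdr_idx[i], call. = FALSE)
    }
    body <- lines[seq(hdr_idx[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[nzchar(body)]
    fields <- strsplit(body, "\\s+")
    sizes <- as.integer(vapply(fields, `[`, "", 1L))
    dt <- as.integer(vapply(fields, function(f) f[2], ""))
    dq <- as.integer(vapply(fields, function(f) f[3], ""))
    out[[i]] <- tibble(
      score = as.numeric(h[2]),
      t_name = h[3], t_size = as.integer(h[4]), t_start = as.integer(h[6]),
      t_end = as.integer(h[7]),
      q_name = h[8], q_size = as.integer(h[9]), q_strand = h[10],
      q_start = as.integer(h[11]), q_end = as.integer(h[12]),
      chain_id = as.integer(h[13]),
      blocks = list(tibble(size = sizes, dt = dt, dq = dq))
    )
  }
  validate_chains(dplyr::bind_rows(out))
}

#' @rdname read_chain
#' @export
write_chain <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(chains))) {
    ch <- chains[i, ]
    writeLines(paste("chain", format(ch$score, scientific = FALSE),
                     ch$t_name, ch$t_size, "+", ch$t_start, ch$t_end,
                     ch$q_name, ch$q_size, ch$q_strand, ch$q_start, ch$q_end,
                     ch$chain_id), con)
    b <- ch$blocks[[1]]
    n <- nrow(b)
    if (n > 1) {
      writeLines(paste(b$size[-n], b$dt[-n], b$dq[-n]), con)
    }
    writeLines(c(as.character(b$size[n]), ""), con)
  }
  invisible(chains)
}

#' Remap an interval through alignment chains (liftOver-style)
#'
#' Projects every base of a target interval that falls inside a gapless
#' block through the block offsets, chain by chain. A chain's remapping is
#' reported when the fraction of interval bases that project is at least
#' `min_match` (the liftOver `-minMatch` semantics, measured against the
#' source interval length); the reported query interval spans the minimum
#' to maximum projected position, bridging chain gaps interior to the
#' projection. With `multiple = FALSE` only the highest-scoring qualifying
#' chain is kept (`-multiple` off). Minus-strand projections are returned
#' in forward query coordinates with `strand = "-"`.
#'
#' @param chains A chain tibble from [read_chain()].
#' @param t_name Target sequence name of the interval.
#' @param start,end Interval, 0-based half-open, on the target.
#' @param min_match Minimum fraction of interval bases that must project.
#' @param multiple Report one remapping per qualifying chain?
#' @return A tibble with columns `q_name`, `start`, `end`, `strand`,
#'   `chain_id`, `bases_mapped`; zero rows when the interval is unmapped.
#' @examples
#' ch <- new_chain(100, "t", 100, 0, 100, "q", 100, "+", 0, 100, 1,
#'                 tibble::tibble(size = 100L, dt = NA, dq = NA))
#' lift_interval(ch, "t", 10, 20)
#' @export
lift_interval <- function(chains, t_name, start, end, min_match = 0.1,
                          multiple = TRUE) {
  stopifnot(end > start, min_match >= 0, min_match <= 1)
  cand <- chains[chains$t_name == t_name & chains$t_start < end &
                   chains$t_end > start, ]
  out <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    project_through_chain(cand[i, ], start, end)
  })
  if (nrow(out) > 0) {
    out <- out[out$bases_mapped / (end - start) >= min_match, ]
  }
  if (nrow(out) == 0) {
    return(tibble(q_name = character(), start = integer(), end = integer(),
                  strand = character(), chain_id = integer(),
                  bases_mapped = integer()))
  }
  if (!multiple) {
    best <- which.max(cand$score[match(out$chain_id, cand$chain_id)])
    out <- out[best, ]
  }
  out
}

# Project [start, end) through one chain; returns 0- or 1-row tibble.
project_through_chain <- function(ch, start, end) {
  b <- ch$blocks[[1]]
  tb <- ch$t_start
  qb <- ch$q_start
  q_min <- Inf; q_max <- -Inf; mapped <- 0L
  for (i in seq_len(nrow(b))) {
    a <- max(start, tb); z <- min(end, tb + b$size[i])
    if (a < z) {
      qa <- qb + (a - tb)
      qz <- qb + (z - tb)
      q_min <- min(q_min, qa); q_max <- max(q_max, qz)
      mapped <- mapped + (z - a)
    }
    if (i < nrow(b)) {
      tb <- tb + b$size[i] + b$dt[i]
      qb <- qb + b$size[i] + b$dq[i]
    }
  }
  if (mapped == 0L) return(tibble())
  if (ch$q_strand == "-") {
    fwd_start <- ch$q_size - q_max
    fwd_end <- ch$q_size - q_min
  } else {
    fwd_start <- q_min
    fwd_end <- q_max
  }
  tibble(q_name = ch$q_name, start = as.integer(fwd_start),
         end = as.integer(fwd_end), strand = ch$q_strand,
         chain_id = ch$chain_id, bases_mapped = as.integer(mapped))
}

#' Pick the largest-span remapping
#'
#' When an interval remaps through several chains, the remapping with the
#' larger coordinate span is retained (it typically contains the sequence
#' of interest); ties break by more bases mapped, then lower chain id.
#'
#' @param result A remapping tibble from [lift_interval()].
#' @return A one-row tibble.
#' @export
select_largest_span <- function(result) {
  if (nrow(result) == 0) stop("empty remapping result", call. = FALSE)
  result |>
    dplyr::arrange(dplyr::desc(.data$end - .data$start),
                   dplyr::desc(.data$bases_mapped), .data$chain_id) |>
    dplyr::slice(1)
}

#' Remap a BED table of intervals through chains
#'
#' Applies [lift_interval()] to every row and keeps the largest-span
#' remapping per interval. Intervals with no qualifying chain are returned
#' with `remapped = FALSE` and `NA` coordinates, mirroring liftOver's
#' unmapped output.
#'
#' @param bed A BED6 tibble (`chrom`, `start`, `end`, `name`, ...).
#' @inheritParams lift_interval
#' @return The BED tibble with remapped coordinates `q_name`, `q_start`,
#'   `q_end`, `q_strand`, `bases_mapped` and a logical `remapped` column.
#' @export
lift_bed <- function(bed, chains, min_match = 0.1, multiple = TRUE) {
  lifted <- purrr::map_dfr(seq_len(nrow(bed)), function(i) {
    res <- lift_interval(chains, bed$chrom[i], bed$start[i], bed$end[i],
                         min_match = min_match, multiple = multiple)
    if (nrow(res) == 0) {
      return(tibble(q_name = NA_character_, q_start = NA_integer_,
                    q_end = NA_integer_, q_strand = NA_character_,
                    bases_mapped = 0L, remapped = FALSE))
    }
    best <- select_largest_span(res)
    tibble(q_name = best$q_name, q_start = best$start, q_end = best$end,
           q_strand = best$strand, bases_mapped = best$bases_mapped,
           remapped = TRUE)
  })
  dplyr::bind_cols(bed, lifted)
}
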
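#' Simulate diverged enhancer tiles with a truth chain
#'
#' Builds a reference genome of `n_tiles` tiles (~2 kb, the size of the
#' embryonic enhancer fragments this emulates) separated by spacers, and a
#' diverged copy in which every base is substituted with probability
#' `1 - target_identity` — substitutions only, so the truth alignment
#' geometry stays exact and per-tile identity concentrates tightly around
#' the target. With `scaffold_shuffle` the diverged genome is cut at spacer
#' midpoints into pieces that are reordered and optionally inverted, each
#' becoming its own scaffold; the truth chain records every piece as a
#' UCSC-style chain (inverted pieces on the `-` query strand).
#'
#' @param n_tiles Number of tiles.
#' @param tile_length Tile length in bp.
#' @param target_identity Expected per-base identity of tile orthologs,
#'   in `(0, 1]`.
#' @param scaffold_shuffle Cut, reorder and invert the diverged genome?
#' @param seed Integer seed.
#' @param spacer Spacer length between tiles in bp.
#' @param gc GC fraction of the simulated sequence.
#' @param n_pieces,n_inversions Number of pieces and inverted pieces when
#'   shuffling.
#' @return A list: `reference` and `diverged` genomes (`tibble(name, seq)`),
#'   `tiles_ref` and `tiles_div` (BED6 tibbles of the tile positions on
#'   each genome), and `chains` (a chain tibble mapping reference
#'   coordinates onto the diverged genome, see [read_chain()]).
#' @examples
#' sim <- simulate_ortholog_tiles(5, 500, 0.9, seed = 1)
#' sim$chains$q_strand
#' @export
simulate_ortholog_tiles <- function(n_tiles, tile_length = 2000L,
                                    target_identity = 0.75,
                                    scaffold_shuffle = FALSE, seed = 1L,
                                    spacer = 500L, gc = 0.42,
                                    n_pieces = 4L, n_inversions = 1L) {
  stopifnot(n_tiles >= 1, tile_length >= 1, target_identity > 0,
            target_identity <= 1, spacer >= 1)
  set.seed(child_seed(seed, 4L))
  len <- n_tiles * (tile_length + spacer) + spacer
  if (n_tiles * tile_length > len) stop("tiles exceed genome length")
  ref_seq <- random_dna(len, gc)
  tile_start <- spacer + (seq_len(n_tiles) - 1L) * (tile_length + spacer)
  tiles_ref <- tibble(
    chrom = "ref_1", start = tile_start, end = tile_start + tile_length,
    name = sprintf("tile_%04d", seq_len(n_tiles)), score = 0L, strand = "+"
  )

  div_seq <- ref_seq
  if (target_identity < 1) {
    n_sub <- rbinom(1L, len, 1 - target_identity)
    div_seq <- mutate_bases(div_seq, sample.int(len, n_sub))
  }

  if (!scaffold_shuffle) {
    chains <- new_chain(score = len, t_name = "ref_1", t_size = len,
                        t_start = 0L, t_end = len, q_name = "div_1",
                        q_size = len, q_strand = "+", q_start = 0L,
                        q_end = len, chain_id = 1L,
                        blocks = tibble(size = len, dt = NA_integer_,
                                        dq = NA_integer_))
    tiles_div <- dplyr::mutate(tiles_ref, chrom = "div_1")
    return(list(reference = tibble(name = "ref_1", seq = ref_seq),
                diverged = tibble(name = "div_1", seq = div_seq),
                tiles_ref = tiles_ref, tiles_div = tiles_div,
                chains = chains))
  }

  n_pieces <- min(n_pieces, n_tiles)
  stopifnot(n_inversions <= n_pieces)
  # cut at spacer midpoints so no tile straddles a breakpoint
  spacer_mid <- tile_start + tile_length + spacer %/% 2L
  cuts <- sort(sample(spacer_mid[-n_tiles], n_pieces - 1L))
  piece_start <- c(0L, cuts)           # 0-based on reference
  piece_end <- c(cuts, len)
  order_perm <- sample.int(n_pieces)
  inverted <- seq_len(n_pieces) %in% sample.int(n_pieces, n_inversions)

  diverged <- tibble(
    name = sprintf("div_%d", seq_len(n_pieces)),
    piece = order_perm,
    start = piece_start[order_perm],
    end = piece_end[order_perm],
    inv = inverted[order_perm]
  ) |>
    dplyr::mutate(
      seq = substring(div_seq, .data$start + 1L, .data$end),
      seq = ifelse(.data$inv, revcomp(.data$seq), .data$seq),
      size = .data$end - .data$start
    )

  chains <- purrr::pmap_dfr(
    diverged[, c("name", "start", "end", "inv", "size")],
    function(name, start, end, inv, size) {
      new_chain(score = size, t_name = "ref_1", t_size = len,
                t_start = start, t_end = end, q_name = name, q_size = size,
                q_strand = if (inv) "-" else "+", q_start = 0L, q_end = size,
                chain_id = match(name, diverged$name),
                blocks = tibble(size = size, dt = NA_integer_,
                                dq = NA_integer_))
    })

  # tile positions on the diverged genome (forward coordinates)
  piece_of <- findInterval(tiles_ref$start, piece_start)
  tiles_div <- tiles_ref
  for (i in seq_len(n_tiles)) {
    p <- which(diverged$piece == piece_of[i])
    off <- tiles_ref$start[i] - diverged$start[p]
    if (!diverged$inv[p]) {
      tiles_div$start[i] <- off
      tiles_div$strand[i] <- "+"
    } else {
      tiles_div$start[i] <- diverged$size[p] - (off + tile_length)
      tiles_div$strand[i] <- "-"
    }
    tiles_div$end[i] <- tiles_div$start[i] + tile_length
    tiles_div$chrom[i] <- diverged$name[p]
  }

  list(reference = tibble(name = "ref_1", seq = ref_seq),
       diverged = diverged[, c("name", "seq")],
       tiles_ref = tiles_ref, tiles_div = tiles_div, chains = chains)
}
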
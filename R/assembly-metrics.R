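#' NG(x): length at x% of the estimated genome size
#'
#' Scaffold lengths are sorted longest first and summed; `ng_value()`
#' returns the length at which the running sum first reaches `x`% of the
#' *estimated genome size* (the NG statistic substitutes the genome size
#' for the total assembly length used by N50). When the assembly never
#' reaches that fraction of the genome — the NG curve never intersects the
#' x-axis — the value is undefined and `NA` is returned.
#'
#' @param lengths Scaffold (or contig) lengths in bp.
#' @param genome_size Estimated genome size in bp.
#' @param x Percentage in 1..100 (50 gives the NG50).
#' @return Length in bp, or `NA` when undefined.
#' @examples
#' ng_value(c(100, 50, 50), 200, 50)
#' @export
ng_value <- function(lengths, genome_size, x = 50L) {
  stopifnot(genome_size > 0)
  if (any(x < 1 | x > 100)) stop("x must be in 1..100")
  sorted <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.double(sorted))
  vapply(x, function(xi) {
    i <- which(cum >= xi / 100 * genome_size)[1]
    if (is.na(i)) NA_real_ else sorted[i]
  }, numeric(1))
}

#' The full NG graph, NG(1)..NG(100)
#'
#' @inheritParams ng_value
#' @return A tibble with columns `x` (1..100) and `ng` (bp, `NA` where the
#'   curve is undefined). `ng` is non-increasing over its defined range.
#' @export
ng_graph <- function(lengths, genome_size) {
  tibble(x = 1:100, ng = ng_value(lengths, genome_size, 1:100))
}

#' Contiguity and completeness statistics for an assembly
#'
#' Computes the scaffold- and contig-level summary of an assembly against
#' an estimated genome size: total scaffold length, N50 and NG50, longest
#' scaffold, contig NG50 (contigs split on every N, including single Ns),
#' longest contig, total gap (N) length, the percentage of the genome
#' assembled, and the full scaffold/contig NG graphs.
#'
#' @param assembly An assembly `tibble(name, seq)` (or a FASTA path).
#' @param genome_size Estimated genome size in bp.
#' @return An `assembly_stats` object; see [glance.assembly_stats()] for
#'   the one-row summary, [tidy.assembly_stats()] for the NG graphs, and
#'   [autoplot.assembly_stats()] to draw the NG graph.
#' @export
assembly_stats <- function(assembly, genome_size) {
  if (is.character(assembly) && length(assembly) == 1 && file.exists(assembly)) {
    assembly <- read_fasta(assembly)
  }
  assembly <- as_seq_tbl(assembly, "assembly")
  if (nrow(assembly) == 0) stop("empty assembly", call. = FALSE)
  stopifnot(genome_size > 0)
  scaffold_lengths <- nchar(assembly$seq)
  contigs <- extract_contigs(assembly)
  contig_lengths <- contigs$length
  total <- sum(as.double(scaffold_lengths))
  structure(
    list(
      summary = tibble(
        n_scaffolds = nrow(assembly),
        total_scaffold_length = total,
        scaffold_n50 = ng_value(scaffold_lengths, total, 50L),
        scaffold_ng50 = ng_value(scaffold_lengths, genome_size, 50L),
        longest_scaffold = max(scaffold_lengths),
        contig_ng50 = ng_value(contig_lengths, genome_size, 50L),
        longest_contig = max(contig_lengths),
        total_gap_length = total - sum(as.double(contig_lengths)),
        percent_assembled = percent_genome_assembled(total, genome_size),
        gene_sized_percent = gene_sized_fraction(scaffold_lengths)
      ),
      ng = dplyr::bind_rows(
        dplyr::mutate(ng_graph(scaffold_lengths, genome_size), level = "scaffold"),
        dplyr::mutate(ng_graph(contig_lengths, genome_size), level = "contig")
      ),
      scaffold_lengths = scaffold_lengths,
      contig_lengths = contig_lengths,
      genome_size = genome_size
    ),
    class = "assembly_stats"
  )
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly statistics (estimated genome size ",
      format(x$genome_size, big.mark = ","), " bp)\n", sep = "")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Percentage of the assembly in gene-sized scaffolds
#'
#' The fraction of the total scaffold length held in scaffolds at least
#' `threshold` bp long. The 6.3 kb default is an upper estimate of the
#' average Drosophila gene length, so this measures whether an assembly is
#' usable for gene-scale (and smaller, e.g. enhancer-scale) analyses
#' regardless of its NG50.
#'
#' @param lengths Scaffold lengths in bp.
#' @param threshold Gene-size threshold in bp (inclusive).
#' @return Percentage of total scaffold length.
#' @export
gene_sized_fraction <- function(lengths, threshold = 6300L) {
  if (length(lengths) == 0) stop("no lengths supplied")
  100 * sum(as.double(lengths[lengths >= threshold])) / sum(as.double(lengths))
}

#' Percentage of the estimated genome size assembled
#'
#' `100 * total_scaffold_length / est_genome_size`, rounded to one decimal
#' for reporting. Values above 100 indicate haplotype inflation (divergent
#' haplotypes assembled on separate scaffolds); values well below 100
#' typically reflect missing repeat copies.
#'
#' @param total_scaffold_length Total assembly length in bp.
#' @param est_genome_size Estimated genome size in bp.
#' @return Percentage, one decimal.
#' @export
percent_genome_assembled <- function(total_scaffold_length, est_genome_size) {
  stopifnot(est_genome_size > 0)
  round(100 * total_scaffold_length / est_genome_size, 1)
}

#' Pearson correlation with a two-sided test
#'
#' Convenience wrapper around [stats::cor.test()] (`method = "pearson"`)
#' that drops incomplete pairs first, the form used for, e.g., estimated
#' genome size against log10 repeat-branch frequency.
#'
#' @param x,y Paired numeric vectors; pairs with `NA` are dropped.
#' @return A one-row tibble: `estimate` (r), `statistic`, `p.value`, `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         p.value = ct$p.value, n = length(x))
}

#' Ordinary least squares fit
#'
#' Wrapper around [stats::lm()] for the regression analyses of assembly
#' contiguity on sample covariates (repeat content, heterozygosity,
#' coverage); incomplete rows are dropped. The returned `lm` object works
#' with `broom::tidy()`/`glance()`.
#'
#' @param data A data frame of response and predictors.
#' @param formula A model formula.
#' @return An `lm` fit.
#' @export
ols_fit <- function(data, formula) {
  fit <- stats::lm(formula, data = data, na.action = stats::na.omit)
  if (fit$rank < length(stats::coef(fit))) {
    stop("rank-deficient design", call. = FALSE)
  }
  fit
}
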
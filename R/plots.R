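#' Plot a k-mer frequency spectrum
#'
#' Distinct canonical k-mers per multiplicity on a log y scale, with the
#' detected error trough and coverage mode marked when estimable.
#'
#' @param object A `kmer_spectrum`.
#' @param max_multiplicity Right edge of the x axis.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kmer_spectrum
#' @export
autoplot.kmer_spectrum <- function(object, max_multiplicity = 100L, ...) {
  tm <- spectrum_trough_mode(object)
  dat <- object[object$multiplicity <= max_multiplicity, ]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$multiplicity,
                                         y = .data$n_kmers)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = sprintf("%d-mer multiplicity", attr(object, "k")),
                  y = "distinct k-mers")
  if (!is.na(tm$trough)) {
    p <- p + ggplot2::geom_vline(xintercept = c(tm$trough, tm$mode),
                                 linetype = c("dotted", "dashed"))
  }
  p
}

#' Plot the NG graph of an assembly
#'
#' NG(x) against x for scaffolds and contigs; the x value where a curve
#' ends (never intersecting the axis) is the percentage of the estimated
#' genome size the assembly reaches.
#'
#' @param object An `assembly_stats` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot assembly_stats
#' @export
autoplot.assembly_stats <- function(object, ...) {
  ggplot2::ggplot(tidyr::drop_na(object$ng, "ng"),
                  ggplot2::aes(x = .data$x, y = .data$ng,
                               colour = .data$level)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "x (% of estimated genome size)", y = "NG(x), bp",
                  colour = NULL)
}

#' GC % against average k-mer coverage, with an optional gate
#'
#' The scaffold-signature plot used to spot contaminant clusters; when
#' gate ranges are supplied the rectangle is drawn and points coloured by
#' candidate status.
#'
#' @param signatures A tibble from [scaffold_signatures()].
#' @param gc_range,cov_range Optional gate bounds `c(lo, hi)`.
#' @return A ggplot.
#' @export
plot_gc_coverage <- function(signatures, gc_range = NULL, cov_range = NULL) {
  p <- ggplot2::ggplot(signatures,
                       ggplot2::aes(x = .data$gc_percent,
                                    y = .data$avg_kmer_coverage))
  if (!is.null(gc_range) && !is.null(cov_range)) {
    flagged <- classify_candidates(signatures, gc_range, cov_range)
    p <- ggplot2::ggplot(flagged,
                         ggplot2::aes(x = .data$gc_percent,
                                      y = .data$avg_kmer_coverage,
                                      colour = .data$candidate)) +
      ggplot2::annotate("rect", xmin = gc_range[1], xmax = gc_range[2],
                        ymin = cov_range[1], ymax = cov_range[2],
                        alpha = 0.1, fill = "red")
  }
  p + ggplot2::geom_point(ggplot2::aes(size = .data$length), alpha = 0.6) +
    ggplot2::labs(x = "GC %", y = "average k-mer coverage")
}

#' 2D histogram of query coverage against weighted identity
#'
#' Summarises an [rbh_pipeline()] result the way fragment-similarity
#' surveys are drawn: binned counts of fragments by query coverage and
#' length-weighted percent identity.
#'
#' @param results An [rbh_pipeline()] tibble.
#' @param bins Number of bins per axis.
#' @return A ggplot.
#' @export
plot_identity_coverage <- function(results, bins = 20L) {
  dat <- tidyr::drop_na(results, "query_coverage", "weighted_identity")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$query_coverage,
                                    y = .data$weighted_identity)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::labs(x = "query coverage (%)",
                  y = "length-weighted identity (%)")
}
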
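#' Tidy an assembly_stats object
#'
#' Returns the scaffold and contig NG graphs in long form (`x`, `ng`,
#' `level`), the broom-style counterpart to [glance.assembly_stats()].
#'
#' @param x An `assembly_stats` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy assembly_stats
#' @export
tidy.assembly_stats <- function(x, ...) {
  x$ng
}

#' One-row summary of an assembly_stats object
#'
#' @param x An `assembly_stats` object.
#' @param ... Unused.
#' @return A one-row tibble of the contiguity/completeness statistics.
#' @method glance assembly_stats
#' @export
glance.assembly_stats <- function(x, ...) {
  x$summary
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
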
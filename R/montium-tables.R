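#' Bundled summary tables of the 23-genome D. montium assembly resource
#'
#' The package ships the published per-species summary tables of the
#' *Drosophila montium* clade genome resource its methods were built for:
#' genome size estimates and assembly statistics (`"assembly"`), sample
#' and read-profile information including de Bruijn variant/repeat branch
#' frequencies at k = 41 (`"samples"`, `NA` where coverage was too low to
#' estimate), and the enhancer remapping / reciprocal-best-hit outcomes
#' per species (`"enhancers"`, including the previously published
#' *D. kikkawai* assembly for comparison). Columns are returned in snake
#' case with numbers parsed.
#'
#' @param which One of `"assembly"`, `"samples"`, `"enhancers"`.
#' @return A tibble.
#' @examples
#' mean(montium_table("assembly")$scaffold_ng50)
#' @export
montium_table <- function(which = c("assembly", "samples", "enhancers")) {
  which <- match.arg(which)
  file <- switch(which,
    assembly = "montium_assembly_stats.tsv",
    samples = "montium_sample_info.tsv",
    enhancers = "montium_enhancer_remapping.tsv"
  )
  path <- system.file("extdata", file, package = "cladeqc", mustWork = TRUE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  names(raw) <- switch(which,
    assembly = c("species", "est_genome_size", "total_scaffold_length",
                 "scaffold_ng50", "longest_scaffold", "contig_ng50",
                 "longest_contig", "total_gap_length"),
    samples = c("species", "strain", "ncbi_accession", "coverage",
                "gc_percent", "variant_branch_freq", "repeat_branch_freq"),
    enhancers = c("species", "attempted_remappings", "successful_remappings",
                  "pct_successful_remappings", "reciprocal_best_hits",
                  "pct_remappings_rbh")
  )
  numeric_cols <- setdiff(names(raw), c("species", "strain", "ncbi_accession"))
  raw |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(numeric_cols),
      ~ as.numeric(gsub(",", "", as.character(.x), fixed = TRUE))
    ))
}

#' @rdname montium_table
#' @export
montium_tables <- function() {
  list(assembly = montium_table("assembly"),
       samples = montium_table("samples"),
       enhancers = montium_table("enhancers"))
}
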
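# cladeqc

Assembly QC, haplotype consensus and enhancer orthology for short-read
clade genomics.

## The problem

Clade-genomics projects sequence dozens of related species from single
small-insert Illumina libraries (~350 bp inserts, 100 bp paired-end reads
at ~30-35x). That design is cheap, but it leaves the assemblies
fragmented and haplotype-mosaic, and it shifts the analytical weight onto
the stages *around* the assembler: read QC and decontamination before
assembly; scaffold surgery, phasing consensus and contamination screening
after it; and completeness metrics that ask whether genes and regulatory
elements are usable rather than how long the scaffolds are. cladeqc
implements those stages as tested, reusable R functions, for people
building or evaluating such resources. It also bundles the published
per-species summary tables of the 23-genome *Drosophila montium* assembly
collection built this way, so the headline statistics of that resource
recompute directly from the package.

## What is in the box

- **k-mer spectrum profiling** — `build_spectrum()`, `estimate_genome_size()`,
  `branch_frequencies()`, `genome_profile()`. Canonical k-mer spectra
  (k = 41); genome size as Σ<sub>m≥trough</sub> m·n(m) / peak, where the
  peak is the spectrum's refined coverage mode and the trough the
  multiplicity with fewest distinct k-mers below it (the error trough);
  heterozygosity and repeat proxies as the frequency of
  variant branches (balanced solid extensions, minor/major ≥ 0.25) and
  repeat branches (combined coverage > 1.75× peak) over the (k−1)-mer
  vertices of the read de Bruijn graph.
- **Read preparation** — `force_trim()`, `quality_trim()` (two-sided
  Phred/Mott at Q10), `read_gc_percent()`, `detect_ssr_contaminants()`
  (8/10 bp SSRs dominating both mates), `filter_reads_by_kmer()`
  (k = 75, Hamming ≤ 1, exact), `subsample_pairs()`.
- **Scaffold surgery** — `split_on_oversized_gaps()`, `extract_contigs()`
  (split on every N), `hard_mask_region()` (300 N masks),
  `resolve_ambiguities()`, `drop_short_scaffolds()`,
  `excise_contaminant_span()`.
- **Assembly metrics** — `ng_value()`/`ng_graph()` (NG50 substitutes the
  estimated genome size G for the assembly length: NG(x) is the length L
  at which scaffolds ≥ L first cover x·G/100), `assembly_stats()` with
  `glance()`/`tidy()`/`autoplot()`, `gene_sized_fraction()` (≥ 6.3 kb),
  `percent_genome_assembled()`, `pearson_r()`, `ols_fit()`.
- **Contamination screening** — `scaffold_signatures()` (GC % × average
  k-mer coverage per scaffold), `classify_candidates()` (rectangular
  inclusive gate), `plot_gc_coverage()`.
- **Haplotype consensus** — `resolve_overlaps()`, `score_phase_sets()`
  (per phase set, cumulative allele read depth per haplotype with indels
  weighted ½), `select_consensus_variants()`, `apply_variants()`; phased
  VCF I/O with GT/PS/AD.
- **Coordinate remapping** — `read_chain()`/`write_chain()` (UCSC chain),
  `lift_interval()`/`lift_bed()` (liftOver semantics with minMatch = 0.1
  and per-chain multiple mappings), `select_largest_span()`.
- **Enhancer orthology** — `local_align()` (seeded Smith–Waterman, BLASTN
  scoring +2/−3, gap 5+2L), `evalue_threshold()` (1/n fragments),
  `best_hit()`, `classify_rbh()` (reciprocal best hits by ≥ 1 bp overlap
  both ways), `trim_overlapping_hits()`, `alignment_summary()` (query
  coverage and length-weighted identity), `rbh_pipeline()`.
- **Synthetic data** — `simulate_diploid()`, `simulate_reads()`,
  `simulate_phased_vcf()`, `simulate_ortholog_tiles()`: every input above
  with truth variants, truth coordinates and truth chains, so the whole
  pipeline is testable without downloads.

## Worked example

Profile a simulated 100 kb diploid sample from its reads, then run the
enhancer-orthology pipeline over rearranged, 75%-identity scaffolds:

```r
library(cladeqc)

truth <- simulate_diploid(sim_genome_spec(100000, het_rate = 0.002, seed = 1))
reads <- simulate_reads(truth, sim_read_spec(coverage = 30, error_rate = 0,
                                             seed = 1))
genome_profile(reads)
#> # A tibble: 1 × 7
#>   est_genome_size gc_percent coverage_mode coverage variant_branch_freq
#>             <dbl>      <dbl>         <int>    <dbl>               <dbl>
#> 1         105463.       41.8            17     28.4             0.00347
#> # i 2 more variables: repeat_branch_freq <dbl>, estimable <lgl>

sim <- simulate_ortholog_tiles(20, 2000, 0.75, scaffold_shuffle = TRUE,
                               seed = 1)
res <- rbh_pipeline(sim$reference, sim$diverged, sim$tiles_ref, sim$chains)
c(rbh_rate = mean(res$is_rbh),
  query_coverage = mean(res$query_coverage),
  weighted_identity = mean(res$weighted_identity))
#>          rbh_rate    query_coverage weighted_identity
#>           1.00000          99.48750          75.15948
```

The genome-size estimate sits ~5% above the 100,000 bp truth — expected
for a heterozygous sample, where variant sites split k-mer coverage
between alleles and pull the fitted coverage peak down (on a homozygous
simulation the same estimator recovers the truth within 2%). The sample's
variant-branch frequency (0.0035) tracks the 2×10⁻³ simulated site
density (each heterozygous site contributes branch vertices on both sides
of its bubble), and all 20 tiles come back as reciprocal best hits at a
length-weighted identity of 75.2%, matching the simulated 75% divergence
regime.

The bundled resource tables are available directly:

```r
asm <- montium_table("assembly")
round(c(mean = mean(asm$est_genome_size), median = median(asm$est_genome_size)) / 1e6, 1)
#>   mean median
#>  196.4  198.1
```

## Documentation

The methods vignette (`vignettes/cladeqc-methods.Rmd`) describes each
model and procedure, its assumptions, the tunable parameters and their
defaults, the numerical choices (trough detection, tie-breaks, E-value
constants), what the synthetic generator does and does not emulate, and
known limitations.
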
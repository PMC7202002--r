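---
title: "Methods behind cladeqc: profiling, consensus and orthology for short-read clade genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind cladeqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladeqc)
```

cladeqc implements the bespoke computational stages used to build
multi-genome resources from single small-insert Illumina libraries, the
design used for the 23-genome *Drosophila montium* clade collection whose
published summary tables the package bundles (`montium_tables()`). This
vignette explains each method, its assumptions and tunables, the numerical
choices made where the design was open, and what the synthetic-data tests
do and do not demonstrate about real data.

## The study design the toolkit serves

One ~350 bp insert, PCR-free library per species, 100 bp paired-end reads
at roughly 30-35x: cheap enough to sequence dozens of species, but with no
long-range information. Assemblies built this way are fragmented in
repeats and sensitive to sample heterozygosity, so the pipeline around the
assembler carries unusual weight: read-level QC and decontamination before
assembly, aggressive scaffold surgery and haplotype consensus after it,
and completeness metrics that ask "can I study genes and enhancers with
this?" rather than "is the NG50 large?".

## Read preparation

`force_trim()` truncates reads to a fixed cycle count (some runs emit 101
bases instead of 100). `quality_trim()` implements two-sided Phred (Mott)
trimming: scanning inward from each end, the removed prefix/suffix is the
one maximising the cumulative sum of `q_threshold - q_i`; equivalently the
retained window maximises the sum of `q_i - q_threshold` over cut points
at the ends. Defaults Q10 and a 51 bp survivor floor. The trimmer never
lengthens a read and always returns a contiguous substring; for paired
input the pair is dropped when either mate falls below the floor, since
downstream assembly consumes pairs.

`detect_ssr_contaminants()` targets a contamination mode seen in several
libraries: highly abundant fragments that are pure 8 bp or 10 bp simple
sequence repeats in *both* mates of a pair. A read is SSR-dominated when
one period-p motif (any rotation, either strand; motifs canonicalised to
the lexicographic minimum over rotations of the unit and its reverse
complement) covers at least a `dominance` fraction of its length. The
dominance default of 0.8 is this package's own choice: in simulation it
separates pure-repeat reads (coverage ~1.0) from random reads (motif
coverage < 0.2) with a wide margin, and the flag requires both mates to
agree on the canonical motif, which drives the false-positive rate to
effectively zero (asserted over hundreds of random pairs).

`filter_reads_by_kmer()` removes pairs sharing any length-k window (k = 75
default) within Hamming distance 1 of a contaminant sequence, on either
strand; Ns mismatch everything, including themselves (conservative). The
implementation brute-forces window pairs in C++ and is checked against an
exhaustive R oracle; at read scale this is exact, not heuristic.

## k-mer spectrum profiling

`build_spectrum()` counts canonical k-mers (k = 41 by default, matching
the profiling convention of the resource tables) over all read windows,
skipping windows containing N. The spectrum satisfies, exactly, the
conservation identity `sum(multiplicity x count) = windows scanned`, which
the suite asserts.

`estimate_genome_size()` first finds the coverage peak — the argmax of
the 3-bin moving-median smoothed spectrum over multiplicities of at least
2, since the sequencing-error pile sits at multiplicity 1 — and then the
error trough, the multiplicity with the fewest distinct k-mers *before*
that peak. This peak-first formulation is deliberately not a naive
first-local-minimum scan: collapsed repeats put a second cluster high in
the spectrum whose sparse counts create spurious local minima beyond the
coverage peak, and error-free spectra have no error pile at all (their
trough correctly degenerates to the first multiplicity). The estimate is
total k-mer instances at or above the trough divided by the coverage
peak. One deliberate refinement:
the divisor is not the integer argmax but the count-weighted mean
multiplicity within [0.5, 1.5] x argmax (the repeat shoulder at >= 2x the
peak stays excluded). At ~18x k-mer coverage the argmax is quantised to
+-1 multiplicity bin, which alone injects a ~5% genome-size error; the
refinement removes it, and recovery on 30x error-free simulations is
within 2%. Spectra with no interior trough-and-peak structure (coverage
too low) are reported `estimable = FALSE` with `NA` fields, mirroring how
low-coverage samples appear in the published tables.

`branch_frequencies()` approximates de Bruijn graph heterozygosity and
repeat proxies from the solid k-mer set (multiplicity >= trough). Every
(k-1)-mer vertex with two or more solid single-base extensions on a side
is classified: a *repeat branch* when the top two extension counts sum to
more than `c_rep` x coverage peak (collapsed repeat copies stack
coverage), a *variant branch* when the minor/major ratio is at least
`r_min` below that coverage (heterozygous alleles split coverage roughly
in half). Defaults `r_min = 0.25`, `c_rep = 1.75` sit between the
expected diploid-allele signature (two branches near half the peak each,
ratio ~1, combined ~1x peak) and the collapsed-repeat signature (combined
>= 2x peak) with margin on both sides; both are exposed as arguments.
These estimators are approximations built from one-line descriptions of
spectrum-based profilers, so the package claims — and the tests assert —
property-level behaviour only: near-zero frequencies on homozygous
repeat-free genomes, and strict monotonicity in the generating
heterozygosity and repeat copy number under paired simulation seeds. No
numeric equality with any external profiler is claimed.

## Scaffold surgery

All coordinates are 0-based half-open internally (BED/chain convention);
VCF positions are 1-based in I/O and converted at the boundary.

- `split_on_oversized_gaps()`: N-runs longer than `max_gap` are
  implausible against a 350 bp insert (scaffolders occasionally emit gaps
  of tens of kb) and are removed by splitting. The threshold is inclusive
  (a run of exactly `max_gap` survives) and is configuration per library —
  200-600 bp is the realistic range, 600 the default.
- `extract_contigs()` splits on *every* N, single Ns included: the
  conservative contig convention under which the published contig NG50s
  are computed, because single-N seams frequently mark tandem-allele
  misassemblies rather than honest gaps.
- `hard_mask_region()` replaces a span with exactly 300 Ns (default):
  widening single-N seams to a fixed-width mask lets a gap-filling pass
  re-extract flanks beyond the original misassembly boundary.
- `resolve_ambiguities()` assigns each non-N IUPAC code uniformly at
  random among its encoded bases, deterministically under a seed; N is
  preserved.
- `drop_short_scaffolds()` removes scaffolds under 1 kb (inclusive keep at
  exactly the threshold).
- `excise_contaminant_span()` trims terminal contaminant spans and splits
  on internal ones, choosing the mode automatically from the span
  position.

Every operation conserves non-gap base content except where removal is the
stated effect, and splitting commutes with contig extraction (asserted as
a property).

## Assembly metrics

`ng_value()` implements NG(x): sort scaffold lengths descending,
accumulate, and report the length at which the running sum first reaches
x% of the *estimated genome size*. Unlike N50 this does not reward
haplotype-inflated assemblies, and it is undefined (NA) when the assembly
never reaches x% of the genome — the "curve never intersects the x-axis"
case that itself diagnoses either heavy repeat loss or an inflated
assembly. `assembly_stats()` returns an object with `glance()` (one-row
summary), `tidy()` (scaffold and contig NG graphs) and `autoplot()` (the
NG graph). `gene_sized_fraction()` reports the percentage of the assembly
in scaffolds of at least 6.3 kb — an upper estimate of the average
Drosophila gene length — the pragmatic "can I study genes?" measure.
`pearson_r()` and `ols_fit()` are thin wrappers over `stats::cor.test()`
and `stats::lm()` (complete pairs/rows only), the exact procedures used
for the published correlation of estimated genome size with log10 repeat
content and the contiguity regressions.

## Contamination screening of assemblies

`scaffold_signatures()` places each scaffold (>= 1 kb) on the GC % x
average k-mer coverage plane, coverage being the mean multiplicity of the
scaffold's canonical k-mers in the *read* spectrum. Microbial contaminants
differ in base composition and in stoichiometry, so they form separate
clusters; `classify_candidates()` applies a rectangular inclusive gate.
The gates are sample-specific configuration read off the observed plot —
the bundled *D. pectinifera* gate values (GC 35-66, coverage 40.5-68)
are a test fixture, not defaults. Candidate confirmation against sequence
databases is deliberately outside the computational core: the module
accepts a confirmed id list and hands excision to the scaffold-surgery
ops, avoiding any external database dependence.

## Phase-set majority-haplotype consensus

Short-insert assemblies of heterozygous samples come out as haplotype
mosaics, creating recombinant sequences absent from the sample. The
consensus procedure converts a read-back phased call set into one
deterministic haplotype choice per phase block:

1. `resolve_overlaps()`: within each connected cluster of variants whose
   reference spans intersect (shared start positions included), keep one
   variant — the structural variant if present, else the one with the
   greatest alt read depth. Overlapping calls otherwise derail phasing.
2. `score_phase_sets()`: per phase set, sum the read depth of the allele
   on each haplotype, weighting indels and SVs by 0.5 (indel read counts
   are less reliable due to alignment ambiguity; SNPs weigh 1). The
   greater weighted sum names the majority haplotype.
3. `select_consensus_variants()`: phased variants whose alt allele sits on
   the majority haplotype are retained; those whose majority-haplotype
   allele is the reference are dropped (equivalent, for consensus
   building, to emitting homozygous-reference records). Unphased variants
   keep the deeper allele.
4. `apply_variants()` substitutes the retained alleles with VCF-anchored
   indel semantics and hard-errors on any reference mismatch, naming the
   offending `chrom:pos`.

Open points resolved as package policy: "read count" means the per-allele
AD-style depth (the only per-allele count the described toolchain
provides); the SV threshold is 50 bp or a symbolic allele; score ties go
to haplotype A (the first allele of the genotype ordering) and unphased
ref/alt depth ties drop the variant — both deterministic and conservative;
two overlapping SVs resolve by alt depth, then longer reference span. The
suite verifies per-block decisions against an oracle that enumerates both
haplotype options, and end-to-end consensus recovery at depth 20 with
30% of blocks phase-swapped.

## Chain parsing and coordinate remapping

`read_chain()`/`write_chain()` handle the UCSC chain format with load-time
verification that block sizes and gaps sum to the header spans (a
violation is a parse error naming the chain). `lift_interval()` projects
every interval base falling inside a gapless block through the block
offsets, chain by chain. A chain's remapping is reported when at least
`min_match` (default 0.1) of the interval's bases project — measured
against the source interval length, the literal reading of the liftOver
`-minMatch` flag — and the reported interval spans min to max projected
position, bridging chain gaps interior to the projection, because 2 kb
features routinely cross indel gaps within one chain. `multiple = TRUE`
reports one remapping per qualifying chain; `select_largest_span()`
retains the larger coordinate span when several qualify (ties: more bases
mapped, then lower chain id). Minus-strand query coordinates follow the
UCSC reversed-sequence convention and are converted to forward coordinates
on output. The implementation is validated against a per-base projection
oracle that walks blocks one base at a time, on random chains including
minus-strand and gap-bridging cases; no claim is made about matching the
external liftOver binary's undocumented multi-chain merging.

## Enhancer orthology by reciprocal best hits

The orthology test for a remapped fragment is classical RBH: the best
local alignment of the candidate ortholog back onto the source genome must
overlap (>= 1 bp) the fragment's original coordinates, and the best
alignment of the fragment onto the second genome must overlap the
remapped interval. `local_align()` provides the alignments: Smith-Waterman
with affine gaps under the BLASTN scheme +2/-3, gap open 5, extend 2.
Pairs small enough for full dynamic programming (`dp_limit`, default
4.5e6 cells) are aligned exhaustively — on those pairs the top hit
provably attains the Smith-Waterman optimum, asserted against an
independent DP oracle. Genome-sized subjects are screened BLAST-style:
exact 11-mer seeds, diagonal clustering, an x-drop ungapped extension
filter, then full DP within windows around surviving clusters; additional
HSPs come from masking the query and realigning. E-values use the
Karlin-Altschul form `K * m * n * exp(-lambda * S)`; lambda = 0.625 and
K = 0.41 are configuration defaults for this scoring scheme, and the
package asserts only the E-value's monotonicity (decreasing in score,
increasing in search space), not the constants. The search cutoff is the
reciprocal of the fragment count (`evalue_threshold()`), e.g. 1/3457 =
0.00029 for the enhancer tile set. Externally produced 12-column tabular
hits can be read with `read_tabular_hits()` and used in place of the
built-in engine.

For similarity summaries, `trim_overlapping_hits()` processes hits in
descending score order, removing hits nested in occupied query positions
and trimming partial overlaps to their unoccupied portions (identity kept
as-is; subject coordinates of trimmed hits adjusted proportionally and
flagged approximate — downstream statistics use query-side lengths only).
`alignment_summary()` then reports query coverage and length-weighted
percent identity over the now-disjoint hits.

## The synthetic-data generator

Every input the pipeline consumes can be generated: diploid genomes with
tunable GC, repeat families, heterozygosity (geometric indel lengths,
SNP:indel ratio, SVs as indels >= 50 bp), 100 bp read pairs from ~350 bp
inserts with uniform substitution errors, phased call sets with per-allele
depths, phase blocks and controllable block-swap errors, and diverged
~2 kb ortholog tiles with exact truth chains. Design choices: base
composition is i.i.d. at the GC target (no dinucleotide structure —
sufficient for every property tested); reads carry their truth coordinates
in their names and as columns, so coverage and error-rate oracles need no
mapper; one global seed expands to fixed per-stage child seeds so stages
re-run independently remain reproducible; haplotype B is constructed by an
independent code path from the one `apply_variants()` uses, so the
generator round trip is a genuine cross-check rather than a tautology.
Tile divergence uses substitutions only: truth chains stay exact identity
blocks and per-tile identity concentrates within ~0.7 points of the
target at 2 kb, at the cost of not exercising indel divergence in the
end-to-end orthology regime (indel handling is exercised separately by
the aligner and consensus tests). Scaffold shuffling cuts at spacer
midpoints, so tiles never straddle breakpoints and the truth tile BED
stays exact.

What passing these tests shows about real data — and what it does not:
the algorithms are exact or property-correct on inputs matching their
assumptions (uniform coverage, substitution-dominated divergence, honest
insert sizes). Real libraries add GC-coverage bias, error profiles
concentrated at read ends, PCR and optical artifacts, and repeat
structure far richer than implanted families; the published per-assembly
numbers (per-species NG50s, BUSCO completeness, per-species remapping
counts) depend on the deposited ~35x read sets and are therefore outside
what synthetic runs can reproduce. The package instead demonstrates the
qualitative regime on its own data: near-total remapping success and
>= 90% RBH at 75% identity across rearranged scaffolds.

## Problem sizes used by the test suite

Simulations run at 30-100 kb genome scale and 15-30x coverage, 20-50
tiles of 2 kb for the orthology regimes, and oracle sweeps of hundreds of
random cases per property. These sizes were chosen so the full suite and
the acceptance script each complete comfortably on one CPU while keeping
every estimator in its intended operating regime (k-mer coverage ~18x,
binomial errors small relative to the tolerances tested).

## Worked example

```{r example, eval = FALSE}
library(cladeqc)
truth <- simulate_diploid(sim_genome_spec(100000, het_rate = 0.002, seed = 1))
reads <- simulate_reads(truth, sim_read_spec(coverage = 30, seed = 1))
genome_profile(reads)

sim <- simulate_ortholog_tiles(50, 2000, 0.75, scaffold_shuffle = TRUE,
                               seed = 1)
res <- rbh_pipeline(sim$reference, sim$diverged, sim$tiles_ref, sim$chains)
mean(res$is_rbh)
plot_identity_coverage(res)
```

## Known limitations

- The branch-frequency estimators are property-calibrated approximations;
  their absolute values are not comparable across k or coverage regimes.
- The aligner's seeded mode can miss alignments containing no exact
  11-mer (below ~60% identity); within the tested regimes this does not
  occur, and the full-DP mode has no such blind spot.
- `-multiple`-style lifts report one interval per chain and bridge
  within-chain gaps; sub-chain splitting of a single feature is not
  modelled.
- The read simulator has no quality-dependent or position-dependent error
  structure beyond the optional quality ramp.
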
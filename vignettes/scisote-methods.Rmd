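---
title: "scisote: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scisote: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`scisote`, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open. It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

# The analysis pipeline

## Read processing

A read is **full-length (FL)** when both the 5' and 3' primer are found in
one orientation (forward tried first, then the reverse complement; the
orientation with more primer hits wins). One primer hit gives `non-FL`,
none gives `unknown`; the three statuses partition any read set. Primer
search tolerates `max_mismatch = 2` substitutions (HiFi-grade reads are
near-perfect; two mismatches absorb residual errors without hitting
random 23-mers) inside a window of three primer lengths at either end.
The cell barcode (16 nt) and UMI (10 nt) sit directly after the 5'
primer — a 10x-bead-style layout — and a polyA run of at least 10 A's
ending within 5 nt of the 3' primer is trimmed from the insert. A cDNA
that genuinely ends in adenines is indistinguishable from the tail start,
so round-trips are exact only up to that trailing-A boundary; tests
account for this explicitly.

**Barcode correction** is exact-match first, then unique
Hamming-distance-1 rescue: a raw barcode at distance 1 from exactly one
whitelist member is corrected to it; distance >1 or a tie is dropped.
The radius of 1 bounds false merges and is sufficient for
substitution-dominated errors on accurate reads; whitelists with pairwise
distance >= 3 (which the simulator's `make_whitelist()` guarantees) make
every single-substitution error uniquely correctable. **UMI collapse is
exact-match** — consensus-read error rates make 1-mismatch UMI clustering
unnecessary, and it would risk merging genuinely distinct molecules at
10-nt UMI length. A molecule is a distinct (barcode, UMI, feature)
triple; the count of a (barcode, feature) pair is its number of distinct
UMIs.

## Isoform collapse and classification

Spliced alignments are collapsed into nonredundant isoforms per
(chromosome, strand):

* **Multi-exon reads** merge when their intron chains are identical and
  their terminal ends lie within a tolerance of 50 nt at each end
  (`tol_5`, `tol_3`). Fifty nucleotides absorb polyA-priming and TSS
  jitter without merging distinct start/end sites. Merging is the
  transitive closure of this pairwise relation; the representative model
  of a group is its **longest member read** (ties: leftmost, then read
  id). Using an actual member rather than the union span makes collapse
  provably idempotent: representatives of two distinct groups can never
  be directly mergeable, or their groups would already have merged.
* A read whose chain is a strict 3'-anchored suffix of another's (a
  5'-shortened model) is **never merged** — it keeps its own isoform.
  This preserves genuine alternative-TSS and degradation products, which
  matter here because 3'/5'-partial transcripts are a finding, not noise.
* **Mono-exon reads** merge at reciprocal overlap >= 0.5.
* Collapsed isoforms are grouped into gene clusters (overlapping spans on
  one strand) and numbered `PB.<cluster>.<n>`.

**Structural classes** follow the standard long-read taxonomy. FSM: chain
equals a reference transcript's; ISM: chain is a consecutive sub-chain of
one; NIC: all splice sites annotated but the chain is new; NNC: at least
one novel site; `other`: antisense, intergenic, or unmatched mono-exon.
Only FSM/ISM/NIC/NNC enter downstream matrices. The gene assigner
(replacing an external comparison tool) takes the same-strand gene with
the largest exonic overlap, minimum 50 nt. CAGE support means the 5'
terminal position lies within 200 bp of a same-strand peak; strand
awareness is this package's choice where the convention is ambiguous —
antisense peaks should not certify a sense TSS.

## ORF prediction and integrity typing

`predict_orf()` scans the three forward frames of the transcript-oriented
sequence (orientation is resolved upstream, so reverse frames would only
add noise) and enumerates four candidate shapes: complete (ATG...stop),
5'-open (frame start to first stop, no upstream ATG), 3'-open (ATG to
sequence end, no stop), and open at both ends (a stop-free, ATG-free
frame). The longest candidate wins; ties prefer a start codon, then a
stop codon, then the leftmost start, then the lowest frame (so a
complete ORF beats an equally long open one). `min_length_aa = 100` is
the conventional coding-potential threshold; anything below maps to type
`others`. The remaining mapping is mechanical: start+stop = `complete`,
start only = `three_prime_partial`, stop only = `five_prime_partial`,
neither = `internal`. An exhaustive-enumeration oracle in the test suite
checks the finder on random sequences.

## Expression matrices

Matrices are `SingleCellExperiment` objects, features in rows.
**CPM/10** normalization scales each cell to copies per 100,000
molecules; the denominator is the cell's total deduplicated molecules
across the features of that matrix's kind — a UMI-level reading of
"mapped reads", consistent with UMI-count matrices (all-zero cells are
left at zero with a warning). Isoform matrices drop features detected in
fewer than 5 cells. Spike-in evaluation reports Pearson correlation on
log10(x + 1) between true copies per cell and mean observed UMIs per
cell per spike-in gene (log scale is the standard convention for
dilution-series spike-ins; fewer than 3 distinct abundance levels flags
the correlation undefined), plus a truth-versus-assigned isoform
confusion matrix whose off-diagonal counts are mis-assignments.
Saturation curves use nested subsampling (one permutation, prefixes per
depth), which makes them monotone by construction.

## Locus-level TE quantification

The assignment of a read to a TE locus applies, in order: (1) only
uniquely aligned reads count — pinned as primary, non-secondary,
non-supplementary, mapping quality >= 30 (common practice for
long-read aligners); (2) overlap with each locus is the total
**exon-block** intersection — a spliced cDNA alignment should not claim
intronic TE bases; (3) candidate loci must contain the alignment's
genomic start or end position — this endpoint rule (using the genomic
span endpoints of the primary alignment) suppresses reads that merely
pass through a repeat internally; (4) the longest overlap wins; (5) ties
break by overlap, then leftmost locus start, then locus id. Strand is
ignored: antisense TE transcription is real, and the annotation strand
refers to the repeat consensus. Reads with supplementary segments are
routed exclusively to chimera detection. Dropping the endpoint rule can
only grow the assigned set (a monotonicity property the tests assert).

Cell x locus UMI matrices roll up by subfamily, family and class through
summation; per-locus activity summaries average only over cells where
the locus is detected.

**Chimera detection**: a read with two or more alignment segments yields
a TE-gene link when one segment passes the locus-assignment rules and a
different segment overlaps a protein-coding gene's exons by >= 50 nt.
Links deduplicate by (barcode, UMI, locus, gene) and aggregate to a
locus x gene UMI table.

## Stage-level analyses

**Stage-specific selection**: for each adjacent stage pair, log2 fold
change of stage-mean CPM/10 (pseudocount 1) plus a two-sided Wilcoxon
rank-sum test on per-cell CPM/10; a feature is selected when any pair
shows |logFC| > 1 and p < 0.01. The magnitude reading of the fold-change
threshold is deliberate: maternally loaded transcripts *fall* across the
early boundaries, and a one-sided reading would miss the oocyte-peaked
cluster entirely. The external NB-GLM machinery this replaces is out of
scope; the selection contract — thresholds and peak clustering — is what
is preserved. Selected features cluster by the stage of their maximal
mean; the number of clusters is the number of stages with at least one
peaking feature (in the embryo series, six for genes/isoforms and five
for TE loci arise from the data, not from a fixed k). Note the rank-sum
test needs roughly 8 cells per group before p < 0.01 is attainable at
all; pairs with fewer than 2 cells are skipped with a warning.

**Isoform diversity** assigns each expressed gene, per stage (cells
pooled), to a category by its number of detected isoforms (1...5, >5).
**Major-isoform ratio** is the most abundant isoform's share of the
gene's pooled UMIs, reported only for genes with more than 5 UMIs; it is
1 exactly when one isoform is detected.

**Isoform switching** between two stages: isoform fraction IF = isoform
UMIs / gene UMIs on pooled counts; dIF = IF2 - IF1; the isoform p-value
is a two-sided exact test (hypergeometric) on the 2x2 table of isoform
versus other-isoform UMIs across the stages; the gene p-value is the
Bonferroni-adjusted minimum isoform p; both sets are BH-adjusted.
Switched requires |dIF| >= 0.1 (the conventional minimum effect size for
isoform-fraction changes) and isoform q < 0.05 and gene q < 0.01. Genes
under 10 pooled UMIs in either stage are skipped with a recorded reason.
The procedure is symmetric: swapping the stages negates dIF and leaves
the q-values unchanged.

**TE-gene adjacency**: TE loci averaging more than 5 UMIs per cell are
paired with genes by the gap between closest interval edges, strand
ignored (0 when overlapping). Pairs under 10 kb are `adjacent`; pairs
over 1 Mb are `non_adjacent`; in-between pairs are excluded. Genes on a
different chromosome are unlinked and treated as non-adjacent (distance
infinity) — within a toy chromosome of a few hundred kb a literal 1 Mb
separation cannot exist, so the gene-free chromosome carries the distal
loci. Correlation is Pearson on log10(CPM/10 + 1) across shared cells;
zero-variance vectors are flagged undefined rather than silently dropped.

# The synthetic-data generator

## What it emulates

The generator builds a toy reference and molecules with the statistical
structure the analyses assume:

* **Gene models** with 3-6 exons and 1-6 isoforms by internal exon
  skipping. The full transcript is one ORF (220-320 codons) between
  short UTRs. Exon boundaries inside the CDS are codon-aligned and
  internal exons are fully coding, so skipping preserves the frame; a
  recurring 9-mer in the codon body places stop codons in both shifted
  frames, so no spurious frame can outrun the annotated ORF. This makes
  ORF-integrity truth exact by construction rather than approximate.
* **Truncations** per molecule with per-stage rates (defaults: 3'-partial
  at 0.25 in the first two stages and 0.05 after, emulating the
  maternal-transcript pattern; 5'-partial 0.05, internal 0.02
  everywhere). A 3'-partial molecule ends strictly before the stop
  codon; a 5'-partial starts strictly after the ATG; every truncated
  molecule keeps >= 110 codons of open frame so typing reflects codon
  content, not length censoring.
* **TE loci** from a small class/family/subfamily hierarchy (LINE/L1
  with Lx7-like subfamilies, LTR/ERVL with MERVL-like and MT2-like,
  LTR/ERVK, SINE, DNA, Satellite). A configurable fraction sits in
  intergenic gaps near genes; the rest live on a gene-free chromosome.
  TE molecules are contiguous sub-intervals of a locus, so both
  endpoints fall inside it.
* **Chimeric molecules** concatenate a TE segment and a gene segment and
  emit a primary (gene) plus supplementary (TE) truth alignment.
* **Spike-ins** on a dedicated chromosome: gene-level copies double
  across genes from a configurable base, split over 2-3 isoforms.
* **Reads**: 5' primer + barcode + UMI + cDNA + polyA + 3' primer, half
  reverse-complemented; PCR duplicates at Poisson rate 0.2 share
  (barcode, UMI, molecule); substitution errors optional (default 0 —
  consensus reads — configurable up to a few percent); barcode
  corruption as a separate, truth-recorded step. Cell barcodes are
  generated with pairwise Hamming distance >= 3.
* **Truth**: one row per molecule (cell, UMI, source feature, truncation,
  chimera partner) and spliced truth alignments in SAM with
  `read_id|barcode|UMI` names, so no external aligner is ever needed;
  the pipeline equally accepts a real aligner's SAM.

Expression-level companions (`simulate_stage_counts()`,
`simulate_switch_counts()`, `simulate_coupled_te_gene()`) generate count
matrices directly for the operating-characteristic studies, where
sequence-level simulation would add nothing but runtime. In the coupled
TE-gene study, each gene-adjacent TE locus shares a per-cell log-normal
activity factor (sd 0.8) with its neighbour gene while distal loci get
independent factors; the reference there uses ~20 kb intergenic gaps so
that each near locus has exactly one gene within the 10 kb adjacency
distance — adjacency then coincides with planted coupling, which is the
contrast the study is meant to exhibit. That study uses 100 cells,
matching the order of magnitude of a single-cell embryo series.

## What it does not emulate

No concatemeric (multi-cDNA) reads — the artifact starts from
demultiplexed full-length reads; no indels or homopolymer artifacts
(substitution-only errors); no UMI errors; no amplification-bias
structure beyond a flat duplicate rate; no multi-mapping ambiguity
between TE copies (truth alignments are unique, so the `not_unique`
branch is exercised with constructed low-quality records rather than
realistic repeats); and incidental split reads do not occur, so chimera
detection on synthetic data faces no structural false-positive pressure
— its specificity checks cover mis-assignment of genuine split reads,
not spurious splits. Passing tests therefore demonstrate correctness of
the rules and calibration of the statistics under these conditions, not
robustness to alignment ambiguity in real repeat-rich genomes.

# Numerical and testing choices

Coordinates are 0-based half-open everywhere internally; GTF is written
1-based inclusive and rmsk/BED 0-based half-open, matching the formats.
Determinism: every generator takes a seed and derives child seeds
arithmetically (kept below 2^31); identical inputs give byte-identical
reference files. Degenerate inputs: empty alignment sets collapse to
empty model tables; empty read sets summarize to zeros without division
errors; all-zero cells normalize to zero with a warning; ambiguous
barcodes drop rather than guess.

Tests pit each rule-based component against an independent naive oracle
(linear-scan TE assignment, quadratic all-pairs collapse, exhaustive
3-frame ORF enumeration, exhaustive Hamming scans, hypergeometric tail
sums) on randomized instances under fixed seeds. The validation studies
use 5,000 reads x 500 loci for TE-assignment equivalence; 2,000
molecules for ORF-typing recovery; twenty 100-read instances for
collapse; 8 spike-in levels x 10 cells; 2,000 features (200 planted,
8 stages x 20 cells) for stage-specific selection; 200 genes with 20
planted switches plus ten 500-gene null runs; 10 chimera pairs over a
~5,000-molecule background; and 10,000 reads against a 100-barcode
whitelist for correction. These sizes give the selection and FDR
statistics enough events to be meaningful while keeping a full run in
minutes on one CPU.

# Known limitations

The collapse tolerance model (50 nt terminal windows with transitive
closure) can chain gradually shifting ends into one model in pathological
inputs; real data rarely produce such ladders, and the quadratic oracle
defines the intended semantics. The stage-specific test is rank-based and
needs several cells per stage for any power; with 2-3 cells per stage
nothing can pass p < 0.01. Gene-level quantification assigns each read
to a single best gene (largest exonic overlap) with no multi-gene
rescue. The switch test pools cells within a stage, trading cell-level
variance modelling for an exact small-count test.
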
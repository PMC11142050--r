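---
title: "Haplotype-guided de novo MHC assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-guided de novo MHC assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The human MHC (chr6: 28,509,120–33,481,577 on GRCh38, ~5 Mb) is the most
polymorphic region of the genome. Reference-based alignment of short reads
systematically under-calls its variation: novel heterozygosity, copy-number
variation at complement C4, and the large class II structural haplotypes
driven by the *HLA-DRB* paralogs (*DRB1* with *DRB5* = DR2, with *DRB3* =
DR3, with *DRB4* = DR4; DR8 haplotypes carry no second expressed paralog)
all defeat a single linear reference. Trio binning solves this by
partitioning reads between parental assemblies, but trio data are rarely
available in disease cohorts.

This package implements a proxy-parental alternative at desk scale: each
individual's HLA-DRB1 first-field genotype and C4 status select one or two
**best-matching guide haplotypes** (BMHs) from a panel; reads are binned
against each BMH and assembled *de novo* per guide, producing one
pseudo-haploid consensus per assigned haplotype rather than one mixed
diploid assembly. The guide steers read selection, scaffold ordering and
orientation — the sequence content itself comes from the reads.

## Pipeline

For each individual, `run_individual()` executes:

1. **Read QC** (`qc_reads()`): pairs carrying a ≥ 20 bp G homopolymer
   (the two-channel Illumina poly-G artifact) are dropped whole; optional
   seeded subsampling; leading/trailing bases below Q3 or N stripped;
   4 bp sliding windows truncate at the first window of mean quality ≤ 15;
   mates shorter than 40 bp discard the pair. Adapter removal is assumed
   upstream.
2. **BMH assignment** (`assign_dr_class()`, `assign_bmh()`): first-field
   DRB1 allele groups map onto DR classes through an editable table
   (defaults: 01/10→DR1, 15/16→DR2, 03/11/12/13/14→DR3, 04/07/09→DR4,
   08→DR8). Homozygous individuals receive one BMH; heterozygous, two.
   Within a class, a guide whose C4 annotation matches the individual's
   (exact copy number > long/short form > class default) wins.
   Recombinant haplotypes are not modelled. A deliberately naive k-mer
   genotyper (`naive_drb1_genotype()`) is included as plumbing so
   simulations run end to end; it counts reads carrying k-mers unique to
   one allele group's exemplar and calls a second allele when its count
   reaches 25% of the top (an invented threshold, documented as such). It
   is not an HLA typing tool.
3. **Binning** (`bin_reads()`, and the driver): reads are mapped
   end-to-end (seed-and-extend, seeds of 15 bp, scoring match 0 /
   mismatch −6 / gap open −5 / extend −3) and accepted at score ≥ −0.6 per
   read base — a 150 bp read tolerates exactly 15 mismatches. A pair is
   mapped if either mate maps. For heterozygous individuals the driver
   additionally partitions mapped pairs to the better-scoring BMH, ties
   going to both bins. This competitive partition is the package's design
   choice: it realises the trio-binning idea the proxy-parental framing
   promises, and without it every heterozygous site would be assembled
   from a 50/50 allele mixture and resolved by coin flip.
4. **Superblock assembly** (`build_superblocks()`, `assemble_pool()`):
   the covered guide is tiled into 50 kb spans overlapping by 5 kb
   (a deterministic simplification of coverage-contiguity blocks; the
   downstream role — localised de novo assembly — is unchanged), and each
   tile's pairs are assembled with a de Bruijn graph at k = 51 (odd, so no
   k-mer is its own reverse complement). Reads that map to no BMH form a
   separate pool, also assembled at k = 51.
5. **Graph cleaning** (`simplify_graph()`): coverage cutoff
   (`auto` = max(2, ⌈median/10⌉)), tip clipping below 2k bp, and
   coverage-aware bubble popping (below).
6. **Cross-mapping filter** (`filter_cross_mapping()`): unmapped-pool
   contigs aligning to the alternative BMH (or decoys) at ≥ 90% identity
   over ≥ 50% of their length are removed, implemented as 100 bp windowed
   end-to-end mapping (a 100 bp window at score ≥ −60 is exactly ≤ 10
   mismatches). Survivors are combined with the mapped-origin contigs
   *before* redundancy removal.
7. **Supercontig merging** (`merge_supercontigs()`): greedy suffix–prefix
   merging at ≥ 40 bp overlap and ≥ 95% identity, containment removal,
   longest-first. Only *unambiguous* overlaps merge: every de Bruijn
   junction leaves a k−1 = 50 bp exact overlap that would otherwise
   re-join repeat arms into exactly the false contractions the graph was
   careful to avoid.
8. **Polish** (`polish_contigs()`): reads are mapped back; a column with
   ≥ 5 covering reads whose alternative base (or length-1 indel) exceeds
   50% support is corrected. One pass; iterative polishing is out of
   scope.
9. **Scaffolding** (`scaffold_paired()`): contigs link when ≥ 3 pairs
   straddle them with consistent orientation; gap = max(10,
   round(insert − d1 − d2)) averaged over links; orientation conflicts
   keep only a clear majority; branching keeps the best-supported link and
   ties stay unlinked, so chains are strictly linear.
10. **Placement** (`score_placement()`, `place_and_filter()`): scaffolds
    are cut into 400 bp windows mapped on the guide. The location score is
    the aligned bp supporting the modal implied placement (implied starts
    clustered with a tolerance of 5 kb + 10% of scaffold length) over
    total aligned bp; the orientation score is the modal-strand aligned bp
    fraction. Scaffolds with location < 0.1, or location < 0.3 and
    orientation < 0.75, are demoted to the unplaced output (demoted, not
    discarded — the ambiguity in what the original filter does is resolved
    in favour of keeping data). Survivors are ordered by assigned start,
    minus-strand scaffolds reverse-complemented, and concatenated with N
    gaps sized from guide spacing (minimum 10 N). The output FASTA has one
    placed-consensus record plus the unplaced records.

Estimated per-haplotype depth (total retained bp / 2 × guide length) below
25× raises a hard warning — assemblies fragment and full-length consensus
is not achieved — and 25–30× a soft advisory; 30× or more is recommended.

## The bubble model: heterozygosity vs tandem repeats

A bubble (two branches between the same flanking nodes, ≥ 95% identical)
can be three different things, and the coverage of its branches says
which:

* **noise** — one branch far below the other (minor ≤ 50% of major, or
  ≤ 5×): sequencing error or residual reads from the other haplotype that
  the competitive binning let through. Popped, keeping the major branch.
* **heterozygous allele** — balanced branches, each at roughly *half* the
  graph-wide median coverage. In a mixed (single-BMH, homozygous-class)
  bin each allele carries half the reads. Popped: the product is a
  pseudo-haploid consensus, and unresolved heterozygosity is precisely the
  het-inclusion error the evaluator quantifies.
* **near-identical tandem copies** — balanced branches at *full* median
  coverage (both copies contribute). Kept: collapsing them welds the
  copies into a single one and emits a confident, gap-free contraction of
  several kb. The C4 block — tandem ~5 kb units differing by a handful of
  substitutions and a ~1 kb insertion — is the canonical case. Kept
  branches fragment the region into short contigs that place with gaps,
  so unresolvable repeats appear as N gaps (missing sequence) rather than
  as false structural variants, mirroring how C4 shows up as alignment
  gaps, not errors, in real short-read MHC assemblies.

The 75%-of-median boundary between the last two cases assumes reasonably
uniform coverage; strong capture bias would blur it.

## Evaluation

`anchor_align()` compares an assembly to a truth sequence via maximal runs
of 63-mers unique in both sequences (kept at ≥ 100 bp), chained by
weighted LIS, with inter-anchor segments aligned by affine-gap DP.
`call_errors()` then classifies: single-base substitutions are base-call
errors; indels ≥ 1 bp are structural (SV) errors. An SV whose sequence is
repetition of a ≤ 100 bp motif present immediately adjacent in the truth
is a tandem expansion/contraction; an SV overlapping the repeat mask by
≥ 1 bp is repeat-associated (the overlap rule is a package decision — the
source material does not define one). Each percentage is 100 × event bp /
assembled length; the three categories sum exactly to the total. Event bp
(not event counts) is used in the numerator, consistent with dividing by
total length. Two deliberate exclusions:

* assembly N gaps and unaligned ends are missing sequence, not errors —
  percentages are over assembled (non-N) bp;
* `attribute_het_switch()` splits base-call mismatches into true errors
  vs improper inclusion of the other haplotype's allele, by lifting each
  mismatch position through an anchor alignment of the two truth
  haplotypes.

`assembly_stats()` (N50 by its minimal-set definition),
`unique_kmer_ratio()` (distinct canonical k-mers occurring exactly once /
reads of length ≥ k; the per-read normalisation is a declared choice, and
the tested contract is comparative — more divergent read sets score
higher), `call_variants_vs_reference()` (left-normalised, anchored VCF
records) and `merge_haplotype_variants()` (1/1, 0/1, 1/2 genotypes)
complete the reporting.

## The simulator as study design

`generate_guide_panel()` builds all guides from one ancestor backbone so
that differences between guides are exactly the features the pipeline must
handle:

* **class II cassettes** at a fixed locus: DR1 3 kb, DR2 8 kb, DR3 6 kb,
  DR4 14 kb, DR8 none. Only the relative structure (DR4 largest, DR8
  absent) is biological; the sizes are desk-scale picks that make
  cassette-mismatch alignment breaks obvious.
* **C4 block**: 1–3 tandem units of ~5 kb; C4A and C4B differ by 10
  substitutions; long forms carry a 1 kb internal insertion. Real C4A/C4B
  are even more similar — the simulator errs toward assemblability while
  preserving the failure mode.
* **interspersed repeats** at `repeat_density` (default 0.2): Alu-like
  (300 bp), LINE-like (1 kb) and MER-like (600 bp) families, each copy
  ~10% diverged from its consensus, as genomic repeats are. The real MHC
  is ~50% repetitive; 0.2 keeps desk-scale assemblies non-trivial without
  dominating them.
* **backbone divergence** (default 0.004/bp private substitutions per
  guide): real MHC reference haplotypes differ at the SNP level on top of
  their structural differences (~0.4–0.9% pairwise). This matters beyond
  realism: with byte-identical backbones no read could ever be attributed
  to a haplotype, and the proxy-parental design would be untestable.
* a 1 kb allele-group-specific **DRB1 block** (exemplars via
  `drb1_exemplar_panel()`) that gives the naive genotyper something to
  find.

`simulate_individual()` mutates each guide at `divergence` (substitutions)
and `indel_rate` (lengths 1–10), recording every event so
`apply_variants()` reconstructs the haplotype byte-for-byte; repeat
intervals are lifted through the indels. Divergence ≥ 0.1 is rejected —
it would break the guide-binning assumption and models no human scenario.
`simulate_reads()` draws fragments uniformly (Gaussian insert, default
500 ± 50), flips fragment strand at random, injects per-base errors at
`base_error` (baseline FASTQ quality encodes the rate; Q37 when
error-free), low-quality Q2 tails on ~2% of reads (only when errors are
on, so error-free simulations stay pristine), and poly-G artifact reads at
`g_run_rate`. One integer seed drives every stage through named derived
streams (`derive_seed()`), so stages are independently reproducible.

What the simulator does **not** emulate: real human MHC sequence content
and its haplotype structure, empirical Illumina error/quality profiles,
target-capture probe bias, coverage waves, PCR duplicates, or contaminant
reads. Passing tests therefore demonstrate the pipeline's mechanics —
binning, repeat handling, structural reconstruction, error accounting —
not performance on any particular real library.

## Numerical choices and degenerate inputs

* Mapper ties break to the leftmost target start, then the plus strand;
  for small target sets (≤ 4 kb) the mapper switches to full DP, making
  accept/reject decisions exact in the regime where they are
  property-tested against an independent aligner.
* Gap costs are open + ext·length (a 1 bp gap costs −8), matching the
  convention under which the −0.6/base threshold tolerates 15 mismatches
  at 150 bp.
* `cov_cutoff = "auto"` = max(2, ⌈median coverage/10⌉): at 30× one
  erroneous read's k-mers (coverage 1–2) fall below it.
* Unmapped-is-a-value: `map_read()` returns a row with `mapped = FALSE`,
  never an error. Empty read pools assemble to empty contig sets.
* Coordinates are 0-based half-open internally (BED convention); emitted
  placement tables and VCF records are 1-based.
* Scaffolds that align nowhere score (0, 0) and go to the unplaced set.
* The evaluation's inter-anchor DP is capped at 4 × 10⁶ cells; larger
  dissimilar segment pairs (only arising between structurally different
  sequences, e.g. mismatched cassettes) are reported as paired
  insertion/deletion blocks.

## Problem sizes

The package's own validation runs a 300 kb-backbone DR3/DR4 heterozygote
at 0.5% divergence, 30× 150 bp pairs and 0.1% base error (~62,000 pairs),
assembled per BMH — large enough for superblock tiling, repeat content and
C4 to be exercised, and it completes comfortably on one CPU. Unit tests
use 20–60 kb backbones. The mapper/DP oracle equivalence is tested at
≤ 2 kb targets where exhaustive DP is exact; the naive genotyper's
parameter recovery runs 40 seeded 30× simulations on a 30 kb panel.

## Known limitations

* Pseudo-haploid output: heterozygous sites within one BMH bin resolve to
  one allele; for homozygous-class individuals this is a coin flip per
  site (quantified, not hidden, by `attribute_het_switch()`).
* Near-identical tandems (C4) are represented as gapped fragments, not
  resolved copy-by-copy — short reads cannot do better; C4 copy number
  should come from a dedicated caller upstream as part of the genotype
  input.
* The naive genotyper is a simulation convenience, unsuitable for real
  HLA typing, clinical or otherwise.
* Single best placement per read; multi-mapping is not reported.
* No long-read integration, no pan-genome output, no containerisation —
  the interface is R functions plus the thin `inst/scripts/mhcforge.R`
  wrapper.
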
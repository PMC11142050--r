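# mhcforge

Haplotype-guided *de novo* assembly of the human MHC from paired-end short
reads, at desk scale and fully in R.

The ~5 Mb major histocompatibility complex (chr6:28,509,120–33,481,577 on
GRCh38) is the most polymorphic region of the human genome; aligning short
reads to a single linear reference systematically misses its novel
heterozygosity, C4 copy-number variation, and the large HLA class II
structural haplotypes (*DRB1*+*DRB5* = DR2, +*DRB3* = DR3, +*DRB4* = DR4,
DR8 with no second expressed paralog). `mhcforge` assembles each individual
against one or two **best-matching guide haplotypes** (BMHs) chosen from
their HLA-DRB1 first-field genotype and C4 status — a proxy-parental
emulation of trio binning — and emits one pseudo-haploid consensus per
assigned haplotype.

The pipeline per BMH: read QC (poly-G artifact removal, seeded
subsampling, quality trimming) → read binning by end-to-end seed-and-extend
mapping (accept at score ≥ −0.6·*L* under match 0 / mismatch −6 /
gap −5,−3) → per-superblock de Bruijn assembly at *k* = 51 plus separate
assembly of unmapped reads → cross-mapping contig filtering against the
alternative BMH → non-redundant supercontig merging → pileup majority
polishing → paired-end scaffolding with gap estimation → guide-based
ordering/orientation, demoting scaffolds with location score < 0.1 or
(location < 0.3 and orientation < 0.75) to an unplaced set.

An evaluation module quantifies assembly error against truth haplotypes
the way MHC assembly validations report it: base-call error %, non-repeat
SV error % and repeat-associated SV error % of assembled length (SV =
indel ≥ 1 bp; tandem and repeat-mask-aware classification), heterozygous
switch attribution, N50/contig statistics, unique-150mer read ratios, and
VCF-style per-individual variant merging. A seeded synthetic module
generates MHC-like guide panels (class II cassettes, tandem C4 units,
interspersed repeats, SNP-divergent backbones), diploid individuals with
full truth tracking, and paired-end reads with realistic artifacts, so the
whole pipeline is testable without any external data.

Intended users: people building or stress-testing MHC/HLA assembly and
evaluation workflows, and anyone needing a self-contained, reproducible
short-read assembly sandbox with truth tracking. Not a clinical HLA typing
tool.

## Worked example

Simulate a DR3/DR4 heterozygote from a synthetic guide panel and assemble
it per haplotype:

```r
library(mhcforge)

panel <- generate_guide_panel(n = 4, base_len = 60000,
                              dr_mix = c("DR3", "DR4", "DR2", "DR8"),
                              seed = 101)
ind <- simulate_individual(panel, c("guide01_DR3", "guide02_DR4"),
                           divergence = 0.005, seed = 102)
reads <- simulate_reads(ind, read_sim_config(depth = 30, seed = 103))

run <- run_individual(reads, panel, truth = ind, id = "demo", verbose = FALSE)
run
#> <mhc_run> demo
#>   genotype: 03/04  BMH: guide01_DR3, guide02_DR4
#>   estimated depth: 29.9 x
#>    guide01_DR3 : consensus 76884 non-N bp, 75 contigs, N50 4239
#>      error vs truth hap a: total 0.0065%
#>    guide02_DR4 : consensus 82456 non-N bp, 82 contigs, N50 4849
#>      error vs truth hap b: total 0.0097%
```

The naive k-mer genotyper recovered the simulated DRB1 genotype (03/04),
so two BMHs were assigned and assembled separately. Each consensus covers
its ~77–85 kb truth haplotype with a total error well below 0.01% of
assembled sequence. The per-category breakdown for one haplotype:

```r
glance(run$bmh$guide01_DR3$error_report)
#> # A tibble: 1 × 5
#>   assembly_len base_call_error_pct nonrepeat_sv_error_pct repeat_sv_error_pct
#>          <int>               <dbl>                  <dbl>               <dbl>
#> 1        76884             0.00650                      0                   0
#> # ℹ 1 more variable: total_error_pct <dbl>
```

`base_call_error_pct` counts single-base mismatches against the truth
haplotype (including improper inclusions of the other haplotype's allele —
split out by `attribute_het_switch()`); the two SV columns count inserted/
deleted bp outside and inside the repeat mask. Assembly N gaps count as
missing sequence, not as errors. `tidy()` on the report lists every event;
`autoplot()` draws the category bars, and `autoplot(anchor_align(...))`
gives the classic assembly-vs-reference dotplot in which a mismatched
class II guide shows a cassette-sized break.

Result objects are tibble-first: `tidy()`/`glance()` methods cover error
reports, anchor alignments and placed assemblies, so results drop straight
into dplyr pipelines.

A thin command-line wrapper (`inst/scripts/mhcforge.R`) exposes
`simulate-panel`, `simulate-individual`, `simulate-reads`, `qc`,
`genotype` and `run` subcommands over FASTA/FASTQ/TSV files.

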
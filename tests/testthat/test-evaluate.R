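# anchor alignment, error calling and classification, het attribution,
# assembly statistics, unique k-mers, variant emission and merging

test_that("anchor alignment handles identity, indels and reversed input", {
  s <- rnd_dna(20000, 50)
  aln <- anchor_align(s, s)
  expect_equal(nrow(aln$anchors), 1)
  expect_equal(aln$anchors$len, 20000)
  expect_equal(nrow(aln$events), 0)

  # truth carries 500 bp the assembly lacks: a deletion flanked by 2 anchors
  asm <- paste0(substr(s, 1, 10000), substr(s, 10501, 20000))
  aln2 <- anchor_align(asm, s)
  expect_equal(nrow(aln2$anchors), 2)
  del <- aln2$events[aln2$events$type == "del", ]
  expect_equal(del$len, 500)
  expect_equal(del$tpos, 10000)

  # reversed assembly: anchors found after orientation flip, blocks monotone
  aln3 <- anchor_align(revcomp(s), s)
  expect_identical(aln3$orientation, "-")
  expect_equal(nrow(aln3$anchors), 1)

  expect_error(anchor_align(rnd_dna(5000, 51), s), "unrelated")
})

test_that("error percentages follow the bp-over-assembled-length definition", {
  s <- rnd_dna(5000, 52)
  aln <- anchor_align(s, s)
  rep0 <- call_errors(aln)
  expect_equal(glance(rep0)$total_error_pct, 0)

  # 5 substitutions on a 5000 bp assembly: base-call error 0.1%
  asm <- mutate_seq(s, c(1000, 2000, 2500, 3000, 4000))
  rep1 <- call_errors(anchor_align(asm, s))
  expect_equal(rep1$base_call_error_pct, 100 * 5 / 5000)
  expect_equal(rep1$nonrepeat_sv_error_pct, 0)
  # conservation: components sum exactly to the total
  g <- glance(rep1)
  expect_identical(g$total_error_pct,
                   g$base_call_error_pct + g$nonrepeat_sv_error_pct +
                     g$repeat_sv_error_pct)
})

test_that("the SV classifier matches hand-built toys for all six classes", {
  flankA <- rnd_dna(3000, 53)
  flankB <- rnd_dna(3000, 54)
  flankC <- rnd_dna(3000, 540)
  motif <- rnd_dna(20, 55)
  unit <- rnd_dna(400, 56)
  # truth: flankA + 3x motif + flankB + unit + flankC, `unit` masked as repeat
  truth <- paste0(flankA, strrep(motif, 3), flankB, unit, flankC)
  rbed <- tibble::tibble(start = nchar(flankA) + 60 + nchar(flankB),
                         end = nchar(flankA) + 60 + nchar(flankB) + 400)

  case <- function(asm) {
    ev <- tidy(call_errors(anchor_align(asm, truth), repeat_bed = rbed))
    ev[ev$type != "snp", ]
  }
  # tandem expansion: a fourth motif copy in the assembly
  ev <- case(paste0(flankA, strrep(motif, 4), flankB, unit, flankC))
  expect_identical(ev$type, "tandem_expansion")
  expect_equal(ev$len, 20)
  # tandem contraction: one copy lost
  ev <- case(paste0(flankA, strrep(motif, 2), flankB, unit, flankC))
  expect_identical(ev$type, "tandem_contraction")
  # repeat expansion: extra sequence inside the annotated repeat
  ins <- rnd_dna(150, 57)
  ev <- case(paste0(flankA, strrep(motif, 3), flankB, substr(unit, 1, 200),
                    ins, substr(unit, 201, 400), flankC))
  expect_identical(ev$type, "repeat_expansion")
  expect_true(ev$repeat_associated)
  # repeat contraction: part of the annotated repeat missing
  ev <- case(paste0(flankA, strrep(motif, 3), flankB, substr(unit, 1, 100),
                    substr(unit, 301, 400), flankC))
  expect_identical(ev$type, "repeat_contraction")
  expect_equal(ev$len, 200)
  # plain insertion / deletion: outside repeats, non-periodic
  novel <- rnd_dna(250, 58)
  ev <- case(paste0(substr(flankA, 1, 1500), novel, substr(flankA, 1501, 3000),
                    strrep(motif, 3), flankB, unit, flankC))
  expect_identical(ev$type, "insertion")
  expect_false(ev$repeat_associated)
  ev <- case(paste0(substr(flankA, 1, 1500), substr(flankA, 1801, 3000),
                    strrep(motif, 3), flankB, unit, flankC))
  expect_identical(ev$type, "deletion")
  expect_equal(ev$len, 300)
})

test_that("assembly N-gaps are missing sequence, not SV errors", {
  s <- rnd_dna(12000, 59)
  gappy <- paste0(substr(s, 1, 5000), strrep("N", 40), substr(s, 6001, 12000))
  rep <- call_errors(anchor_align(gappy, s))
  expect_equal(rep$total_error_pct, 0)
  expect_equal(rep$assembly_len, 11040 - 40)
})

test_that("mismatches split into het inclusion vs true error", {
  prim <- rnd_dna(15000, 60)
  other <- mutate_seq(prim, c(3000, 6000, 9000)) # het sites vs primary
  # assembly includes the other haplotype's allele at 3000 and 6000, and a
  # genuinely wrong base (matching neither) at 12000
  asm <- mutate_seq(prim, c(3000, 6000))
  ch <- strsplit(asm, "")[[1]]
  ch[3000] <- substr(other, 3000, 3000)
  ch[6000] <- substr(other, 6000, 6000)
  wrongbase <- setdiff(c("A", "C", "G", "T"),
                       c(substr(prim, 12000, 12000), substr(other, 12000, 12000)))[1]
  ch[12000] <- wrongbase
  asm <- paste(ch, collapse = "")
  rep <- call_errors(anchor_align(asm, prim))
  att <- attribute_het_switch(rep, prim, other)
  expect_equal(att$n_mismatches, 3)
  expect_equal(att$het_inclusion_fraction, 2 / 3)
  expect_equal(att$true_error_fraction, 1 / 3)
  expect_equal(att$het_inclusion_fraction + att$true_error_fraction, 1)

  # identical to the primary: flagged empty classification
  att0 <- attribute_het_switch(call_errors(anchor_align(prim, prim)),
                               prim, other)
  expect_true(att0$no_mismatches)
  expect_equal(att0$het_inclusion_fraction + att0$true_error_fraction, 0)
})

test_that("N50 matches its definition and a brute-force oracle", {
  n50_brute <- function(lens) {
    # direct definition: shortest contig in the minimal set of longest
    # contigs whose summed length covers half the total
    sl <- sort(lens, decreasing = TRUE)
    tot <- sum(sl)
    acc <- 0
    for (x in sl) { acc <- acc + x; if (acc >= tot / 2) return(x) }
  }
  expect_equal(assembly_stats(c(5, 4, 3, 2, 1))$n50, 4)
  expect_equal(assembly_stats(7000)$n50, 7000)
  expect_equal(assembly_stats(rep(42, 10))$n50, 42)
  set.seed(61)
  for (i in 1:25) {
    lens <- sample.int(5000, sample(1:40, 1), replace = TRUE)
    expect_equal(assembly_stats(lens)$n50, n50_brute(lens))
  }
  expect_error(assembly_stats(integer(0)), "no contigs")
})

test_that("unique k-mer ratio behaves at its extremes and tracks divergence", {
  r <- rnd_dna(150, 62)
  expect_lt(unique_kmer_ratio(rep(r, 100), k = 150), 0.02)
  distinct <- vapply(1:200, function(i) rnd_dna(150), character(1))
  expect_gt(unique_kmer_ratio(distinct, k = 150), 0.95)
  expect_error(unique_kmer_ratio(rnd_dna(50, 1), k = 150), "no read")

  # higher divergence from the guide -> higher unique-150mer ratio
  ratios <- vapply(c(0.001, 0.02), function(d) {
    sim <- small_sim(base_len = 20000, depth = 15, divergence = d,
                     indel_rate = 0, base_error = 0, seed = 63,
                     repeat_density = 0)
    unique_kmer_ratio(sim$reads, k = 150)
  }, numeric(1))
  expect_gt(ratios[2], ratios[1])
})

test_that("variant records are left-normalized and merge into genotypes", {
  ref <- rnd_dna(8000, 64)
  expect_equal(nrow(call_variants_vs_reference(ref, ref)), 0)

  # one substitution at position p
  v <- call_variants_vs_reference(mutate_seq(ref, 4000), ref)
  expect_equal(v$pos, 4000)
  expect_identical(v$ref, substr(ref, 4000, 4000))

  # deletion inside a homopolymer run left-normalizes to the run start:
  # hand-derived oracle on a constructed instance
  ref2 <- paste0(substr(ref, 1, 3000), "TTTT", substr(ref, 3001, 8000))
  asm2 <- paste0(substr(ref, 1, 3000), "T", substr(ref, 3001, 8000)) # del TTT
  v2 <- call_variants_vs_reference(asm2, ref2)
  expect_equal(nrow(v2), 1)
  expect_identical(v2$ref, paste0(v2$alt, "TTT")) # anchor + deleted run
  expect_identical(substr(ref2, v2$pos, v2$pos), v2$alt)
  # maximally left-shifted: the anchor base is not part of the T run, and
  # the run continues immediately after it
  expect_false(v2$alt == "T")
  expect_identical(substr(ref2, v2$pos + 1, v2$pos + 3), "TTT")

  # merge semantics
  va <- tibble::tibble(chrom = "ref", pos = c(100L, 200L),
                       ref = c("A", "C"), alt = c("G", "T"))
  vb <- tibble::tibble(chrom = "ref", pos = c(100L, 300L),
                       ref = c("A", "G"), alt = c("G", "A"))
  m <- merge_haplotype_variants(va, vb)
  expect_identical(m$gt[m$pos == 100], "1/1")
  expect_identical(m$gt[m$pos == 200], "0/1")
  expect_identical(m$gt[m$pos == 300], "0/1")
  # conflicting alts at one site -> single 1/2 record
  vc <- tibble::tibble(chrom = "ref", pos = 100L, ref = "A", alt = "T")
  m2 <- merge_haplotype_variants(va, vc)
  expect_identical(m2$gt[m2$pos == 100], "1/2")
  expect_identical(m2$alt[m2$pos == 100], "G,T")
  # empty in, empty out; mismatched references error
  expect_equal(nrow(merge_haplotype_variants(va[0, ], vb[0, ])), 0)
  expect_error(merge_haplotype_variants(
    va, dplyr::mutate(vb, chrom = "other")), "mismatched reference")
})
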
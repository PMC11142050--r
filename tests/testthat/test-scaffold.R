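# pileup polishing, paired-end scaffolding, placement scoring and filtering

mk_contigs <- function(seqs, coverage = 30) {
  tibble::tibble(id = sprintf("c%d", seq_along(seqs)), sequence = seqs,
                 length = nchar(seqs), coverage = coverage,
                 origin = "mapped", superblock_id = NA_character_)
}

test_that("pileup polishing corrects a majority-supported base and respects the depth floor", {
  s <- rnd_dna(2000, 40)
  pr <- tile_pairs(s, read_len = 100, step = 5, insert = 300)
  # error-free reads on the true contig: nothing changes
  out <- polish_contigs(mk_contigs(s), pr)
  expect_identical(out$sequence, s)
  expect_equal(sum(attr(out, "polish_edits")), 0)

  # one wrong base in the contig, true reads at ~30x: corrected
  wrong <- mutate_seq(s, 1000)
  out2 <- polish_contigs(mk_contigs(wrong), pr)
  expect_identical(out2$sequence, s)
  expect_equal(attr(out2, "polish_edits")[["n_sub"]], 1)

  # only 3 covering reads: below the depth floor, never edited
  few <- pr[c(1, 2, 3), ]
  out3 <- polish_contigs(mk_contigs(wrong), few, min_depth = 5)
  expect_identical(out3$sequence, wrong)
})

test_that("paired-end scaffolding joins supported links with a sane gap", {
  s <- rnd_dna(4000, 41)
  pr <- tile_pairs(s, read_len = 100, step = 6, insert = 500)
  # two contigs with a 150 bp true gap between them
  ctgs <- mk_contigs(c(substr(s, 1, 1900), substr(s, 2051, 4000)))
  sc <- scaffold_paired(ctgs, pr, insert_mean = 500, insert_sd = 20)
  expect_equal(nrow(sc), 1)
  gaps <- sc$gaps[[1]]
  expect_length(gaps, 1)
  expect_lt(abs(gaps - 150), 60) # within insert spread of truth
  # scaffold sequence = parts joined by the N run
  expect_equal(nchar(sc$sequence), 1900 + (4000 - 2051 + 1) + gaps)

  # two straddling pairs only: below support, no join
  few <- pr[c(280, 290), ] # fragments spanning the inter-contig gap
  sc2 <- scaffold_paired(ctgs, few, insert_mean = 500, insert_sd = 20)
  expect_equal(nrow(sc2), 2)

  # single contig: single part, no gaps
  sc3 <- scaffold_paired(mk_contigs(substr(s, 1, 1000)), pr, 500)
  expect_equal(nrow(sc3), 1)
  expect_length(sc3$gaps[[1]], 0)
})

test_that("placement scores follow their aligned-bp definitions", {
  guide <- rnd_dna(40000, 42)
  idx <- index_guide(guide)
  # contiguous single-strand scaffold: (1, 1)
  sc <- score_placement(substr(guide, 5001, 15000), idx)
  expect_equal(sc$location_score, 1)
  expect_equal(sc$orientation_score, 1)
  expect_lt(abs(sc$assigned_start - 5000), 50)

  # half the aligned bp on each strand: orientation score 0.5
  half <- paste0(substr(guide, 5001, 10000),
                 revcomp(substr(guide, 10001, 15000)))
  sc2 <- score_placement(half, idx)
  expect_equal(sc2$orientation_score, 0.5, tolerance = 0.05)

  # split equally across two distant windows: location score 0.5
  split <- paste0(substr(guide, 1001, 6000), substr(guide, 30001, 35000))
  sc3 <- score_placement(split, idx)
  expect_equal(sc3$location_score, 0.5, tolerance = 0.05)

  # unalignable scaffold: zero scores
  sc4 <- score_placement(rnd_dna(3000, 43), idx)
  expect_equal(sc4$location_score, 0)
  expect_equal(sc4$orientation_score, 0)
})

test_that("the placement filter demotes by the location/orientation rule", {
  # quadrant behaviour is asserted on the rule itself
  rule_excluded <- function(loc, orient) loc < 0.1 | (loc < 0.3 & orient < 0.75)
  expect_true(rule_excluded(0.05, 1.0))   # loc < 0.1 alone
  expect_true(rule_excluded(0.2, 0.5))    # loc < 0.3 and orient < 0.75
  expect_false(rule_excluded(0.2, 0.9))   # complement of the rule
  expect_false(rule_excluded(0.5, 0.1))

  # and end-to-end through place_and_filter with engineered scaffolds
  guide <- rnd_dna(60000, 44)
  good <- substr(guide, 10001, 22000)
  junk <- rnd_dna(6000, 45) # unalignable: (0, 0) -> unplaced
  scafs <- tibble::tibble(
    id = c("s1", "s2"), sequence = c(good, junk),
    parts = list(tibble::tibble(contig_id = "c1", strand = "+"),
                 tibble::tibble(contig_id = "c2", strand = "+")),
    gaps = list(integer(0), integer(0)))
  asm <- place_and_filter(scafs, guide)
  expect_identical(asm$placements$scaffold_id, "s1")
  expect_identical(asm$unplaced$id, "s2")
  expect_identical(asm$consensus, good)
})

test_that("minus-strand scaffolds are reverse-complemented into guide order", {
  guide <- rnd_dna(50000, 46)
  s1 <- substr(guide, 5001, 15000)
  s2 <- revcomp(substr(guide, 20001, 30000))
  scafs <- tibble::tibble(
    id = c("a", "b"), sequence = c(s2, s1), # order scrambled on purpose
    parts = list(tibble::tibble(contig_id = "x", strand = "+"),
                 tibble::tibble(contig_id = "y", strand = "+")),
    gaps = list(integer(0), integer(0)))
  asm <- place_and_filter(scafs, guide)
  expect_equal(asm$placements$scaffold_id, c("b", "a"))
  expect_equal(asm$placements$assigned_strand, c("+", "-"))
  # consensus = s1, gap ~5000 N, revcomp(s2)
  expect_identical(substr(asm$consensus, 1, 10000), s1)
  expect_identical(substr(asm$consensus, nchar(asm$consensus) - 9999,
                          nchar(asm$consensus)),
                   substr(guide, 20001, 30000))
  gap_run <- nchar(asm$consensus) - 20000
  expect_lt(abs(gap_run - 5000), 100)
})
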
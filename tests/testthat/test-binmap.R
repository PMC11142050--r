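# seed indexing, read mapping, pair binning, superblock tiling

test_that("seed index statistics match direct enumeration", {
  g <- rnd_dna(1000, 4)
  st <- index_stats(index_guide(g, seed_k = 15))
  expect_equal(st$n_positions, 1000 - 15 + 1)

  mono <- strrep("A", 100)
  st2 <- index_stats(index_guide(mono, seed_k = 15))
  expect_equal(st2$n_distinct, 1)

  expect_error(index_guide(rnd_dna(10, 1), seed_k = 15), "seed_k")
})

test_that("perfect reads map with score 0 on the forward strand", {
  g <- rnd_dna(3000, 5)
  idx <- index_guide(g)
  m <- map_read(substr(g, 501, 650), idx)
  expect_true(m$mapped)
  expect_equal(m$score, 0)
  expect_equal(m$target_start, 500)
  expect_identical(m$strand, "+")
  # reverse-complement reads map on the minus strand at the same locus
  mr <- map_read(revcomp(substr(g, 501, 650)), idx)
  expect_equal(mr$target_start, 500)
  expect_identical(mr$strand, "-")
})

test_that("the score threshold separates 15 from 16 mismatches at L = 150", {
  g <- rnd_dna(3000, 6)
  idx <- index_guide(g)
  r0 <- substr(g, 1001, 1150)
  with_mism <- function(n) mutate_seq(r0, seq(3, by = 9, length.out = n))
  m15 <- map_read(with_mism(15), idx)
  expect_true(m15$mapped)           # 15 * -6 = -90 >= -0.6 * 150
  expect_equal(m15$score, -90)
  m16 <- map_read(with_mism(16), idx)
  expect_false(m16$mapped)          # -96 < -90
})

test_that("accept/reject matches full dynamic programming on small instances", {
  # independent oracle: Biostrings end-to-end (query-global) alignment under
  # the same scoring
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -6,
                                                  baseOnly = TRUE)
  dp_best <- function(r, g) {
    s1 <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(r), Biostrings::DNAString(g),
      type = "global-local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 3, scoreOnly = TRUE)
    s2 <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(revcomp(r)), Biostrings::DNAString(g),
      type = "global-local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 3, scoreOnly = TRUE)
    max(s1, s2)
  }
  set.seed(77)
  g <- rnd_dna(1800)
  idx <- index_guide(g)
  for (case in 1:40) {
    L <- sample(30:60, 1)
    r <- if (runif(1) < 0.6) {
      s <- sample(nchar(g) - L, 1)
      rr <- substr(g, s, s + L - 1)
      nm <- sample(0:7, 1)
      if (nm > 0) rr <- mutate_seq(rr, sample(L, nm))
      if (runif(1) < 0.3) { # 1-2 bp deletion
        p <- sample(L - 3, 1)
        rr <- paste0(substr(rr, 1, p), substr(rr, p + 1 + sample(1:2, 1), L))
      }
      if (runif(1) < 0.5) revcomp(rr) else rr
    } else rnd_dna(L)
    m <- map_read(r, idx)
    best <- dp_best(r, g)
    expect_equal(m$mapped, best >= -0.6 * nchar(r),
                 info = paste("case", case))
    if (m$mapped) expect_equal(m$score, best, info = paste("case", case))
  }
})

test_that("pair binning partitions the input with mate rescue", {
  sim <- small_sim(base_len = 20000, depth = 10, divergence = 0,
                   indel_rate = 0, base_error = 0, seed = 23,
                   dr_mix = c("DR3", "DR3"), repeat_density = 0)
  pairs <- sim$reads
  guide <- stats::setNames(sim$panel$sequence[1], sim$panel$id[1])
  bin <- bin_reads(pairs, index_targets(guide))
  expect_equal(nrow(bin$mapped) + nrow(bin$unmapped), nrow(pairs))
  expect_length(intersect(bin$mapped$read_id, bin$unmapped$read_id), 0)
  # zero-divergence reads against their own guide: only artifacts unmapped
  art <- attr(pairs, "truth")$g_artifact
  expect_lte(nrow(bin$unmapped), sum(art))
  # a pair with one junk mate still lands in the mapped bin (mate rescue)
  pr <- make_pairs(substr(guide, 101, 250), rnd_dna(150, 9))
  bin2 <- bin_reads(pr, index_targets(guide))
  expect_equal(nrow(bin2$mapped), 1)
})

test_that("raising divergence never increases the mapped fraction", {
  fracs <- vapply(c(0.005, 0.02, 0.05), function(d) {
    sim <- small_sim(base_len = 20000, depth = 15, divergence = d,
                     indel_rate = 0, base_error = 0, seed = 99,
                     dr_mix = c("DR3", "DR3"), repeat_density = 0)
    guide <- stats::setNames(sim$panel$sequence[1], sim$panel$id[1])
    bin <- bin_reads(sim$reads, index_targets(guide))
    bin$counts$pairs_mapped / bin$counts$pairs_in
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0.002)) # non-increasing within noise
})

test_that("superblock tiling follows the span/overlap arithmetic", {
  mk_aln <- function(starts, ends) tibble::tibble(
    query_id = sprintf("q%04d", seq_along(starts)), mapped = TRUE,
    target_start = starts, target_end = ends)
  # footprints spanning 0..100 kb -> 3 superblocks
  aln <- mk_aln(seq(0, 99700, by = 100), seq(300, 100000, by = 100))
  sb <- build_superblocks(aln, target_span = 50000, overlap = 5000)
  expect_equal(nrow(sb), 3)
  expect_equal(sb$start, c(0, 45000, 90000))
  expect_equal(sb$end, c(50000, 95000, 100000))
  # every mapped pair is assigned to every tile its footprint intersects
  expect_true(all(vapply(seq_len(3), function(i) {
    ids <- sb$read_ids[[i]]
    all(aln$target_start[match(ids, aln$query_id)] < sb$end[i])
  }, logical(1))))

  # all reads within 10 kb -> a single superblock
  sb1 <- build_superblocks(mk_aln(c(1000, 5000), c(1300, 5300)))
  expect_equal(nrow(sb1), 1)

  # no mapped reads -> empty
  expect_equal(nrow(build_superblocks(mk_aln(integer(0), integer(0)))), 0)

  expect_error(build_superblocks(aln, target_span = 1000, overlap = 1000),
               "overlap")
})
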
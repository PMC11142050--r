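# de Bruijn graph construction, cleaning, contig extraction, cross-mapping
# filter, supercontig merging

test_that("graph nodes are exactly the distinct canonical k-mers", {
  # single read of length k: one node
  r <- rnd_dna(31, 1)
  g <- build_debruijn(r, k = 31)
  expect_equal(dbg_stats(g)$n_nodes, 1)
  expect_identical(dbg_nodes(g)$kmer, min(r, revcomp(r)))

  # brute-force enumeration oracle on a toy sequence
  s <- rnd_dna(300, 2)
  reads <- substring(s, 1:(300 - 59), 60:300)
  g2 <- build_debruijn(reads, k = 21)
  brute <- unique(vapply(1:(300 - 20), function(i) {
    km <- substr(s, i, i + 20)
    min(km, revcomp(km))
  }, character(1)))
  expect_setequal(dbg_nodes(g2)$kmer, brute)

  expect_error(build_debruijn(c("ACGT", "GGGA"), k = 21), "shorter than k")
  expect_error(build_debruijn(r, k = 30), "odd")
})

test_that("cleaning removes error k-mers, clips tips, pops skewed bubbles", {
  s <- rnd_dna(600, 3)
  reads <- substring(s, seq(1, 501, by = 2), seq(100, 600, by = 2))
  # one read with a single mismatch: its novel k-mers sit at coverage 1
  bad <- mutate_seq(substr(s, 201, 300), 50)
  g <- build_debruijn(c(reads, bad), k = 31)
  n_before <- dbg_stats(g)$n_nodes
  simplify_graph(g) # auto cutoff = max(2, ceiling(median/10))
  expect_lt(dbg_stats(g)$n_nodes, n_before)
  ctg <- extract_contigs(g)
  expect_equal(nrow(ctg), 1)
  # the surviving contig is clean source sequence (coverage ramps at the
  # extreme ends fall below the cutoff, so ends may be trimmed)
  got <- ctg$sequence
  if (!grepl(substr(got, 1, 31), s, fixed = TRUE)) got <- revcomp(got)
  expect_true(grepl(got, s, fixed = TRUE))
  expect_gte(nchar(got), 600 - 2 * 31)

  # a path graph is already at its fixpoint
  g3 <- build_debruijn(substring(s, seq(1, 501, 5), seq(100, 600, 5)), k = 31)
  n3 <- dbg_stats(g3)$n_nodes
  simplify_graph(g3, cov_cutoff = 0)
  expect_equal(dbg_stats(g3)$n_nodes, n3)
})

test_that("a low-coverage SNP bubble at >= 0.95 identity is collapsed", {
  # two homologous sequences differing at one interior site form a bubble
  # (flanks longer than k on both sides); identity ~0.99 >= 0.95
  a <- rnd_dna(150, 11)
  b <- mutate_seq(a, 75)
  g <- build_debruijn(c(a, b), k = 51)
  simplify_graph(g, cov_cutoff = 0, tip_len = 1) # no end clipping at depth 1
  ctg <- extract_contigs(g, min_contig_len = 50)
  expect_equal(nrow(ctg), 1)
  expect_true(ctg$sequence %in% c(a, b, revcomp(a), revcomp(b)))
  # a dissimilar branch pair (identity < 0.95) is preserved
  c2 <- paste0(substr(a, 1, 60), rnd_dna(80, 12), substr(a, 141, 150))
  g2 <- build_debruijn(c(a, c2), k = 51)
  simplify_graph(g2, cov_cutoff = 0, tip_len = 10)
  expect_gt(nrow(extract_contigs(g2, min_contig_len = 50)), 1)
})

test_that("contigs reconstruct error-free unique sequence losslessly", {
  s <- rnd_dna(5000, 12)
  pr <- tile_pairs(s, read_len = 150, step = 10, insert = 400)
  ctg <- assemble_pool(pr, k = 51, cov_cutoff = 0) # error-free input
  expect_equal(nrow(ctg), 1)
  got <- ctg$sequence
  if (substr(got, 1, 51) != substr(s, 1, 51)) got <- revcomp(got)
  expect_identical(got, s)
})

test_that("an exact interspersed repeat longer than k breaks the assembly", {
  rep200 <- rnd_dna(200, 13)
  s <- paste0(rnd_dna(1500, 14), rep200, rnd_dna(1500, 15), rep200,
              rnd_dna(1500, 16))
  pr <- tile_pairs(s, read_len = 150, step = 5, insert = 400)
  ctg <- assemble_pool(pr, k = 51)
  expect_gte(nrow(ctg), 2)
})

test_that("every contig k-mer occurs in the input reads", {
  s <- rnd_dna(2000, 17)
  pr <- tile_pairs(s, read_len = 120, step = 7, insert = 360)
  ctg <- assemble_pool(pr, k = 51)
  read_kmers <- new.env()
  for (r in c(pr$seq1, pr$seq2)) {
    for (i in 1:(nchar(r) - 50)) {
      km <- substr(r, i, i + 50)
      assign(min(km, revcomp(km)), TRUE, envir = read_kmers)
    }
  }
  for (cs in ctg$sequence) {
    for (i in seq(1, nchar(cs) - 50, by = 17)) {
      km <- substr(cs, i, i + 50)
      expect_true(exists(min(km, revcomp(km)), envir = read_kmers))
    }
  }
})

test_that("total assembled length plateaus between 30x and 60x", {
  p <- generate_guide_panel(n = 2, base_len = 30000, dr_mix = c("DR3", "DR3"),
                            seed = 31)
  ind <- simulate_individual(p, c(p$id[1], p$id[1]), divergence = 0,
                             indel_rate = 0, seed = 32)
  tot <- vapply(c(30, 60), function(d) {
    rd <- simulate_reads(ind, read_sim_config(depth = d, base_error = 0,
                                              g_run_rate = 0, seed = 33))
    sum(assemble_pool(rd, k = 51)$length)
  }, numeric(1))
  expect_gte(tot[2], tot[1] * 0.98)
  expect_lte(abs(tot[2] - tot[1]) / tot[1], 0.02)
})

test_that("cross-mapping filter removes alt-BMH content and keeps novel", {
  alt <- rnd_dna(5000, 18)
  novel <- rnd_dna(400, 19)
  ctg <- tibble::tibble(
    id = c("c1", "c2"),
    sequence = c(substr(alt, 1001, 1600), novel),
    length = c(600L, 400L), coverage = c(30, 30),
    origin = "unmapped", superblock_id = NA_character_)
  out <- filter_cross_mapping(ctg, alt_bmh = alt)
  expect_identical(out$id, "c2")
  # no alt and no decoy: identity
  out2 <- filter_cross_mapping(ctg)
  expect_identical(out2$id, ctg$id)
})

test_that("supercontig merging joins, rejects short overlaps, removes contained", {
  base <- rnd_dna(1000, 20)
  mk <- function(seqs) tibble::tibble(
    id = sprintf("c%d", seq_along(seqs)), sequence = seqs,
    length = nchar(seqs), coverage = 30, origin = "mapped",
    superblock_id = NA_character_)
  # 60 bp exact overlap -> one merged contig reproducing the source
  two <- mk(c(substr(base, 1, 530), substr(base, 471, 1000)))
  m <- merge_supercontigs(two)
  expect_equal(nrow(m), 1)
  expect_true(m$sequence == base || revcomp(m$sequence) == base)

  # 30 bp overlap: below min_ovl, not merged
  short <- mk(c(substr(base, 1, 530), substr(base, 501, 1000)))
  expect_equal(nrow(merge_supercontigs(short)), 2)

  # exact substring: removed as contained
  cont <- mk(c(base, substr(base, 301, 700)))
  mc <- merge_supercontigs(cont)
  expect_equal(nrow(mc), 1)
  expect_identical(mc$sequence, base)

  # ambiguous overlap (one suffix, two possible prefixes) stays unmerged
  amb <- mk(c(substr(base, 1, 530),
              paste0(substr(base, 471, 1000), rnd_dna(100, 21)),
              paste0(substr(base, 471, 1000), rnd_dna(100, 22))))
  expect_equal(nrow(merge_supercontigs(amb)), 3)
})
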
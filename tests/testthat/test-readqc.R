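# read QC: poly-G filter, seeded subsampling, quality trimming

test_that("the G-homopolymer filter drops pairs at exactly the run threshold", {
  ok <- paste0(strrep("A", 10), strrep("G", 19), strrep("T", 21))
  bad <- paste0(strrep("A", 10), strrep("G", 20), strrep("T", 20))
  other <- rnd_dna(50, 1)
  pairs <- make_pairs(c(ok, bad, other), c(other, other, bad))
  out <- filter_g_homopolymer(pairs, 20)
  # pair 2 (mate 1) and pair 3 (mate 2) carry 20-G runs and drop whole
  expect_identical(out$read_id, "p0001")

  expect_identical(filter_g_homopolymer(pairs[0, ], 20), pairs[0, ])
  # order of survivors preserved
  many <- make_pairs(rep(c(ok, bad), 5), rep(other, 10))
  expect_identical(filter_g_homopolymer(many, 20)$read_id,
                   many$read_id[seq(1, 9, by = 2)])
})

test_that("subsampling keeps mates together and is seed-stable", {
  pairs <- make_pairs(replicate(30000 / 10, rnd_dna(30)),
                      replicate(3000, rnd_dna(30)))
  s1 <- subsample_pairs(pairs, 1000, seed = 7)
  s2 <- subsample_pairs(pairs, 1000, seed = 7)
  expect_equal(nrow(s1), 1000)
  expect_identical(s1, s2)
  expect_true(all(s1$read_id %in% pairs$read_id))
  # pass-through cases
  expect_identical(subsample_pairs(pairs, nrow(pairs), 1), pairs)
  expect_warning(out <- subsample_pairs(pairs, nrow(pairs) + 10, 1),
                 "passing all")
  expect_identical(out, pairs)
})

test_that("trimming follows the leading/trailing, window and length rules", {
  cfg <- qc_config()
  # 150 bp at Q30: unchanged
  s <- rnd_dna(150, 2)
  p <- make_pairs(s, s, qual_string(rep(30, 150)), qual_string(rep(30, 150)))
  expect_identical(trim_reads(p, cfg)$seq1, s)

  # a (14,14,14,14) window starting after base 50 truncates to 50 bp
  q <- c(rep(30, 50), rep(14, 4), rep(30, 96))
  p <- make_pairs(s, s, qual_string(q), qual_string(rep(30, 150)))
  out <- trim_reads(p, cfg)
  expect_equal(nchar(out$seq1), 50)
  expect_identical(out$seq1, substr(s, 1, 50))

  # post-trim length 39 < 40: the pair is dropped whole
  q39 <- c(rep(30, 39), rep(2, 111))
  p <- make_pairs(s, s, qual_string(q39), qual_string(rep(30, 150)))
  expect_equal(nrow(trim_reads(p, cfg)), 0)
  # post-trim length 40 survives
  q40 <- c(rep(30, 40), rep(2, 110))
  p <- make_pairs(s, s, qual_string(q40), qual_string(rep(30, 150)))
  expect_equal(nchar(trim_reads(p, cfg)$seq1), 40)

  # leading N and low-quality bases are stripped
  sN <- paste0("NN", substr(s, 3, 150))
  p <- make_pairs(sN, s, qual_string(rep(30, 150)), qual_string(rep(30, 150)))
  expect_identical(trim_reads(p, cfg)$seq1, substr(s, 3, 150))

  expect_error(
    trim_reads(make_pairs(s, s, qual_string(rep(30, 10)),
                          qual_string(rep(30, 150))), cfg),
    "malformed FASTQ record")
})

test_that("trimming is idempotent and never increases read content", {
  set.seed(31)
  n <- 200
  seqs <- replicate(n, rnd_dna(150))
  quals <- replicate(n, qual_string(sample(c(2, 10, 16, 30, 37), 150, TRUE,
                                           prob = c(.05, .1, .15, .3, .4))))
  p <- make_pairs(seqs, rev(seqs), quals, rev(quals))
  t1 <- trim_reads(p)
  t2 <- trim_reads(t1)
  expect_identical(t1, t2)
  expect_lte(nrow(t1), nrow(p))
  expect_lte(sum(nchar(t1$seq1)) + sum(nchar(t1$seq2)),
             sum(nchar(p$seq1)) + sum(nchar(p$seq2)))
})

test_that("error-free Q37 simulated reads pass QC unchanged", {
  sim <- small_sim(base_len = 20000, depth = 10, divergence = 0,
                   indel_rate = 0, base_error = 0, seed = 8,
                   repeat_density = 0)
  out <- qc_reads(sim$reads, qc_config())
  sm <- attr(out, "qc_summary")
  attr(out, "qc_summary") <- NULL
  expect_identical(out, sim$reads[sim$reads$read_id %in% out$read_id, ])
  # only poly-G artifact pairs may have been removed
  expect_equal(sm$pairs_out[sm$stage == "trim"],
               sm$pairs_in[sm$stage == "trim"])
})
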
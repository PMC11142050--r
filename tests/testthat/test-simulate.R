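# synthetic panel, diploid individual and read simulation

test_that("guide panels encode DR-class structure and are seed-deterministic", {
  p <- generate_guide_panel(n = 4, base_len = 60000,
                            dr_mix = c("DR3", "DR4", "DR2", "DR8"), seed = 42)
  expect_equal(p$length, nchar(p$sequence))

  len <- stats::setNames(p$length, p$dr_class)
  # class II cassette ordering: DR4 longest, DR8 carries no second cassette
  expect_gt(len[["DR4"]], len[["DR3"]])
  expect_gt(len[["DR3"]], len[["DR8"]])
  expect_gt(len[["DR2"]], len[["DR3"]])

  reps <- panel_repeats(p)
  expect_true(all(reps$start >= 0))
  expect_true(all(reps$end <= p$length[match(reps$guide_id, p$id)]))

  p2 <- generate_guide_panel(n = 4, base_len = 60000,
                             dr_mix = c("DR3", "DR4", "DR2", "DR8"), seed = 42)
  expect_identical(p$sequence, p2$sequence)
  expect_identical(panel_repeats(p), panel_repeats(p2))

  p3 <- generate_guide_panel(n = 2, base_len = 20000, dr_mix = c("DR3", "DR4"),
                             repeat_density = 0, seed = 1)
  expect_true(all(panel_repeats(p3)$family == "C4Sim"))

  expect_error(generate_guide_panel(n = 2, dr_mix = c("DR3", "DR99")),
               "invalid dr_class")
})

test_that("simulated individuals round-trip through their truth variants", {
  p <- generate_guide_panel(n = 2, base_len = 30000, dr_mix = c("DR3", "DR4"),
                            seed = 5)
  ind <- simulate_individual(p, p$id, divergence = 0.005, indel_rate = 5e-4,
                             seed = 9)
  for (h in c("a", "b")) {
    gseq <- p$sequence[p$id == ind$source_guides[match(h, c("a", "b"))]]
    hap <- if (h == "a") ind$hap_a else ind$hap_b
    tv <- ind$truth_variants[ind$truth_variants$hap == h, ]
    expect_identical(apply_variants(gseq, tv), hap)
  }
  # genotype derived from the guides' classes
  expect_identical(ind$drb1_genotype, c("03", "04"))
  expect_identical(ind$dr_classes, c("DR3", "DR4"))
})

test_that("zero divergence reproduces the guide exactly", {
  p <- generate_guide_panel(n = 2, base_len = 20000, dr_mix = c("DR3", "DR3"),
                            seed = 5)
  ind <- simulate_individual(p, c(p$id[1], p$id[1]), divergence = 0,
                             indel_rate = 0, seed = 1)
  expect_identical(ind$hap_a, p$sequence[1])
  expect_identical(ind$hap_b, p$sequence[1])
  expect_equal(nrow(ind$truth_variants), 0)
})

test_that("unrealistic divergence is rejected", {
  p <- generate_guide_panel(n = 2, base_len = 20000, dr_mix = c("DR3", "DR4"),
                            seed = 5)
  expect_error(simulate_individual(p, p$id, divergence = 0.1), "divergence")
  expect_error(simulate_individual(p, c(p$id[1], "nope")), "not in panel")
})

test_that("truth variant count tracks the requested mutation rate", {
  p <- generate_guide_panel(n = 2, base_len = 100000, dr_mix = c("DR3", "DR4"),
                            repeat_density = 0, seed = 2)
  ind <- simulate_individual(p, p$id, divergence = 0.005, indel_rate = 0,
                             seed = 3)
  n_sites <- sum(nchar(c(ind$hap_a, ind$hap_b)))
  n_var <- nrow(ind$truth_variants)
  expected <- 0.005 * n_sites
  # binomial sampling: within 15% of expectation at this n
  expect_gt(n_var, expected * 0.85)
  expect_lt(n_var, expected * 1.15)
})

test_that("read simulation honours the pair-count formula and the seed", {
  p <- generate_guide_panel(n = 2, base_len = 30000, dr_mix = c("DR3", "DR3"),
                            repeat_density = 0, seed = 5)
  ind <- simulate_individual(p, c(p$id[1], p$id[1]), divergence = 0,
                             indel_rate = 0, seed = 1)
  cfg <- read_sim_config(depth = 30, read_len = 150, base_error = 0,
                         g_run_rate = 0, seed = 4)
  rd <- simulate_reads(ind, cfg)
  total_len <- nchar(ind$hap_a) + nchar(ind$hap_b)
  expect_equal(nrow(rd), round(30 * total_len / (2 * 150)))

  rd2 <- simulate_reads(ind, cfg)
  expect_identical(rd, rd2)

  # error-free reads substring-match a haplotype (either orientation)
  some <- rd[sample.int(nrow(rd), 50), ]
  hits <- vapply(some$seq1, function(s) {
    grepl(s, ind$hap_a, fixed = TRUE) || grepl(s, ind$hap_b, fixed = TRUE) ||
      grepl(revcomp(s), ind$hap_a, fixed = TRUE) ||
      grepl(revcomp(s), ind$hap_b, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))
})

test_that("mean coverage is within 10% of the configured depth", {
  p <- generate_guide_panel(n = 2, base_len = 30000, dr_mix = c("DR3", "DR4"),
                            repeat_density = 0, seed = 6)
  ind <- simulate_individual(p, p$id, divergence = 0, indel_rate = 0, seed = 2)
  cfg <- read_sim_config(depth = 30, base_error = 0, g_run_rate = 0, seed = 8)
  rd <- simulate_reads(ind, cfg)
  cov <- (sum(nchar(rd$seq1)) + sum(nchar(rd$seq2))) /
    (nchar(ind$hap_a) + nchar(ind$hap_b))
  expect_gt(cov, 0.9 * 30)
  expect_lt(cov, 1.1 * 30)
})

test_that("poly-G artifacts appear at the configured rate, reproducibly", {
  p <- generate_guide_panel(n = 2, base_len = 30000, dr_mix = c("DR3", "DR4"),
                            repeat_density = 0, seed = 6)
  ind <- simulate_individual(p, p$id, divergence = 0, indel_rate = 0, seed = 2)
  cfg <- read_sim_config(depth = 20, base_error = 0, g_run_rate = 0.01,
                         seed = 21)
  rd <- simulate_reads(ind, cfg)
  n_art <- sum(grepl(strrep("G", 20), rd$seq1) | grepl(strrep("G", 20), rd$seq2))
  expect_gt(n_art, 0)
  # two mates, each at 1%: expect about 2% of pairs, loosely bounded
  expect_gt(n_art / nrow(rd), 0.005)
  expect_lt(n_art / nrow(rd), 0.05)
  rd2 <- simulate_reads(ind, cfg)
  expect_identical(attr(rd, "truth")$g_artifact, attr(rd2, "truth")$g_artifact)
})
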
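# DRB1 class mapping, BMH assignment, naive stand-in genotyper

test_that("allele groups map to the expected DR classes", {
  expect_identical(assign_dr_class(c("03", "04")), c("DR3", "DR4"))
  expect_identical(assign_dr_class(c("15", "15")), "DR2")
  expect_identical(assign_dr_class(c("08", "08")), "DR8")
  expect_identical(assign_dr_class(c("11", "13")), "DR3")
  expect_error(assign_dr_class(c("03", "99")), "99")
  # user-overridable table
  tab <- tibble::tibble(allele_group = c("03", "04"),
                        dr_class = c("DR4", "DR4"))
  expect_identical(assign_dr_class(c("03", "04"), tab), "DR4")
})

test_that("BMH assignment gives one guide per class with C4-aware ranking", {
  p <- generate_guide_panel(n = 4, base_len = 20000,
                            dr_mix = c("DR3", "DR3", "DR4", "DR8"), seed = 3)
  # homozygous: a single BMH
  hom <- assign_bmh("DR3", NULL, p)
  expect_length(hom$guide_ids, 1)
  # heterozygous: two BMHs, one per class
  het <- assign_bmh(c("DR3", "DR4"), NULL, p)
  expect_length(het$guide_ids, 2)
  expect_setequal(p$dr_class[match(het$guide_ids, p$id)], c("DR3", "DR4"))
  # exact C4 copy match beats the class default
  second_dr3 <- p[p$dr_class == "DR3", ][2, ]
  st <- tibble::tibble(c4a = second_dr3$c4a, c4b = second_dr3$c4b,
                       long = second_dr3$c4_long)
  expect_identical(assign_bmh("DR3", st, p)$guide_ids, second_dr3$id)
  # absent class errors with the available ones listed
  expect_error(assign_bmh("DR2", NULL, p), "available")
  # pure function: repeated calls identical
  expect_identical(assign_bmh(c("DR3", "DR4"), NULL, p),
                   assign_bmh(c("DR3", "DR4"), NULL, p))
})

test_that("the naive genotyper recovers simulated DR genotypes", {
  sim <- small_sim(base_len = 30000, depth = 30, seed = 17)
  gt <- naive_drb1_genotype(qc_reads(sim$reads), drb1_exemplar_panel(sim$panel))
  expect_identical(gt$alleles, c("03", "04"))
  expect_identical(gt$source, "naive_caller")

  # homozygote: DR2/DR2
  p2 <- generate_guide_panel(n = 2, base_len = 30000,
                             dr_mix = c("DR2", "DR2"), seed = 18)
  ind2 <- simulate_individual(p2, c(p2$id[1], p2$id[1]), seed = 19)
  rd2 <- simulate_reads(ind2, read_sim_config(depth = 30, seed = 20))
  gt2 <- naive_drb1_genotype(rd2, drb1_exemplar_panel(p2))
  expect_identical(gt2$alleles, c("15", "15"))

  # empty read set: no-call
  gt0 <- naive_drb1_genotype(sim$reads[0, ], drb1_exemplar_panel(sim$panel))
  expect_identical(gt0$status, "no_call")
})
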
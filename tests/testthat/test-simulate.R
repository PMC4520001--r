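test_that("family simulation respects rate and conservation settings", {
  cfg0 <- simulation_config(seed = 3, substitution_rate = 0,
                            root_protein_length = 30, family_size = 5)
  msa0 <- simulate_homolog_family(cfg0)
  expect_length(unique(msa0$sequences), 1L)     # rate 0: identical rows
  cfg1 <- simulation_config(seed = 3, substitution_rate = 0.5,
                            conserved_fraction = 1,
                            root_protein_length = 30, family_size = 5)
  expect_length(unique(simulate_homolog_family(cfg1)$sequences), 1L)
  # conserved columns never mutate even at rate 1
  cfg2 <- simulation_config(seed = 9, substitution_rate = 1,
                            conserved_fraction = 0.5,
                            root_protein_length = 40, family_size = 6)
  msa2 <- simulate_homolog_family(cfg2)
  cons <- attr(msa2, "conserved_columns")
  root <- attr(msa2, "root")
  m <- do.call(rbind, strsplit(msa2$sequences, ""))
  for (j in cons)
    expect_true(all(m[, j] == substr(root, j, j)))
})

test_that("generators are pure functions of the seed", {
  cfg <- simulation_config(seed = 123)
  expect_identical(simulate_homolog_family(cfg),
                   simulate_homolog_family(cfg))
  expect_identical(simulate_indel_catalog(cfg, 200),
                   simulate_indel_catalog(cfg, 200))
  tr <- worked_example_preset()$transcripts[[2]]
  expect_identical(simulate_genotyped_variants(cfg, tr, n = 50),
                   simulate_genotyped_variants(cfg, tr, n = 50))
  expect_identical(worked_example_preset()$gvariants, worked_example_preset()$gvariants)
})

test_that("simulated genotyped variants recover their class labels", {
  tr <- worked_example_preset()$transcripts[[2]]
  cfg <- simulation_config(seed = 8)
  gv <- simulate_genotyped_variants(cfg, tr, n = 120)
  cls <- classify_variant_class(gv, tr)
  expect_equal(cls, gv$true_class)
  # class-1-only request round-trips through set formation
  cfg1 <- simulation_config(seed = 8, class_frequencies = c(1, 0, 0, 0))
  gv1 <- simulate_genotyped_variants(cfg1, tr, n = 30)
  expect_true(all(classify_variant_class(gv1, tr) == 1L))
  sets <- form_variant_sets(gv1, tr, "sim")
  expect_equal(nrow(sets[[1]]$members), 30L)
})

test_that("class frequencies concentrate near their configured proportions", {
  tr <- transcript_model("big", "c", "+",
                         data.frame(start = 0L, end = 9000L))
  cfg <- simulation_config(seed = 5,
                           class_frequencies = c(0.4, 0.2, 0.2, 0.2))
  gv <- simulate_genotyped_variants(cfg, tr, n = 5000, gene_length = 20000)
  freq <- tabulate(gv$true_class, 4) / nrow(gv)
  expect_equal(freq, c(0.4, 0.2, 0.2, 0.2), tolerance = 0.1)
})

test_that("indel catalogs span the admissible and inadmissible delta range", {
  cfg <- simulation_config(seed = 4, indel_catalog_density = 0.5)
  cata <- simulate_indel_catalog(cfg, 400)
  expect_equal(nrow(cata), 200L)
  expect_true(all(cata$delta != 0))
  expect_true(all(abs(cata$delta) <= 5))
  expect_true(any(admit_indel(cata$delta)) &&
                any(!admit_indel(cata$delta)))
  empty <- simulate_indel_catalog(
    simulation_config(indel_catalog_density = 0), 400)
  expect_equal(nrow(empty), 0L)
})

test_that("simulation configs are validated", {
  expect_error(simulation_config(substitution_rate = 1.5))
  expect_error(simulation_config(class_frequencies = c(1, 1, 1, 1)))
  expect_error(simulation_config(family_size = 1))
})
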
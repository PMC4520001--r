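wex <- worked_example_preset()

test_that("variant classes follow location, zygosity and ancestral state", {
  gv <- wex$gvariants
  t1 <- wex$transcripts[[1]]
  cls <- classify_variant_class(gv, t1)
  names(cls) <- gv$id
  expect_equal(unname(cls[c("v1", "v3")]), c(1L, 1L))  # coding hom derived
  expect_equal(unname(cls["v2"]), 3L)                  # coding heterozygous
  expect_equal(unname(cls["v4"]), 4L)                  # outside T1 coding
  expect_equal(unname(cls["v5"]), 4L)                  # intronic everywhere
  # class 2 on transcript 2: homozygous for the ancestral allele
  cls2 <- classify_variant_class(gv, wex$transcripts[[2]])
  names(cls2) <- gv$id
  expect_equal(unname(cls2["v4"]), 2L)
  # every (variant, transcript) pair receives exactly one class
  for (tr in wex$transcripts)
    expect_true(all(classify_variant_class(gv, tr) %in% 1:4))
})

test_that("unknown ancestral alleles block Class 1/2 assignment", {
  gv <- wex$gvariants
  gv$ancestral[gv$id == "v3"] <- NA
  expect_message(cls <- classify_variant_class(gv, wex$transcripts[[1]]),
                 "ancestral allele unknown")
  expect_true(is.na(cls[gv$id == "v3"]))
  sets <- suppressMessages(
    form_variant_sets(gv, wex$transcripts[[1]], "ind"))
  expect_equal(sets[[1]]$members$id, "v1")
})

test_that("the three-transcript worked example yields exactly the printed sets", {
  sets <- form_variant_sets(wex$gvariants, wex$transcripts, "NA001")
  expect_length(sets, 3L)
  got <- lapply(sets, function(s) s$members$id)
  names(got) <- vapply(sets, `[[`, character(1), "transcript_id")
  expect_equal(got$T1, c("v1", "v3"))
  expect_equal(got$T2, c("v3", "v6", "v8"))
  expect_equal(got$T3, c("v6", "v8"))
  # v3 appears in the sets of two transcripts (alternative splicing)
  expect_equal(sum(vapply(got, function(m) "v3" %in% m, logical(1))), 2L)
})

test_that("set membership is invariant to variant input order", {
  shuffled <- wex$gvariants[c(5, 2, 8, 1, 6, 3, 7, 4), ]
  s1 <- form_variant_sets(wex$gvariants, wex$transcripts, "x")
  s2 <- form_variant_sets(shuffled, wex$transcripts, "x")
  expect_equal(lapply(s1, `[[`, "set_id"), lapply(s2, `[[`, "set_id"))
  expect_equal(lapply(s1, function(s) s$members$id),
               lapply(s2, function(s) s$members$id))
})

test_that("identical member lists share a set id across individuals", {
  sA <- form_variant_sets(wex$gvariants, wex$transcripts, "indA")
  sB <- form_variant_sets(wex$gvariants, wex$transcripts, "indB")
  tab <- association_table(c(sA, sB))
  expect_equal(nrow(tab), 6L)
  byT <- split(tab$set_id, tab$transcript_id)
  for (ids in byT) expect_length(unique(ids), 1L)
  # different member lists get different ids
  expect_length(unique(tab$set_id), 3L)
})

test_that("all-heterozygous input forms no sets", {
  gv <- wex$gvariants
  gv$gt1 <- gv$ref; gv$gt2 <- gv$alt
  gv$zygosity <- "het"
  expect_length(form_variant_sets(gv, wex$transcripts, "x"), 0L)
})

test_that("genotype alleles must match REF or ALT", {
  bad <- wex$gvariants
  bad$gt1[1] <- "G"
  expect_error(as_genotyped_variants(bad), "REF or ALT")
})
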
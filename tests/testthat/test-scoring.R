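test_that("odds ratio follows its defining formula", {
  expect_equal(odds_ratio(0.7, 0.7)$O, 1)
  expect_equal(odds_ratio(0.9, 0.5)$O, 9)
  expect_equal(odds_ratio(0.3, 0.8)$O * odds_ratio(0.8, 0.3)$O, 1)
  expect_error(odds_ratio(1, 0.5), "between 0 and 1")
  expect_error(odds_ratio(0.5, 0), "between 0 and 1")
})

test_that("SNP bit-score difference is log2(Pw/Pm) and antisymmetric", {
  expect_equal(snp_score(0.4, 0.4), 0)
  expect_equal(snp_score(0.8, 0.2), 2)
  expect_equal(snp_score(0.3, 0.9), -snp_score(0.9, 0.3))
})

test_that("odds interpretation partitions the positive axis", {
  expect_equal(interpret_odds(1), "neutral")
  expect_equal(interpret_odds(9), "deleterious")
  expect_equal(interpret_odds(0.1), "beneficial")
  expect_error(interpret_odds(-2), "positive")
  # every O gets exactly one category; band edges are neutral
  for (O in c(0.01, 2^-0.5, 0.9, 1, 1.2, 2^0.5, 50))
    expect_length(interpret_odds(O), 1L)
  expect_equal(interpret_odds(2^0.49), "neutral")
  expect_equal(interpret_odds(2^0.51), "deleterious")
})

test_that("odds ratio equals 2^(bit difference) under the bridge", {
  set.seed(5)
  for (i in 1:20) {
    bw <- runif(1, -20, 20); bm <- runif(1, -20, 20)
    o <- odds_ratio(generation_probability(bw), generation_probability(bm))
    expect_equal(o$O, 2^(bw - bm), tolerance = 1e-9)
  }
})

test_that("a mutant identical to the wild type is exactly neutral", {
  fx <- conserved_family_fixture()
  r <- score_mutant(fx$hmm, fx$root, fx$root)
  expect_identical(r$score, 1)
  expect_equal(r$interpretation, "neutral")
  rs <- score_mutant(fx$hmm, fx$root, fx$root, "snp_bits")
  expect_identical(rs$score, 0)
})

test_that("odds ratio is non-decreasing in the number of disruptive substitutions", {
  fx <- conserved_family_fixture()
  mut <- fx$root
  prev <- -Inf
  for (k in 0:5) {
    if (k > 0) {
      p <- 3 * k          # hit a fresh conserved column each step
      substr(mut, p, p) <- setdiff(AA20, substr(fx$root, p, p))[1]
    }
    o <- score_mutant(fx$hmm, fx$root, mut)$log2_O
    expect_gte(o, prev)
    prev <- o
  }
  expect_gt(prev, 0)      # five disruptions are clearly deleterious
})

test_that("joint set scoring returns joint and single scores on one scale", {
  fx <- conserved_family_fixture()
  del <- del_variant(fx$cds, 10, "fs")
  ins <- ins_variant(fx$cds, 16, "A", "rescue")
  joint <- score_variant_set(fx$hmm, fx$cds, rbind(del, ins))
  expect_equal(joint$score_type, "odds_ratio")   # auto: indels present
  expect_equal(joint$n, 2L)
  expect_named(joint$singles, c("fs", "rescue"))
  single <- score_variant_set(fx$hmm, fx$cds, del)
  # the frame-restoring pair scores lower than the frameshift alone
  expect_lt(joint$S, single$S)
  expect_equal(joint$singles[["fs"]], single$S)
  # pure-SNP set defaults to the bit-score difference
  snp <- data.frame(id = "s1", pos = 4,
                    ref = substr(fx$cds, 4, 4),
                    alt = setdiff(c("A", "C", "G", "T"),
                                  substr(fx$cds, 4, 4))[1])
  expect_equal(score_variant_set(fx$hmm, fx$cds, snp)$score_type,
               "snp_bits")
})

test_that("an empty variant set scores the identity with a warning", {
  fx <- conserved_family_fixture()
  expect_warning(r <- score_variant_set(fx$hmm, fx$cds, NULL),
                 "identity")
  expect_equal(r$joint$score, 1)
  expect_equal(r$n, 0L)
})

test_that("set score TSV reports round-trip through classify_cm_table", {
  fx <- conserved_family_fixture()
  rec <- score_variant_set(fx$hmm, fx$cds,
                           rbind(del_variant(fx$cds, 10, "a"),
                                 ins_variant(fx$cds, 16, "A", "b")),
                           set_id = "set1")
  path <- tempfile(fileext = ".tsv")
  write_set_score_tsv(rec, path)
  tab <- utils::read.delim(path)
  expect_equal(tab$set_id, "set1")
  cls <- classify_cm_table(tab)
  expect_true(cls$label %in% c("CM", "nonCM", "neither"))
})
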
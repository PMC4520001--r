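test_that("admission keeps short frame-shifting indels only", {
  expect_false(admit_indel(3))    # divisible by three
  expect_false(admit_indel(-3))
  expect_false(admit_indel(-5))   # too long
  expect_false(admit_indel(5))
  expect_true(admit_indel(1))
  expect_equal(admit_indel(c(1, -2, 3, -5, 4)),
               c(TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("simple partner configurations produce the expected sets", {
  p <- search_params()
  # one +1 partner 10 bp away: a single net-0 set of span 10
  cat1 <- data.frame(id = c("t", "p"), pos = c(100, 110), delta = c(-1, 1))
  r1 <- find_compensatory_sets("t", cat1, p)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$net_delta, 0L)
  expect_equal(r1$span, 10L)
  expect_equal(r1$members, "t;p")
  # a -2 partner gives the valid sum -3
  cat2 <- data.frame(id = c("t", "p"), pos = c(100, 105), delta = c(-1, -2))
  r2 <- find_compensatory_sets("t", cat2, p)
  expect_equal(r2$net_delta, -3L)
  # partner beyond the 20-bp window: no sets
  cat3 <- data.frame(id = c("t", "p"), pos = c(100, 125), delta = c(-1, 1))
  expect_equal(nrow(find_compensatory_sets("t", cat3, p)), 0L)
  # empty / singleton catalog: no sets
  expect_equal(nrow(find_compensatory_sets(
    "t", data.frame(id = "t", pos = 1, delta = -1), p)), 0L)
})

test_that("inadmissible targets are refused", {
  cat <- data.frame(id = c("t3", "p"), pos = c(100, 105), delta = c(-3, 1))
  expect_error(find_compensatory_sets("t3", cat), "admission")
  expect_error(find_compensatory_sets("ghost", cat), "not found")
})

test_that("search equals exhaustive subset enumeration on random catalogs", {
  set.seed(2024)
  tried <- 0L
  while (tried < 120L) {
    n <- sample(3:12, 1)
    cat_r <- data.frame(id = sprintf("i%02d", 1:n),
                        pos = sample(1:60, n, replace = TRUE),
                        delta = sample(c(-5:-1, 1:5), n, replace = TRUE))
    admissible <- cat_r$id[admit_indel(cat_r$delta)]
    if (!length(admissible)) next
    tried <- tried + 1L
    tid <- sample(admissible, 1)
    expect_identical(find_compensatory_sets(tid, cat_r, cap = FALSE),
                     brute_force_sets(tid, cat_r))
  }
})

test_that("caps bind on the adversarial dense catalog", {
  adv <- adversarial20_preset()
  expect_gte(sum(admit_indel(adv$delta)), 30L)
  expect_lte(max(adv$pos) - min(adv$pos), 20L)
  res <- find_compensatory_sets("adv01", adv)
  expect_gt(nrow(res), 0L)
  expect_true(all(res$size <= 10L))
  expect_true(all(res$span <= 20L))
  expect_true(all(res$net_delta %in% c(-3L, 0L, 3L)))
  expect_true(all(table(res$net_delta) <= 20L))
  # every reported member passes admission
  members <- unique(unlist(strsplit(res$members, ";")))
  expect_true(all(admit_indel(adv$delta[match(members, adv$id)])))
})

test_that("search results are deterministic and ranked by span then size", {
  adv <- adversarial20_preset()
  r1 <- find_compensatory_sets("adv01", adv)
  r2 <- find_compensatory_sets("adv01", adv)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$span) >= 0 |
                    diff(r1$span) == 0 & diff(r1$size) >= 0))
})

test_that("anchor window mode bounds member distance from the target", {
  p <- search_params(window_mode = "anchor")
  # two partners 15 bp either side of the target: anchored OK (span 30)
  cat <- data.frame(id = c("a", "t", "b"), pos = c(85, 100, 115),
                    delta = c(2, -1, 2))
  r <- find_compensatory_sets("t", cat, p)
  expect_true("a;t;b" %in% r$members)   # net 3, span 30, anchored <= 20
  rs <- find_compensatory_sets("t", cat, search_params())
  expect_false("a;t;b" %in% rs$members) # span mode rejects span 30
  expect_identical(r, brute_force_sets("t", cat, p))
})
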
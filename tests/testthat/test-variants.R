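test_that("single edits apply as specified", {
  expect_equal(apply_variants("ATGGCC", NULL)$cds, "ATGGCC")
  m <- apply_variants("ATGGCC", data.frame(pos = 2, ref = "T", alt = "A"))
  expect_equal(m$cds, "AAGGCC")
  expect_equal(m$net_length_change, 0L)
  expect_equal(m$frame_status, "in-frame")
})

test_that("a 1-bp deletion plus 1-bp insertion preserves downstream codons", {
  cds <- "ATGGCTAAAGGGTTTCCC"
  vars <- rbind(
    data.frame(id = "d", pos = 4, ref = substr(cds, 4, 5),
               alt = substr(cds, 4, 4)),                    # -1 at 5
    data.frame(id = "i", pos = 9, ref = substr(cds, 9, 9),
               alt = paste0(substr(cds, 9, 9), "T")))       # +1 after 9
  m <- apply_variants(cds, vars)
  expect_equal(nchar(m$cds), nchar(cds))
  expect_equal(m$net_length_change, 0L)
  expect_equal(substr(m$cds, 11, 18), substr(cds, 11, 18))
})

test_that("reference mismatches and overlaps are rejected with names", {
  expect_error(apply_variants("ATG", data.frame(id = "bad", pos = 1,
                                                ref = "C", alt = "G")),
               "REF mismatch.*bad")
  vars <- rbind(data.frame(id = "a", pos = 2, ref = "TG", alt = "T"),
                data.frame(id = "b", pos = 3, ref = "G", alt = "C"))
  expect_error(apply_variants("ATGA", vars), "overlap")
  expect_error(apply_variants("ATG", data.frame(pos = 3, ref = "GA",
                                                alt = "G")),
               "beyond")
})

test_that("translation uses the standard code, stops at stop, warns on partials", {
  expect_equal(translate_cds("ATGAAATAG"), "MK")
  expect_warning(p <- translate_cds("ATGAA"), "partial")
  expect_equal(p, "M")
  expect_equal(translate_cds("TAAATG"), "")
  expect_error(translate_cds("ATGN"), "A/C/G/T")
})

test_that("net length change sums allele-length differences", {
  expect_equal(net_length_change(NULL), 0L)
  vars <- data.frame(pos = c(1, 5, 9),
                     ref = c("ATT", "GCC", "A"),
                     alt = c("A", "G", "AT"))
  expect_equal(net_length_change(vars), -3L)
  expect_equal(net_length_change(data.frame(pos = 1, ref = "A",
                                            alt = "C")), 0L)
})

test_that("frame-effect classification follows length arithmetic", {
  expect_equal(classify_frame_effect("AT", "A"), "frameshift")
  expect_equal(classify_frame_effect("A", "ATTT"), "in-frame")
  expect_equal(classify_frame_effect("A", "C"), "snp")
  expect_equal(classify_frame_effect("ATTT", "A"), "in-frame")
  expect_equal(classify_frame_effect("A", "ATTTT"), "frameshift")
})

test_that("length bookkeeping holds for random variant sets", {
  set.seed(123)
  bases <- c("A", "C", "G", "T")
  for (i in 1:300) {
    cds <- paste(sample(bases, 60, replace = TRUE), collapse = "")
    npos <- sample(1:4, 1)
    pos <- sort(sample(seq(1, 50, by = 6), npos))
    vars <- do.call(rbind, lapply(seq_along(pos), function(j) {
      p <- pos[j]
      kind <- sample(c("snp", "ins", "del"), 1)
      if (kind == "snp")
        data.frame(id = paste0("v", j), pos = p,
                   ref = substr(cds, p, p),
                   alt = sample(setdiff(bases, substr(cds, p, p)), 1))
      else if (kind == "ins")
        data.frame(id = paste0("v", j), pos = p,
                   ref = substr(cds, p, p),
                   alt = paste0(substr(cds, p, p),
                                paste(sample(bases, sample(1:3, 1), TRUE),
                                      collapse = "")))
      else
        data.frame(id = paste0("v", j), pos = p,
                   ref = substr(cds, p, p + sample(1:3, 1)),
                   alt = substr(cds, p, p))
    }))
    m <- apply_variants(cds, vars)
    expect_equal(nchar(m$cds) - nchar(cds), net_length_change(vars))
    expect_equal(m$frame_status,
                 if (net_length_change(vars) %% 3L == 0L) "in-frame"
                 else "frameshift")
  }
})

test_that("a frame-preserving set restores the downstream codon frame", {
  fx <- conserved_family_fixture()
  cds <- fx$cds
  vars <- rbind(del_variant(cds, 10, "d"), ins_variant(cds, 16, "A", "i"))
  m <- apply_variants(cds, vars)
  expect_equal(m$net_length_change, 0L)
  # beyond the affected window the codons, hence residues, match the wild type
  wild_prot <- translate_cds(cds)
  expect_equal(substr(m$protein, 7, nchar(wild_prot)),
               substr(wild_prot, 7, nchar(wild_prot)))
})

test_that("joint application equals one-at-a-time right-to-left application", {
  set.seed(321)
  bases <- c("A", "C", "G", "T")
  cds <- paste(sample(bases, 80, replace = TRUE), collapse = "")
  vars <- rbind(
    data.frame(id = "x", pos = 5, ref = substr(cds, 5, 7),
               alt = substr(cds, 5, 5)),
    data.frame(id = "y", pos = 20, ref = substr(cds, 20, 20),
               alt = paste0(substr(cds, 20, 20), "GT")),
    data.frame(id = "z", pos = 40, ref = substr(cds, 40, 40),
               alt = sample(setdiff(bases, substr(cds, 40, 40)), 1)))
  joint <- apply_variants(cds, vars)$cds
  stepwise <- cds
  for (i in rev(seq_len(nrow(vars))))
    stepwise <- apply_variants(stepwise, vars[i, , drop = FALSE])$cds
  expect_equal(joint, stepwise)
})

test_that("variant normalisation trims to the minimal left-aligned form", {
  n <- normalize_variant(10, "CTT", "CT")
  expect_equal(n, list(pos = 10L, ref = "CT", alt = "C"))
  n2 <- normalize_variant(10, "ACGT", "AT")
  expect_equal(n2$ref, "ACG"); expect_equal(n2$alt, "A")
  expect_equal(normalize_variant(3, "G", "C"),
               list(pos = 3L, ref = "G", alt = "C"))
})
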
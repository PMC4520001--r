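test_that("transcript construction validates exon structure", {
  expect_error(transcript_model("t", "c", "+",
                                data.frame(start = c(0, 5), end = c(6, 9))),
               "disjoint")
  expect_error(transcript_model("t", "c", "*",
                                data.frame(start = 0, end = 9)),
               "strand")
  expect_warning(transcript_model("t", "c", "+",
                                  data.frame(start = 0, end = 10)),
                 "multiple of 3")
  tr <- transcript_model("t", "c", "+",
                         data.frame(start = c(10, 30), end = c(16, 33)))
  expect_equal(tr$cds_length, 9L)
})

test_that("coding-region membership uses whole-variant containment", {
  tr <- transcript_model("t", "c", "+",
                         data.frame(start = c(9, 30), end = c(18, 33)))
  expect_true(in_coding_region(tr, 10))
  expect_true(in_coding_region(tr, 18))
  expect_false(in_coding_region(tr, 19))
  expect_false(in_coding_region(tr, 18, width = 2))  # spans the boundary
  expect_true(in_coding_region(tr, 31, width = 3))
})

test_that("genomic positions map to spliced CDS coordinates on both strands", {
  ex <- data.frame(start = c(9, 30), end = c(18, 33))
  plus <- transcript_model("p", "c", "+", ex)
  expect_equal(genomic_to_cds(plus, 10), 1L)
  expect_equal(genomic_to_cds(plus, 18), 9L)
  expect_equal(genomic_to_cds(plus, 31), 10L)
  minus <- transcript_model("m", "c", "-", ex)
  expect_equal(genomic_to_cds(minus, 33), 1L)   # 3'-most genomic base first
  expect_equal(genomic_to_cds(minus, 10), 12L)
  expect_error(genomic_to_cds(plus, 25), "not in an exon")
})

test_that("CDS extraction splices and reverse-complements", {
  genome <- "AAACCCGGGTTTACGTACGT"
  ex <- data.frame(start = c(3, 12), end = c(6, 15))
  plus <- transcript_model("p", "c", "+", ex)
  expect_equal(extract_cds(plus, genome), "CCCACG")
  minus <- transcript_model("m", "c", "-", ex)
  expect_equal(extract_cds(minus, genome), "CGTGGG")
  tr2 <- set_cds_from_genome(plus, genome)
  expect_equal(tr2$cds_sequence, "CCCACG")
})

test_that("variant projection handles strand and rejects boundary-spanners", {
  genome <- "AAACCCGGGTTTACGTACGT"
  ex <- data.frame(start = c(3, 12), end = c(6, 15))
  plus <- set_cds_from_genome(
    transcript_model("p", "c", "+", ex), genome)
  v <- project_variant_to_cds(plus, 5, "C", "T")
  expect_equal(v, list(pos = 2L, ref = "C", alt = "T"))
  expect_equal(substr(plus$cds_sequence, v$pos, v$pos), "C")
  minus <- set_cds_from_genome(
    transcript_model("m", "c", "-", ex), genome)
  vm <- project_variant_to_cds(minus, 5, "CC", "C")
  expect_equal(vm$ref, "GG")
  expect_error(project_variant_to_cds(plus, 6, "CG", "C"),
               "boundary|not fully contained")
})

test_that("transcript TSV and GFF3 readers agree on the same models", {
  fx <- worked_example_preset()
  tsv <- tempfile(fileext = ".tsv")
  write_transcript_tsv(fx$transcripts, tsv)
  back <- read_transcript_tsv(tsv)
  expect_named(back, c("T1", "T2", "T3"))
  expect_equal(back$T2$exons, fx$transcripts[[2]]$exons)
  gff <- tempfile(fileext = ".gff3")
  lines <- c("##gff-version 3", unlist(lapply(fx$transcripts, function(tr)
    sprintf("gene1\tjointvar\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
            tr$exons$start + 1L, tr$exons$end, tr$strand,
            tr$transcript_id))))
  writeLines(lines, gff)
  via_gff <- read_transcript_gff3(gff)
  expect_equal(via_gff$T2$exons, fx$transcripts[[2]]$exons)
  expect_equal(via_gff$T3$strand, "+")
})
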
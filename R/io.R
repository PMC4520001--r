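#' Read genotyped variants from a VCF file
#'
#' Reads a VCF 4.x file with GT genotypes and an optional `AA` INFO tag
#' (the ancestral allele, 1000 Genomes convention; lowercase marks a
#' low-confidence call).  Multiallelic records are split into biallelic
#' ones; records whose genotype uses an allele absent from the split
#' record, or with missing GT, are skipped with a message.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param sample Sample name or index (default: first sample).
#' @return A genotyped-variant table ([as_genotyped_variants()]), sorted
#'   by position.
#' @export
read_vcf <- function(path, sample = 1L) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (ncol(vcf@gt) < 2L)
    stop("VCF has no sample genotype columns", call. = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  scol <- if (is.numeric(sample)) samples[sample]
          else match.arg(sample, samples)
  gt <- vcfR::extract.gt(vcf, element = "GT")[, scol]
  info <- fix[, "INFO"]
  aa <- vapply(info, function(s) {
    m <- regmatches(s, regexpr("(^|;)AA=[^;]*", s))
    if (!length(m)) NA_character_ else sub("^;?AA=", "", m)
  }, character(1), USE.NAMES = FALSE)

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    g <- gt[i]
    if (is.na(g) || g %in% c(".", "./.", ".|.")) {
      message("record ", fix[i, "CHROM"], ":", fix[i, "POS"],
              ": missing GT, skipped")
      next
    }
    alleles_idx <- as.integer(strsplit(g, "[/|]")[[1]])
    if (length(alleles_idx) != 2L || anyNA(alleles_idx)) {
      message("record ", fix[i, "CHROM"], ":", fix[i, "POS"],
              ": unparseable GT '", g, "', skipped")
      next
    }
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    allele_str <- c(fix[i, "REF"], alts)
    gta <- allele_str[alleles_idx + 1L]
    for (alt in alts) {                  # multiallelic split
      if (!all(gta %in% c(fix[i, "REF"], alt))) {
        if (length(alts) > 1L)
          message("record ", fix[i, "CHROM"], ":", fix[i, "POS"],
                  " alt ", alt, ": genotype uses another allele, skipped")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = if (fix[i, "ID"] %in% c(".", NA)) NA_character_
             else fix[i, "ID"],
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alt,
        gt1 = gta[1], gt2 = gta[2], ancestral = aa[i])
    }
  }
  if (!length(rows))
    stop("no usable genotyped records in ", path, call. = FALSE)
  df <- do.call(rbind, rows)
  if (anyNA(df$id)) df$id[is.na(df$id)] <-
      paste0("var", which(is.na(df$id)))
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  as_genotyped_variants(df)
}

#' Write genotyped variants to a minimal VCF 4.2 file
#'
#' One sample column; the ancestral allele goes to the `AA` INFO tag and
#' the genotype to `GT` (unphased).
#'
#' @param gvariants A genotyped-variant table.
#' @param path Output path.
#' @param sample Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gvariants, path, sample = "SAMPLE") {
  gv <- gvariants
  gt_idx <- function(a, ref) ifelse(a == ref, "0", "1")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\tGT\t%s/%s",
                  gv$chrom, gv$pos, gv$id, gv$ref, gv$alt,
                  ifelse(is.na(gv$ancestral), ".",
                         paste0("AA=", ifelse(gv$aa_low_confidence,
                                              tolower(gv$ancestral),
                                              gv$ancestral))),
                  gt_idx(gv$gt1, gv$ref), gt_idx(gv$gt2, gv$ref))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an indel catalog from TSV
#'
#' Accepts either `id`, `pos`, `delta` columns or the 4-column
#' `id`, `pos`, `ref`, `alt` form (delta derived from allele lengths).
#'
#' @param path TSV path.
#' @return An indel catalog data frame.
#' @export
read_indel_catalog_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  as_indel_catalog(df)
}

#' Write an indel catalog to TSV
#'
#' @param catalog An indel catalog.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indel_catalog_tsv <- function(catalog, path) {
  utils::write.table(as_indel_catalog(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single sequence from a FASTA file
#'
#' @param path FASTA path.
#' @param what `"dna"` or `"protein"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, what = c("dna", "protein")) {
  what <- match.arg(what)
  x <- if (what == "dna") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param what `"dna"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, what = c("dna", "protein")) {
  what <- match.arg(what)
  x <- if (what == "dna") Biostrings::DNAStringSet(seqs)
       else Biostrings::AAStringSet(seqs)
  if (is.null(names(seqs))) names(x) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
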
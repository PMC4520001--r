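#' Normalise a variant table
#'
#' Variants are handled as data frames with columns `pos` (1-based
#' coordinate of the first REF base, VCF convention), `ref`, `alt` and
#' optionally `id` (generated as `v1`, `v2`, ... when absent) and
#' `chrom`.  REF and ALT must be nonempty A/C/G/T strings and differ.
#'
#' @param variants A data frame with at least `pos`, `ref`, `alt`; a
#'   zero-row data frame is allowed (the empty variant set).
#' @return The validated data frame with `id`, `pos`, `ref`, `alt` and a
#'   `kind` column (`snp`, `insertion`, `deletion`, `complex`).
#' @export
as_variant_table <- function(variants) {
  if (is.null(variants))
    variants <- data.frame(pos = integer(), ref = character(),
                           alt = character())
  if (!is.data.frame(variants) ||
      !all(c("pos", "ref", "alt") %in% names(variants)))
    stop("variants must be a data frame with pos, ref, alt", call. = FALSE)
  variants <- as.data.frame(variants)
  if (nrow(variants) == 0L) {
    variants$id <- character(0)
    variants$kind <- character(0)
    return(variants)
  }
  variants$ref <- toupper(as.character(variants$ref))
  variants$alt <- toupper(as.character(variants$alt))
  variants$pos <- as.integer(variants$pos)
  if (anyNA(variants$pos) || any(variants$pos < 1))
    stop("variant positions must be positive integers", call. = FALSE)
  bad <- !grepl("^[ACGT]+$", variants$ref) |
    !grepl("^[ACGT]+$", variants$alt)
  if (any(bad))
    stop("REF/ALT must be nonempty A/C/G/T strings (row ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  if (any(variants$ref == variants$alt))
    stop("REF and ALT must differ", call. = FALSE)
  if (is.null(variants$id))
    variants$id <- paste0("v", seq_len(nrow(variants)))
  variants$kind <- variant_kind(variants$ref, variants$alt)
  variants
}

variant_kind <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == la, ifelse(lr == 1, "snp", "complex"),
         ifelse(lr < la & lr == 1, "insertion",
                ifelse(lr > la & la == 1, "deletion", "complex")))
}

#' Net coding-length change of a variant set
#'
#' @param variants A variant table ([as_variant_table()]).
#' @return Signed integer: the sum of `nchar(alt) - nchar(ref)` over all
#'   variants.  SNPs contribute zero.
#' @export
net_length_change <- function(variants) {
  variants <- as_variant_table(variants)
  as.integer(sum(nchar(variants$alt) - nchar(variants$ref)))
}

#' Reading-frame effect of a single variant
#'
#' @param ref,alt REF and ALT allele strings.
#' @return `"snp"` when the alleles have equal length, `"in-frame"` when
#'   the length change is a nonzero multiple of 3, `"frameshift"`
#'   otherwise.
#' @examples
#' classify_frame_effect("A", "AT")      # frameshift
#' classify_frame_effect("A", "ATTTT")   # in-frame (+3)
#' @export
classify_frame_effect <- function(ref, alt) {
  d <- nchar(alt) - nchar(ref)
  ifelse(d == 0L, "snp",
         ifelse(d %% 3L == 0L, "in-frame", "frameshift"))
}

#' Apply a variant set to a coding sequence
#'
#' Applies all variants of a set to the same copy of the CDS (the
#' determined-haplotype assumption: the variants are linked in cis).
#' Variants must not overlap; their REF strings are checked against the
#' CDS.  Edits are applied right-to-left so that earlier coordinates stay
#' valid.
#'
#' @param cds Wild-type coding sequence (A/C/G/T string).
#' @param variants Variant table in 1-based CDS coordinates.
#' @return An object of class `mutant_sequence`: list with `cds` (mutant
#'   sequence), `protein` (its translation, stop-truncated),
#'   `net_length_change` and `frame_status` (`"in-frame"` or
#'   `"frameshift"`).
#' @examples
#' apply_variants("ATGGCC", data.frame(pos = 2, ref = "T", alt = "A"))$cds
#' @export
apply_variants <- function(cds, variants) {
  cds <- check_dna(cds)
  variants <- as_variant_table(variants)
  n <- nrow(variants)
  if (n > 1L) {
    o <- order(variants$pos, method = "radix")
    variants <- variants[o, , drop = FALSE]
    ends <- variants$pos + nchar(variants$ref) - 1L
    if (any(variants$pos[-1L] <= ends[-n]))
      stop("overlapping variants are not supported: ",
           paste(variants$id[c(which(variants$pos[-1L] <= ends[-n]) + 1L)],
                 collapse = ", "), call. = FALSE)
  }
  mutant <- cds
  for (i in rev(seq_len(n))) {
    p <- variants$pos[i]
    ref <- variants$ref[i]
    end <- p + nchar(ref) - 1L
    if (end > nchar(cds))
      stop("variant ", variants$id[i], " extends beyond the CDS",
           call. = FALSE)
    found <- substr(cds, p, end)
    if (found != ref)
      stop("REF mismatch for variant ", variants$id[i], " at CDS position ",
           p, ": expected ", ref, ", sequence has ", found, call. = FALSE)
    mutant <- paste0(substr(mutant, 1L, p - 1L), variants$alt[i],
                     substr(mutant, end + 1L, nchar(mutant)))
  }
  delta <- net_length_change(variants)
  stopifnot(nchar(mutant) - nchar(cds) == delta)
  structure(list(cds = mutant,
                 protein = translate_cds(mutant, warn_partial = FALSE),
                 net_length_change = delta,
                 frame_status = if (delta %% 3L == 0L) "in-frame"
                                else "frameshift"),
            class = "mutant_sequence")
}

#' @export
print.mutant_sequence <- function(x, ...) {
  cat("Mutant CDS (", nchar(x$cds), " nt, net change ",
      sprintf("%+d", x$net_length_change), ", ", x$frame_status, ")\n",
      sep = "")
  cat("  protein: ", if (nchar(x$protein) > 60)
    paste0(substr(x$protein, 1, 57), "...") else x$protein, "\n")
  invisible(x)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Translation stops at the first stop codon (the stop is not emitted);
#' a trailing partial codon is dropped with a warning.
#'
#' @param cds Nonempty A/C/G/T string.
#' @param warn_partial Warn when the length is not a multiple of 3
#'   (disabled internally when translating frameshifted mutants).
#' @return The protein string; may be empty if the sequence starts with a
#'   stop codon.
#' @examples
#' translate_cds("ATGAAATAG")   # "MK"
#' @export
translate_cds <- function(cds, warn_partial = TRUE) {
  cds <- check_dna(cds)
  n_codon <- nchar(cds) %/% 3L
  if (nchar(cds) %% 3L != 0L && warn_partial)
    warning("CDS length not a multiple of 3; trailing partial codon dropped")
  if (n_codon == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(cds, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1L)]
  paste(aa, collapse = "")
}

#' Left-align and trim a variant to its minimal representation
#'
#' Removes the common suffix, then the common prefix (keeping at least
#' one base on each allele) and adjusts the position — the usual VCF
#' normalisation so that equivalent indel records deduplicate.
#'
#' @param pos 1-based position of the first REF base.
#' @param ref,alt Allele strings.
#' @return List with normalised `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt) {
  r <- strsplit(toupper(ref), "")[[1]]
  a <- strsplit(toupper(alt), "")[[1]]
  # trim common suffix
  while (length(r) > 1L && length(a) > 1L &&
         r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  # trim common prefix
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1L]; a <- a[-1L]; pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

check_dna <- function(x) {
  if (!is.character(x) || length(x) != 1 || is.na(x) || !nzchar(x))
    stop("sequence must be a single nonempty string", call. = FALSE)
  x <- toupper(x)
  if (grepl("[^ACGT]", x))
    stop("sequence contains bases outside A/C/G/T (ambiguity codes are ",
         "not supported)", call. = FALSE)
  x
}
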
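#' Build a genotyped-variant table
#'
#' Genotyped variants extend the variant table with an unordered allele
#' pair (`gt1`, `gt2`, each equal to REF or an ALT) and the ancestral
#' allele (`ancestral`, `NA` when unknown; lowercase input marks a
#' low-confidence call, which is uppercased and flagged in
#' `aa_low_confidence`).
#'
#' @param variants Data frame with `chrom`, `pos`, `ref`, `alt`, `gt1`,
#'   `gt2`, `ancestral` and optionally `id`.
#' @param skip_low_confidence Drop variants whose ancestral call is
#'   low-confidence instead of flagging them.
#' @return The validated data frame with `id`, `kind`, `zygosity` and
#'   `aa_low_confidence` columns added.
#' @export
as_genotyped_variants <- function(variants, skip_low_confidence = FALSE) {
  need <- c("chrom", "pos", "ref", "alt", "gt1", "gt2", "ancestral")
  if (!is.data.frame(variants) || !all(need %in% names(variants)))
    stop("genotyped variants need columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  gv <- as_variant_table(variants)
  gv$gt1 <- toupper(as.character(variants$gt1))
  gv$gt2 <- toupper(as.character(variants$gt2))
  aa <- as.character(variants$ancestral)
  aa[aa %in% c(".", "", "N", "n", "-")] <- NA
  gv$aa_low_confidence <- !is.na(aa) & aa == tolower(aa) &
    aa != toupper(aa)
  gv$ancestral <- toupper(aa)
  ok_allele <- function(a) a == gv$ref | a == gv$alt
  bad <- !(ok_allele(gv$gt1) & ok_allele(gv$gt2))
  if (any(bad))
    stop("genotype alleles must equal REF or ALT (variant ",
         paste(gv$id[bad], collapse = ", "), ")", call. = FALSE)
  gv$zygosity <- ifelse(gv$gt1 == gv$gt2, "hom", "het")
  if (skip_low_confidence && any(gv$aa_low_confidence)) {
    message("dropping ", sum(gv$aa_low_confidence),
            " variant(s) with low-confidence ancestral allele")
    gv <- gv[!gv$aa_low_confidence, , drop = FALSE]
  }
  gv
}

#' Classify genotyped variants into the four genotype/location classes
#'
#' For a given transcript each variant falls in exactly one class:
#' * Class 1 - coding, homozygous, allele different from the ancestral
#'   allele (a determined derived haplotype; only these are scored);
#' * Class 2 - coding, homozygous, allele equal to the ancestral allele;
#' * Class 3 - coding, heterozygous (phase unknown, never combined);
#' * Class 4 - outside the coding region of this transcript (UTR,
#'   intron, intergenic).
#'
#' A coding homozygous variant with unknown ancestral allele cannot be
#' placed in Class 1 or 2 and is returned as `NA` with a logged reason.
#'
#' @param gvariants A genotyped-variant table
#'   ([as_genotyped_variants()]).
#' @param transcript A `transcript_model`.
#' @return Integer vector (1-4 or `NA`), one element per variant.
#' @export
classify_variant_class <- function(gvariants, transcript) {
  gv <- gvariants
  n <- nrow(gv)
  out <- integer(n)
  for (i in seq_len(n)) {
    coding <- in_coding_region(transcript, gv$pos[i], nchar(gv$ref[i]))
    if (!coding) { out[i] <- 4L; next }
    if (gv$zygosity[i] == "het") { out[i] <- 3L; next }
    if (is.na(gv$ancestral[i])) {
      message("variant ", gv$id[i], ": ancestral allele unknown; ",
              "cannot assign Class 1/2, skipped")
      out[i] <- NA_integer_
      next
    }
    out[i] <- if (gv$gt1[i] != gv$ancestral[i]) 1L else 2L
  }
  out
}

#' Form per-transcript Class-1 variant sets for one individual
#'
#' For each transcript the Class-1 variants (coding, homozygous, derived)
#' form the determined-haplotype set to be scored jointly; empty sets are
#' dropped.  Identical member lists receive the same `set_id` (an FNV-1a
#' hash of the sorted `chrom:pos:ref:alt` tuples), reproducing the
#' many-to-many individual/transcript/set association structure.
#'
#' @param gvariants A genotyped-variant table.
#' @param transcripts A `transcript_model` or list of them.
#' @param individual_id Sample identifier carried into the sets.
#' @return A list of `variant_set` objects, each a list with
#'   `individual_id`, `transcript_id`, `set_id` and `members` (rows of
#'   `gvariants`, sorted by position).  Use [association_table()] for
#'   the tabular individual/transcript/set view.
#' @export
form_variant_sets <- function(gvariants, transcripts, individual_id) {
  if (inherits(transcripts, "transcript_model"))
    transcripts <- list(transcripts)
  sets <- list()
  for (tr in transcripts) {
    cls <- classify_variant_class(gvariants, tr)
    members <- gvariants[!is.na(cls) & cls == 1L, , drop = FALSE]
    if (nrow(members) == 0L) next
    members <- members[order(members$pos, members$ref, members$alt), ,
                       drop = FALSE]
    key <- paste(sprintf("%s:%d:%s:%s", members$chrom, members$pos,
                         members$ref, members$alt), collapse = ";")
    sets[[length(sets) + 1L]] <- structure(
      list(individual_id = as.character(individual_id),
           transcript_id = tr$transcript_id,
           set_id = fnv1a_hash(key),
           members = members),
      class = "variant_set")
  }
  sets
}

#' @export
print.variant_set <- function(x, ...) {
  cat("Variant set", x$set_id, "(individual", x$individual_id,
      ", transcript", x$transcript_id, "):",
      paste(x$members$id, collapse = ", "), "\n")
  invisible(x)
}

#' Individual / transcript / set association table
#'
#' @param sets A list of `variant_set` objects from
#'   [form_variant_sets()] (possibly concatenated across individuals).
#' @return Data frame with columns `individual_id`, `transcript_id`,
#'   `set_id`, `n_variants`, `members`.
#' @export
association_table <- function(sets) {
  if (inherits(sets, "variant_set")) sets <- list(sets)
  do.call(rbind, lapply(sets, function(s)
    data.frame(individual_id = s$individual_id,
               transcript_id = s$transcript_id,
               set_id = s$set_id,
               n_variants = nrow(s$members),
               members = paste(s$members$id, collapse = ";"))))
}

# 32-bit FNV-1a hash of a string, as an 8-hex-digit id.  Multiplication
# is split into 16-bit halves so every intermediate stays below 2^53.
fnv1a_hash <- function(key) {
  h <- 2166136261
  prime <- 16777619
  for (b in utf8ToInt(key)) {
    h <- bitwXor32(h, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

bitwXor32 <- function(a, b) {
  # bitwXor works on 32-bit signed ints; route through the signed range
  ai <- if (a >= 2147483648) a - 4294967296 else a
  r <- bitwXor(as.integer(ai), as.integer(b))
  if (r < 0) r + 4294967296 else r
}
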
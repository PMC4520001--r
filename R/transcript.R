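#' Construct a transcript model
#'
#' A transcript is its ordered exon intervals on the genome plus strand
#' and (optionally) the spliced coding sequence.  Exon intervals are
#' half-open 0-based internally (BED convention); the readers convert
#' from their format's native convention.
#'
#' @param transcript_id Identifier.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with `start`, `end` (half-open, 0-based),
#'   disjoint; sorted internally by start.
#' @param cds_sequence Optional spliced CDS (transcription order, i.e.
#'   already reverse-complemented for `-` strand transcripts).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons,
                             cds_sequence = NULL) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$end <= exons$start))
    stop("exon end must exceed start (half-open intervals)", call. = FALSE)
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("exon intervals must be disjoint", call. = FALSE)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'", call. = FALSE)
  width <- sum(exons$end - exons$start)
  if (!is.null(cds_sequence)) {
    cds_sequence <- check_dna(cds_sequence)
    if (nchar(cds_sequence) != width)
      stop("cds_sequence length (", nchar(cds_sequence),
           ") does not match total exon span (", width, ")", call. = FALSE)
  }
  if (width %% 3L != 0L)
    warning("coding length of ", transcript_id,
            " is not a multiple of 3")
  structure(list(transcript_id = as.character(transcript_id),
                 chrom = as.character(chrom), strand = strand,
                 exons = exons, cds_sequence = cds_sequence,
                 cds_length = width),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("Transcript", x$transcript_id, "(", x$chrom, x$strand, "):",
      nrow(x$exons), "exons,", x$cds_length, "coding bases\n")
  invisible(x)
}

#' Is a genomic position range inside the coding region of a transcript?
#'
#' @param transcript A `transcript_model`.
#' @param pos 1-based genomic position of the first base.
#' @param width Number of reference bases (default 1).
#' @return `TRUE` iff the whole range lies within a single exon.
#' @export
in_coding_region <- function(transcript, pos, width = 1L) {
  s0 <- pos - 1L                      # to 0-based
  e0 <- s0 + width
  any(transcript$exons$start <= s0 & e0 <= transcript$exons$end)
}

#' Map a genomic position to a coding (CDS) coordinate
#'
#' @param transcript A `transcript_model`.
#' @param pos 1-based genomic position inside an exon.
#' @return 1-based position in the spliced CDS, counted in transcription
#'   order (from the 3'-most genomic base for `-` strand transcripts).
#' @export
genomic_to_cds <- function(transcript, pos) {
  ex <- transcript$exons
  p0 <- pos - 1L
  hit <- which(ex$start <= p0 & p0 < ex$end)
  if (!length(hit))
    stop("position ", pos, " is not in an exon of ",
         transcript$transcript_id, call. = FALSE)
  # widths of the preceding exons plus the offset inside the hit exon
  offset_plus <- if (hit > 1L)
    sum(ex$end[seq_len(hit - 1L)] - ex$start[seq_len(hit - 1L)]) +
      (p0 - ex$start[hit]) else p0 - ex$start[hit]
  if (transcript$strand == "+") offset_plus + 1L
  else transcript$cds_length - offset_plus
}

#' Project a genomic variant into CDS coordinates
#'
#' Converts a VCF-style variant (1-based genomic, REF/ALT on the plus
#' strand) to CDS coordinates for [apply_variants()].  For minus-strand
#' transcripts both alleles are reverse-complemented and the position
#' re-anchored at the genomically last REF base.  Variants that are not
#' fully contained in one exon are rejected: the effect of an indel
#' spanning an exon boundary on the spliced product is not defined here.
#'
#' @param transcript A `transcript_model`.
#' @param pos,ref,alt Variant in genomic coordinates.
#' @return List with `pos`, `ref`, `alt` in CDS space.
#' @export
project_variant_to_cds <- function(transcript, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!in_coding_region(transcript, pos, nchar(ref)))
    stop("variant at ", transcript$chrom, ":", pos,
         " is not fully contained in a coding exon of ",
         transcript$transcript_id,
         " (boundary-spanning variants are rejected)", call. = FALSE)
  if (transcript$strand == "+") {
    list(pos = genomic_to_cds(transcript, pos), ref = ref, alt = alt)
  } else {
    list(pos = genomic_to_cds(transcript, pos + nchar(ref) - 1L),
         ref = revcomp(ref), alt = revcomp(alt))
  }
}

#' Extract the spliced CDS of a transcript from a genome sequence
#'
#' @param transcript A `transcript_model`.
#' @param genome Chromosome sequence (string) for `transcript$chrom`.
#' @return The spliced CDS string (reverse-complemented for `-` strand),
#'   also stored back in the returned transcript by
#'   [set_cds_from_genome()].
#' @export
extract_cds <- function(transcript, genome) {
  genome <- check_dna(genome)
  ex <- transcript$exons
  pieces <- substring(genome, ex$start + 1L, ex$end)
  cds <- paste(pieces, collapse = "")
  if (transcript$strand == "-") cds <- revcomp(cds)
  cds
}

#' @rdname extract_cds
#' @export
set_cds_from_genome <- function(transcript, genome) {
  transcript$cds_sequence <- extract_cds(transcript, genome)
  transcript
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Read transcript models from a 5-column TSV
#'
#' Columns: `transcript_id`, `chrom`, `strand`, `exon_start`, `exon_end`,
#' one row per exon, coordinates half-open 0-based.
#'
#' @param path TSV path (comment lines starting `#` ignored).
#' @return Named list of `transcript_model` objects.
#' @export
read_transcript_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("transcript_id", "chrom", "strand", "exon_start", "exon_end")
  if (!all(need %in% names(df)))
    stop("transcript TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(df, df$transcript_id), function(d)
    transcript_model(d$transcript_id[1], d$chrom[1], d$strand[1],
                     data.frame(start = d$exon_start, end = d$exon_end)))
  out[unique(df$transcript_id)]
}

#' Write transcript models to the 5-column TSV format
#'
#' @param transcripts List of `transcript_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_tsv <- function(transcripts, path) {
  if (inherits(transcripts, "transcript_model"))
    transcripts <- list(transcripts)
  df <- do.call(rbind, lapply(transcripts, function(tr)
    data.frame(transcript_id = tr$transcript_id, chrom = tr$chrom,
               strand = tr$strand, exon_start = tr$exons$start,
               exon_end = tr$exons$end)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read transcript models from a minimal GFF3 file
#'
#' Supports the common subset: `exon` (or `CDS`) features carrying a
#' `Parent=` or `transcript_id=` attribute; GFF3 1-based inclusive
#' coordinates are converted to the internal half-open convention.
#'
#' @param path GFF3 path.
#' @return Named list of `transcript_model` objects.
#' @export
read_transcript_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(p) length(p) == 9 &&
                   tolower(p[3]) %in% c("exon", "cds"), logical(1))
  f <- f[keep]
  if (!length(f)) stop("no exon/CDS features in GFF3: ", path,
                       call. = FALSE)
  parent <- vapply(f, function(p) {
    m <- regmatches(p[9],
                    regexpr("(Parent|transcript_id)=[^;]+", p[9]))
    if (!length(m)) stop("GFF3 feature lacks Parent/transcript_id: ",
                         p[9], call. = FALSE)
    sub("^[^=]+=", "", m)
  }, character(1))
  df <- data.frame(transcript_id = parent,
                   chrom = vapply(f, `[[`, character(1), 1),
                   strand = vapply(f, `[[`, character(1), 7),
                   exon_start = as.integer(vapply(f, `[[`, character(1),
                                                  4)) - 1L,
                   exon_end = as.integer(vapply(f, `[[`, character(1), 5)))
  out <- lapply(split(df, df$transcript_id), function(d)
    transcript_model(d$transcript_id[1], d$chrom[1], d$strand[1],
                     data.frame(start = d$exon_start, end = d$exon_end)))
  out[unique(df$transcript_id)]
}
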
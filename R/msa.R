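# Amino-acid alphabet in the canonical HMMER column order.
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHARS <- c("-", ".")

#' Construct a protein multiple sequence alignment
#'
#' A lightweight container for a gapped protein alignment: all rows must
#' have equal length, use only the 20 standard amino acids plus gap
#' characters (`-` or `.`), and there must be at least two rows.
#'
#' @param sequences Character vector of equal-length gapped protein strings.
#' @param ids Optional character vector of sequence identifiers; defaults to
#'   `seq1`, `seq2`, ...
#' @return An object of class `protein_msa` with elements `sequences`
#'   (uppercase, `.` normalised to `-`) and `ids`.
#' @examples
#' msa <- protein_msa(c("ACD-", "AC-E", "ACDE"))
#' ncol_msa(msa)
#' @export
protein_msa <- function(sequences, ids = NULL) {
  if (length(sequences) < 2L)
    stop("an alignment needs at least two sequences", call. = FALSE)
  sequences <- toupper(sequences)
  sequences <- gsub(".", "-", sequences, fixed = TRUE)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L)
    stop("alignment rows have unequal lengths", call. = FALSE)
  if (widths[1] == 0L)
    stop("alignment is empty (zero columns)", call. = FALSE)
  bad <- grepl(paste0("[^-", paste(AMINO_ACIDS, collapse = ""), "]"),
               sequences)
  if (any(bad))
    stop("invalid residue in sequence(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  if (length(ids) != length(sequences))
    stop("one identifier per sequence required", call. = FALSE)
  structure(list(sequences = unname(sequences), ids = as.character(ids)),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat("Protein multiple sequence alignment:",
      length(x$sequences), "sequences x", nchar(x$sequences[1]),
      "columns\n")
  show <- utils::head(seq_along(x$sequences), 6L)
  for (i in show) {
    s <- x$sequences[i]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-12s %s\n", x$ids[i], s))
  }
  if (length(x$sequences) > 6L)
    cat("  ... and", length(x$sequences) - 6L, "more\n")
  invisible(x)
}

#' Number of alignment columns
#' @param msa A `protein_msa`.
#' @return Integer column count.
#' @export
ncol_msa <- function(msa) nchar(msa$sequences[1])

# Alignment as a character matrix (rows = sequences, cols = columns).
msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$sequences, "", fixed = TRUE))
}

#' Read an aligned FASTA file as a protein alignment
#'
#' @param path Path to an aligned (gapped) protein FASTA file.
#' @return A `protein_msa`.
#' @export
read_msa_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  protein_msa(as.character(aa), ids = names(aa))
}

#' Write a protein alignment to aligned FASTA
#'
#' @param msa A `protein_msa`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  aa <- Biostrings::AAStringSet(msa$sequences)
  names(aa) <- msa$ids
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read a Stockholm-format protein alignment
#'
#' Supports the single- and multi-block Stockholm 1.0 layout used by HMMER
#' and Pfam: `# STOCKHOLM` header, `name sequence` rows (concatenated
#' across blocks), `#=G*` annotation lines ignored, terminated by `//`.
#'
#' @param path Path to a Stockholm file.
#' @return A `protein_msa`.
#' @export
read_msa_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^#\\s*STOCKHOLM", lines[1]))
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path,
         call. = FALSE)
  seqs <- list()
  for (ln in lines[-1]) {
    if (grepl("^//", ln)) break
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed Stockholm sequence line: ", ln, call. = FALSE)
    nm <- parts[1]
    seqs[[nm]] <- paste0(if (is.null(seqs[[nm]])) "" else seqs[[nm]],
                         parts[2])
  }
  if (!length(seqs)) stop("no sequences in Stockholm file", call. = FALSE)
  protein_msa(unlist(seqs, use.names = FALSE), ids = names(seqs))
}
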
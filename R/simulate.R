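#' Configuration for the synthetic-data generators
#'
#' All generators are deterministic functions of their configuration:
#' the same `seed` reproduces the same families, variants and catalogs
#' byte for byte.
#'
#' @param seed Integer RNG seed.
#' @param root_protein_length Length of the simulated family's root
#'   protein.
#' @param family_size Number of homolog sequences in a family.
#' @param substitution_rate Per-site substitution probability on each
#'   branch of the star phylogeny, in `[0, 1]`.
#' @param conserved_fraction Fraction of columns that never mutate.
#' @param indel_catalog_density Expected indels per base pair when
#'   simulating indel catalogs.
#' @param class_frequencies Length-4 probability vector over the four
#'   genotype/location classes used by
#'   [simulate_genotyped_variants()].
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              root_protein_length = 120L,
                              family_size = 12L,
                              substitution_rate = 0.1,
                              conserved_fraction = 0.4,
                              indel_catalog_density = 0.3,
                              class_frequencies =
                                c(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            conserved_fraction >= 0, conserved_fraction <= 1,
            indel_catalog_density >= 0,
            length(class_frequencies) == 4,
            all(class_frequencies >= 0),
            abs(sum(class_frequencies) - 1) < 1e-9,
            family_size >= 2, root_protein_length >= 1)
  structure(list(seed = as.integer(seed),
                 root_protein_length = as.integer(root_protein_length),
                 family_size = as.integer(family_size),
                 substitution_rate = substitution_rate,
                 conserved_fraction = conserved_fraction,
                 indel_catalog_density = indel_catalog_density,
                 class_frequencies = class_frequencies),
            class = "simulation_config")
}

#' Simulate a homologous protein family
#'
#' Draws a random root protein and mutates independent copies of it
#' (star phylogeny): a fixed, randomly chosen `conserved_fraction` of
#' positions never mutates; every other position substitutes to a
#' uniformly chosen different residue with probability
#' `substitution_rate` per sequence.  The result is gap-free, so every
#' column is a match column of the fitted profile HMM.
#'
#' @param config A [simulation_config()].
#' @return A [protein_msa] with attributes `root` (the root protein) and
#'   `conserved_columns`.
#' @export
simulate_homolog_family <- function(config = simulation_config()) {
  set.seed(config$seed)
  L <- config$root_protein_length
  root <- sample(AMINO_ACIDS, L, replace = TRUE)
  n_cons <- round(config$conserved_fraction * L)
  conserved <- sort(sample.int(L, n_cons))
  rows <- matrix(rep(root, config$family_size), nrow = config$family_size,
                 byrow = TRUE)
  mutable <- setdiff(seq_len(L), conserved)
  for (s in seq_len(config$family_size)) {
    hit <- mutable[stats::runif(length(mutable)) <
                     config$substitution_rate]
    for (j in hit) {
      rows[s, j] <- sample(setdiff(AMINO_ACIDS, rows[s, j]), 1L)
    }
  }
  msa <- protein_msa(apply(rows, 1, paste, collapse = ""),
                     ids = paste0("hom", seq_len(config$family_size)))
  attr(msa, "root") <- paste(root, collapse = "")
  attr(msa, "conserved_columns") <- conserved
  msa
}

#' Reverse-translate a protein to a coding sequence
#'
#' Uses a fixed codon per amino acid (the alphabetically first codon of
#' the standard code), so the mapping is deterministic; a TAA stop is
#' appended when `add_stop` is set.
#'
#' @param protein Protein string.
#' @param add_stop Append a stop codon.
#' @return A CDS string whose translation ([translate_cds()]) is
#'   `protein`.
#' @export
reverse_translate <- function(protein, add_stop = TRUE) {
  aa <- check_protein_seq(protein)
  code <- Biostrings::GENETIC_CODE
  codon_for <- vapply(AMINO_ACIDS, function(a)
    sort(names(code)[code == a])[1], character(1))
  paste0(paste(codon_for[aa], collapse = ""),
         if (add_stop) "TAA" else "")
}

#' Simulate genotyped variants with known class labels
#'
#' Emits SNP variants whose genotype/location class for `transcript` is
#' known by construction: coding positions with derived homozygous,
#' ancestral homozygous or heterozygous genotypes (classes 1-3) and
#' non-coding positions (class 4), in the configured proportions.
#'
#' @param config A [simulation_config()].
#' @param transcript A `transcript_model`.
#' @param n Number of variants.
#' @param gene_length Span of the simulated gene (defaults to the last
#'   exon end plus 200).
#' @return A genotyped-variant table with an extra `true_class` column.
#' @export
simulate_genotyped_variants <- function(config, transcript, n = 100L,
                                        gene_length = NULL) {
  set.seed(config$seed + 1L)
  if (is.null(gene_length))
    gene_length <- max(transcript$exons$end) + 200L
  coding_pos <- unlist(mapply(function(s, e) seq(s + 1L, e),
                              transcript$exons$start,
                              transcript$exons$end, SIMPLIFY = FALSE))
  noncoding_pos <- setdiff(seq_len(gene_length), coding_pos)
  classes <- sample.int(4L, n, replace = TRUE,
                        prob = config$class_frequencies)
  pos <- integer(n)
  need_coding <- classes %in% 1:3
  if (sum(need_coding) > length(coding_pos) ||
      sum(!need_coding) > length(noncoding_pos))
    stop("transcript too small for the requested number of variants",
         call. = FALSE)
  pos[need_coding] <- sample(coding_pos, sum(need_coding))
  pos[!need_coding] <- sample(noncoding_pos, sum(!need_coding))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                character(1), USE.NAMES = FALSE)
  gt1 <- ifelse(classes == 1L, alt, ref)
  gt2 <- ifelse(classes %in% c(1L), alt,
                ifelse(classes == 3L, alt, ref))
  gt1[classes == 3L] <- ref[classes == 3L]
  # class 4: arbitrary genotypes; keep homozygous reference for clarity
  df <- data.frame(id = paste0("sv", seq_len(n)),
                   chrom = transcript$chrom, pos = pos,
                   ref = ref, alt = alt, gt1 = gt1, gt2 = gt2,
                   ancestral = ref, true_class = classes)
  df <- df[order(df$pos), , drop = FALSE]
  rownames(df) <- NULL
  as_genotyped_variants(df)
}

#' The three-transcript worked example
#'
#' A deterministic preset encoding the classic toy configuration used to
#' illustrate genotype-based set formation: one gene with three
#' alternatively spliced transcripts and eight genotyped variants
#' (`v1`..`v8`) such that the Class-1 members are `{v1, v3}` for
#' transcript 1, `{v3, v6, v8}` for transcript 2 and `{v6, v8}` for
#' transcript 3, with the remaining variants heterozygous, ancestral or
#' non-coding.  Variant `v1` has ancestral allele `T` and genotype
#' `A|A`.
#'
#' @return A list with `gene` (a 1000-bp sequence), `transcripts` (list
#'   of three `transcript_model`s), `gvariants` (genotyped-variant
#'   table) and `expected_sets` (named list of expected Class-1 member
#'   ids per transcript).
#' @export
worked_example_preset <- function() {
  set.seed(73015L)   # preset-internal; the configuration is hard-coded
  gene <- paste(sample(c("A", "C", "G", "T"), 1000L, replace = TRUE),
                collapse = "")
  substr(gene, 110L, 110L) <- "T"   # v1 ancestral/reference allele
  transcripts <- list(
    transcript_model("T1", "gene1", "+",
                     data.frame(start = 99L, end = 300L)),
    transcript_model("T2", "gene1", "+",
                     data.frame(start = c(199L, 449L),
                                end = c(349L, 800L))),
    transcript_model("T3", "gene1", "+",
                     data.frame(start = 500L, end = 800L)))
  base_at <- function(p) substr(gene, p, p)
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  pos <- c(110L, 160L, 260L, 310L, 410L, 510L, 560L, 710L)
  ref <- vapply(pos, base_at, character(1))
  alt <- vapply(ref, other, character(1), USE.NAMES = FALSE)
  alt[1] <- "A"                     # v1: T -> A, genotype A|A
  # genotypes: hom-derived (class 1 where coding) unless stated
  gt1 <- alt; gt2 <- alt
  gt1[2] <- ref[2]                  # v2 heterozygous
  gt1[4] <- ref[4]; gt2[4] <- ref[4]   # v4 homozygous ancestral
  gt1[7] <- ref[7]                  # v7 heterozygous
  gv <- as_genotyped_variants(data.frame(
    id = paste0("v", 1:8), chrom = "gene1", pos = pos,
    ref = ref, alt = alt, gt1 = gt1, gt2 = gt2, ancestral = ref))
  list(gene = gene, transcripts = transcripts, gvariants = gv,
       expected_sets = list(T1 = c("v1", "v3"),
                            T2 = c("v3", "v6", "v8"),
                            T3 = c("v6", "v8")))
}

#' Simulate an indel catalog
#'
#' Places indels uniformly over a coding region with length changes
#' drawn from \{-5..-1, +1..+5\}, so both admissible and inadmissible
#' indels (multiples of 3, length 5) occur and the admission filters
#' and search caps are exercised.
#'
#' @param config A [simulation_config()].
#' @param region_length Length of the region in base pairs (at least the
#'   search window).
#' @return An indel catalog data frame (`id`, `pos`, `delta`).
#' @export
simulate_indel_catalog <- function(config, region_length = 500L) {
  stopifnot(region_length >= search_params()$window)
  set.seed(config$seed + 2L)
  n <- round(region_length * config$indel_catalog_density)
  if (n == 0L)
    return(data.frame(id = character(), pos = integer(),
                      delta = integer()))
  pos <- sort(sample.int(region_length, n, replace = TRUE))
  delta <- sample(c(-5:-1, 1:5), n, replace = TRUE)
  data.frame(id = paste0("indel", seq_len(n)), pos = pos, delta = delta)
}

#' Adversarially dense indel catalog
#'
#' A deterministic catalog of 36 admissible frameshift indels
#' (alternating +1/-1) packed into an 18-bp window, so the per-sum cap,
#' the set-size cap and the window bound are all binding during
#' compensatory-set search.
#'
#' @return An indel catalog data frame; the natural search target is
#'   `adv01` (the first -1 deletion).
#' @export
adversarial20_preset <- function() {
  pos <- rep(100:117, each = 2L)
  delta <- rep(c(-1L, 1L), times = 18L)
  data.frame(id = sprintf("adv%02d", seq_along(pos)),
             pos = pos, delta = delta)
}
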
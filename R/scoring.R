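#' Odds ratio of wild-type versus mutant generation probabilities
#'
#' The joint-effect score for a protein carrying one or more variants:
#' `O = (P_w / (1 - P_w)) / (P_m / (1 - P_m))`, where `P_w` and `P_m` are
#' the probabilities that the wild-type and mutant proteins were generated
#' by the family profile HMM.  `O > 1` suggests the variant set is
#' deleterious, `O` near 1 neutral, `O < 1` beneficial.
#'
#' @param p_w,p_m Generation probabilities, each strictly in (0, 1).
#' @param neutral_band Half-width, in log2 units, of the band around
#'   `O = 1` reported as neutral (see [interpret_odds()]).
#' @return A list of class `odds_ratio_score` with elements `O`, `p_w`,
#'   `p_m`, `log2_O` and `interpretation`.
#' @examples
#' odds_ratio(0.9, 0.5)   # O = 9, deleterious
#' @export
odds_ratio <- function(p_w, p_m, neutral_band = 0.5) {
  check_prob(p_w, "p_w")
  check_prob(p_m, "p_m")
  O <- (p_w / (1 - p_w)) / (p_m / (1 - p_m))
  structure(list(O = O, p_w = p_w, p_m = p_m, log2_O = log2(O),
                 interpretation = interpret_odds(O, neutral_band)),
            class = "odds_ratio_score")
}

#' @export
print.odds_ratio_score <- function(x, ...) {
  cat(sprintf("odds ratio O = %.4g (log2 O = %.4g): %s\n",
              x$O, x$log2_O, x$interpretation))
  invisible(x)
}

#' Bit-score difference for SNP variants
#'
#' For pure-SNP variant sets the odds ratio is less reliable than the
#' plain bit-score difference, so SNPs are scored as
#' `log2(P_w / P_m)`.  Under the logistic probability bridge this equals
#' the difference of the model bit scores only approximately for large
#' scores; both readings are kept behind `score_type` switches.
#'
#' @inheritParams odds_ratio
#' @return A single number, `log2(p_w / p_m)`; positive for deleterious
#'   SNPs.
#' @examples
#' snp_score(0.8, 0.2)   # 2
#' @export
snp_score <- function(p_w, p_m) {
  check_prob(p_w, "p_w")
  check_prob(p_m, "p_m")
  log2(p_w / p_m)
}

#' Interpret an odds ratio as deleterious, neutral or beneficial
#'
#' The raw score is continuous; the qualitative call uses a symmetric
#' band on the log2 scale: neutral iff `|log2 O| <= neutral_band`
#' (default half a bit), deleterious above it, beneficial below.
#'
#' @param O Positive odds ratio.
#' @param neutral_band Nonnegative half-width of the neutral band in log2
#'   units.
#' @return One of `"deleterious"`, `"neutral"`, `"beneficial"`.
#' @export
interpret_odds <- function(O, neutral_band = 0.5) {
  if (!is.numeric(O) || length(O) != 1 || is.na(O) || O <= 0)
    stop("'O' must be a single positive number", call. = FALSE)
  l <- log2(O)
  if (l > neutral_band) "deleterious"
  else if (l < -neutral_band) "beneficial"
  else "neutral"
}

#' Score a mutant protein against the wild type under a profile HMM
#'
#' The elementary scoring step shared by single variants and joint sets:
#' both proteins are scored by Viterbi, converted to generation
#' probabilities, and compared either by odds ratio (`"odds_ratio"`, the
#' indel default) or bit-score difference (`"snp_bits"`).
#'
#' @param hmm A `profile_hmm`.
#' @param wild,mutant Nonempty protein strings; `mutant` carries all
#'   variants of the set simultaneously.
#' @param score_type `"odds_ratio"` or `"snp_bits"`.
#' @return A list with `score` (O for odds-ratio, bits for snp), `log2_O`,
#'   `bit_w`, `bit_m`, `p_w`, `p_m`, `score_type`, `interpretation`.
#' @export
score_mutant <- function(hmm, wild, mutant,
                         score_type = c("odds_ratio", "snp_bits")) {
  score_type <- match.arg(score_type)
  sw <- viterbi_bit_score(hmm, wild)
  sm <- viterbi_bit_score(hmm, mutant)
  if (score_type == "odds_ratio") {
    # algebraically O = 2^(bit_w - bit_m) under the logistic bridge;
    # computed that way to stay finite for extreme bit scores
    l2 <- sw$bit_score - sm$bit_score
    list(score = 2^l2, log2_O = l2,
         bit_w = sw$bit_score, bit_m = sm$bit_score,
         p_w = sw$probability, p_m = sm$probability,
         score_type = score_type,
         interpretation = interpret_odds(2^l2))
  } else {
    b <- log2(sw$probability / sm$probability)
    list(score = b, log2_O = NA_real_,
         bit_w = sw$bit_score, bit_m = sm$bit_score,
         p_w = sw$probability, p_m = sm$probability,
         score_type = score_type,
         interpretation = if (b > 0.5) "deleterious"
                          else if (b < -0.5) "beneficial" else "neutral")
  }
}

#' Joint and single-variant scores for a variant set on a coding sequence
#'
#' Applies the whole variant set to the CDS at once (all variants on the
#' same haplotype), translates wild-type and mutant proteins, and scores
#' the mutant against the wild type; then scores each member variant
#' alone to give the single scores `s_i`.  With `score_type = "auto"`
#' (default) a set containing any indel is scored by odds ratio and a
#' pure-SNP set by the bit-score difference.  Scores are reported on the
#' log2 scale (`log2 O` for odds-ratio scoring) so that joint and single
#' scores are directly comparable and usable by [classify_cm()].
#'
#' @param hmm A `profile_hmm` for the protein family of the transcript.
#' @param cds Wild-type coding sequence (string, A/C/G/T).
#' @param variants A variant table in CDS coordinates as accepted by
#'   [apply_variants()]: data frame with `pos`, `ref`, `alt` and
#'   optionally `id`.
#' @param score_type `"auto"`, `"odds_ratio"` or `"snp_bits"`.
#' @param set_id,transcript_id,individual_id Optional identifiers carried
#'   into the record.
#' @return An object of class `set_score_record`: a list with `set_id`,
#'   `transcript_id`, `individual_id`, `n`, `score_type`, `S` (joint
#'   score, log2 scale), `singles` (named numeric `s_i`), `joint` (the
#'   full [score_mutant()] result) and `interpretation`.
#' @export
score_variant_set <- function(hmm, cds, variants,
                              score_type = c("auto", "odds_ratio",
                                             "snp_bits"),
                              set_id = NA_character_,
                              transcript_id = NA_character_,
                              individual_id = NA_character_) {
  score_type <- match.arg(score_type)
  variants <- as_variant_table(variants)
  if (score_type == "auto") {
    has_indel <- any(nchar(variants$ref) != nchar(variants$alt))
    score_type <- if (has_indel || nrow(variants) == 0) "odds_ratio"
                  else "snp_bits"
  }
  wild_protein <- translate_cds(cds)
  if (nrow(variants) == 0L)
    warning("empty variant list: joint score is the identity value")
  mut <- apply_variants(cds, variants)
  mutant_protein <- translate_cds(mut$cds, warn_partial = FALSE)
  joint <- score_mutant(hmm, wild_protein, mutant_protein, score_type)

  singles <- numeric(nrow(variants))
  names(singles) <- variants$id
  for (i in seq_len(nrow(variants))) {
    mi <- apply_variants(cds, variants[i, , drop = FALSE])
    pi <- translate_cds(mi$cds, warn_partial = FALSE)
    si <- score_mutant(hmm, wild_protein, pi, score_type)
    singles[i] <- if (score_type == "odds_ratio") si$log2_O else si$score
  }
  S <- if (score_type == "odds_ratio") joint$log2_O else joint$score
  structure(list(set_id = set_id, transcript_id = transcript_id,
                 individual_id = individual_id,
                 n = nrow(variants), score_type = score_type,
                 S = S, singles = singles, joint = joint,
                 interpretation = joint$interpretation),
            class = "set_score_record")
}

#' @export
print.set_score_record <- function(x, ...) {
  cat("Variant set score (", x$score_type, ", log2 scale)\n", sep = "")
  if (!is.na(x$set_id)) cat("  set:       ", x$set_id, "\n")
  cat("  n variants:", x$n, "\n")
  cat(sprintf("  joint S:    %.4f  (%s)\n", x$S, x$interpretation))
  if (x$n > 0)
    cat("  singles:   ", paste(sprintf("%.4f", x$singles),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Write a TSV report for scored variant sets
#'
#' @param records A list of `set_score_record` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_set_score_tsv <- function(records, path) {
  if (inherits(records, "set_score_record")) records <- list(records)
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(set_id = r$set_id, transcript_id = r$transcript_id,
               individual_id = r$individual_id, n_variants = r$n,
               score_type = r$score_type, S = r$S,
               single_scores = paste(signif(r$singles, 8),
                                     collapse = ";"),
               interpretation = r$interpretation)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

check_prob <- function(p, what) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p >= 1)
    stop("'", what, "' must be strictly between 0 and 1 ",
         "(work in log-odds space for boundary scores)", call. = FALSE)
  invisible(p)
}
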
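#' Viterbi bit score of a protein sequence under a profile HMM
#'
#' Computes the log2-odds of the single best (Viterbi) state path through
#' the model against an i.i.d. null model that emits the background
#' distribution:
#' `bit_score = log2( P(seq, best path | HMM) / P(seq | null) )`.
#' Alignment is global: the path runs Begin to End through every layer,
#' using delete states for skipped match states and insert states for
#' extra residues.
#'
#' @param hmm A `profile_hmm`.
#' @param seq A single nonempty protein string over the 20-letter
#'   amino-acid alphabet.
#' @return A list of class `sequence_score` with `bit_score` and
#'   `probability` (see [generation_probability()]).
#' @examples
#' hmm <- profile_hmm(c("ACDEF", "ACDEF", "ACDEF"))
#' viterbi_bit_score(hmm, "ACDEF")
#' @export
viterbi_bit_score <- function(hmm, seq) {
  x <- check_protein_seq(seq)
  M <- hmm$M
  L <- length(x)
  xi <- match(x, AMINO_ACIDS)

  lt <- log2(hmm$trans)                 # -Inf where forbidden
  le_m <- log2(hmm$match_emissions)
  le_i <- log2(hmm$insert_emissions)

  neg <- -Inf
  # vM/vI/vD[k+1, i+1]: best log2 path prob ending in state layer k with i
  # residues emitted; layer 0 of M is Begin.
  vM <- matrix(neg, M + 1, L + 1)
  vI <- matrix(neg, M + 1, L + 1)
  vD <- matrix(neg, M + 1, L + 1)
  vM[1, 1] <- 0

  for (i in 0:L) {
    for (k in 0:M) {
      if (i > 0 && k > 0)
        vM[k + 1, i + 1] <- le_m[k, xi[i]] +
          max(vM[k, i] + lt[k, "MM"],
              vI[k, i] + lt[k, "IM"],
              vD[k, i] + lt[k, "DM"])
      if (i > 0)
        vI[k + 1, i + 1] <- le_i[k + 1, xi[i]] +
          max(vM[k + 1, i] + lt[k + 1, "MI"],
              vI[k + 1, i] + lt[k + 1, "II"],
              vD[k + 1, i] + lt[k + 1, "DI"])
      if (k > 0)
        vD[k + 1, i + 1] <-
          max(vM[k, i + 1] + lt[k, "MD"],
              vI[k, i + 1] + lt[k, "ID"],
              vD[k, i + 1] + lt[k, "DD"])
    }
  }
  best <- max(vM[M + 1, L + 1] + lt[M + 1, "MM"],
              vI[M + 1, L + 1] + lt[M + 1, "IM"],
              vD[M + 1, L + 1] + lt[M + 1, "DM"])
  null_bits <- sum(log2(hmm$bg[xi]))
  bits <- best - null_bits
  structure(list(bit_score = bits,
                 probability = generation_probability(bits)),
            class = "sequence_score")
}

#' @export
print.sequence_score <- function(x, ...) {
  cat(sprintf("bit score %.4f  (generation probability %.6g)\n",
              x$bit_score, x$probability))
  invisible(x)
}

#' Generation probability of a bit score
#'
#' Maps a log2-odds bit score `b` to the probability
#' `P = 2^b / (1 + 2^b)` that the sequence was generated by the model
#' rather than the null, the logistic bridge that makes the wild/mutant
#' odds ratio collapse to `2^(b_w - b_m)` exactly.  Strictly increasing;
#' `log2(P / (1 - P))` recovers `b`.
#'
#' @param bit_score Finite numeric bit score.
#' @return Probability strictly between 0 and 1.
#' @examples
#' generation_probability(0)   # 0.5
#' generation_probability(3)   # 8/9
#' @export
generation_probability <- function(bit_score) {
  if (!is.numeric(bit_score) || length(bit_score) != 1 ||
      !is.finite(bit_score))
    stop("'bit_score' must be a single finite number", call. = FALSE)
  # computed as plogis in base-2 for numerical symmetry at large |b|
  stats::plogis(bit_score * log(2))
}

#' Exhaustive best-path score (test oracle)
#'
#' Enumerates every state path through the model that emits the sequence
#' and returns the best log2-odds score.  Exponential in size, so it
#' refuses models with more than 5 match states or sequences longer
#' than 6; it exists as an independent check on [viterbi_bit_score()].
#'
#' @param hmm A `profile_hmm` with `M <= 5`.
#' @param seq Protein string of length `<= 6`.
#' @return A `sequence_score`, identical in contract to
#'   [viterbi_bit_score()].
#' @export
brute_force_best_path <- function(hmm, seq) {
  x <- check_protein_seq(seq)
  M <- hmm$M
  L <- length(x)
  if (M > 5 || L > 6)
    stop("brute-force oracle limited to M <= 5 and sequences <= 6",
         call. = FALSE)
  xi <- match(x, AMINO_ACIDS)
  lt <- log2(hmm$trans)
  le_m <- log2(hmm$match_emissions)
  le_i <- log2(hmm$insert_emissions)

  best <- -Inf
  # walk(type, layer, emitted, logp): extend the path by one state
  walk <- function(typ, k, i, logp) {
    if (!is.finite(logp)) return()
    # to End
    if (k == M && i == L) {
      s <- logp + lt[M + 1, paste0(typ, "M")]
      if (s > best) best <<- s
    }
    # to M_{k+1}
    if (k < M && i < L)
      walk("M", k + 1L, i + 1L,
           logp + lt[k + 1, paste0(typ, "M")] + le_m[k + 1, xi[i + 1]])
    # to I_k
    if (i < L)
      walk("I", k, i + 1L,
           logp + lt[k + 1, paste0(typ, "I")] + le_i[k + 1, xi[i + 1]])
    # to D_{k+1}
    if (k < M)
      walk("D", k + 1L, i,
           logp + lt[k + 1, paste0(typ, "D")])
  }
  walk("M", 0L, 0L, 0)
  bits <- unname(best) - sum(log2(hmm$bg[xi]))
  structure(list(bit_score = bits,
                 probability = generation_probability(bits)),
            class = "sequence_score")
}

# Validate and split a single protein string into residues.
check_protein_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq) || !nzchar(seq))
    stop("sequence must be a single nonempty string", call. = FALSE)
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- !(x %in% AMINO_ACIDS)
  if (any(bad))
    stop("invalid residue(s) in sequence: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  x
}
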
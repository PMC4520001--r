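TRANS_COLS <- c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DI", "DD")

#' Fit a profile hidden Markov model to a protein alignment
#'
#' Builds a left-to-right profile HMM with one match, insert and delete
#' state per consensus column, in the classic plan of Krogh/Durbin profile
#' models.  A column is a match (consensus) column iff its gap fraction is
#' strictly below 0.5; other columns feed the insert states.  Match
#' emissions are Laplace-smoothed column frequencies,
#' `(count + w) / (n_residues + 20 w)`.  Transition probabilities are
#' smoothed counts of the state paths traced by the aligned rows.  Insert
#' states emit the background distribution, so inserted residues are
#' scored against the same frequencies as the null model.  The null model
#' is i.i.d. emission of the (smoothed) overall residue frequencies of the
#' alignment.
#'
#' @param msa A [protein_msa], or a character vector of gapped sequences.
#' @param pseudocount Nonnegative Laplace pseudocount weight `w` added to
#'   every residue and legal-transition count.  With `w = 0`, residues and
#'   transitions unseen in the alignment get probability zero (their
#'   Viterbi log-score is `-Inf`); the default `w = 1` keeps every path
#'   realisable.
#' @return An object of class `profile_hmm`; see [new_profile_hmm()] for
#'   its components.
#' @examples
#' msa <- protein_msa(c("ACDEF", "ACDEF", "ACDDF", "AC-EF"))
#' hmm <- profile_hmm(msa)
#' hmm
#' predict(hmm, "ACDEF")
#' @seealso [viterbi_bit_score()], [predict.profile_hmm()],
#'   [read_hmmer3_model()]
#' @export
profile_hmm <- function(msa, pseudocount = 1) {
  if (is.character(msa)) msa <- protein_msa(msa)
  if (!inherits(msa, "protein_msa"))
    stop("'msa' must be a protein_msa", call. = FALSE)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      is.na(pseudocount) || pseudocount < 0)
    stop("'pseudocount' must be a single nonnegative number", call. = FALSE)
  w <- pseudocount
  mat <- msa_matrix(msa)
  nseq <- nrow(mat)
  is_gap <- mat == "-"

  gap_frac <- colMeans(is_gap)
  match_cols <- which(gap_frac < 0.5)
  M <- length(match_cols)
  if (M == 0L)
    stop("degenerate model: no column has gap fraction below 0.5",
         call. = FALSE)

  # background: overall residue frequencies, smoothed so it is strictly
  # positive even at pseudocount 0 (the null must assign P > 0 everywhere)
  res_counts <- table(factor(mat[!is_gap], levels = AMINO_ACIDS))
  bg <- (as.numeric(res_counts) + max(w, 1)) /
    (sum(res_counts) + 20 * max(w, 1))
  names(bg) <- AMINO_ACIDS

  # match emissions: Laplace-smoothed per-column counts
  match_emissions <- matrix(0, M, 20, dimnames = list(NULL, AMINO_ACIDS))
  for (j in seq_len(M)) {
    col <- mat[, match_cols[j]]
    col <- col[col != "-"]
    cnt <- as.numeric(table(factor(col, levels = AMINO_ACIDS)))
    tot <- length(col) + 20 * w
    if (tot == 0) stop("empty match column", call. = FALSE)
    match_emissions[j, ] <- (cnt + w) / tot
  }

  insert_emissions <- matrix(rep(bg, each = M + 1), M + 1, 20,
                             dimnames = list(NULL, AMINO_ACIDS))

  # transition counts from the state path of each aligned row
  counts <- matrix(0, M + 1, 9, dimnames = list(NULL, TRANS_COLS))
  col_is_match <- logical(ncol(mat))
  col_is_match[match_cols] <- TRUE
  for (s in seq_len(nseq)) {
    prev_type <- "M"      # Begin behaves as M_0
    prev_k <- 0L
    k <- 0L
    for (j in seq_len(ncol(mat))) {
      if (col_is_match[j]) {
        k <- k + 1L
        typ <- if (is_gap[s, j]) "D" else "M"
      } else {
        if (is_gap[s, j]) next
        typ <- "I"
      }
      counts[prev_k + 1L, paste0(prev_type, typ)] <-
        counts[prev_k + 1L, paste0(prev_type, typ)] + 1
      prev_type <- typ
      prev_k <- if (typ == "I") prev_k else k
    }
    # exit to End: uses the "*M" slot of the last layer (must be M)
    counts[prev_k + 1L, paste0(prev_type, "M")] <-
      counts[prev_k + 1L, paste0(prev_type, "M")] + 1
  }

  trans <- normalise_transitions(counts, M, w)

  hmm <- new_profile_hmm(match_emissions, insert_emissions, trans, bg)
  hmm$pseudocount <- w
  hmm$match_columns <- match_cols
  hmm$nseq <- nseq
  hmm
}

# Smooth and row-normalise raw transition counts.  Legal successor triples:
# row k < M: (MM,MI,MD), (IM,II,ID), (DM,DI,DD); row M loses the D column
# (no D_{M+1}); row 0 has no D_0 so its D-source triple is zeroed.
normalise_transitions <- function(counts, M, w) {
  trans <- matrix(0, M + 1, 9, dimnames = list(NULL, TRANS_COLS))
  groups <- list(c("MM", "MI", "MD"), c("IM", "II", "ID"),
                 c("DM", "DI", "DD"))
  for (k in 0:M) {
    for (g in groups) {
      if (k == 0L && g[1] == "DM") next
      legal <- if (k == M) g[1:2] else g
      cnt <- counts[k + 1L, legal] + w
      tot <- sum(cnt)
      trans[k + 1L, legal] <-
        if (tot > 0) cnt / tot else rep(1 / length(legal), length(legal))
    }
  }
  trans
}

#' Assemble a profile HMM from explicit parameter matrices
#'
#' Low-level constructor used by the fitting routine, the HMMER3 reader
#' and tests that need hand-specified toy models.  All invariants are
#' checked: each emission row and each legal outgoing-transition triple
#' must sum to 1 within 1e-9.
#'
#' @param match_emissions `M x 20` matrix, one row per match state, columns
#'   in the order `ACDEFGHIKLMNPQRSTVWY`.
#' @param insert_emissions `(M+1) x 20` matrix for insert states I0..IM.
#' @param trans `(M+1) x 9` matrix with columns
#'   `MM, MI, MD, IM, II, ID, DM, DI, DD`; row `k+1` holds the transitions
#'   out of layer `k` (`MM` at the last row is the transition to End).
#' @param bg Length-20 background (null) emission distribution.
#' @param name Optional model name.
#' @return An object of class `profile_hmm` with elements `M`,
#'   `match_emissions`, `insert_emissions`, `trans`, `bg`, `consensus`.
#' @export
new_profile_hmm <- function(match_emissions, insert_emissions, trans, bg,
                            name = NULL) {
  M <- nrow(match_emissions)
  stopifnot(M >= 1, ncol(match_emissions) == 20,
            nrow(insert_emissions) == M + 1, ncol(insert_emissions) == 20,
            nrow(trans) == M + 1, ncol(trans) == 9, length(bg) == 20)
  colnames(match_emissions) <- AMINO_ACIDS
  colnames(insert_emissions) <- AMINO_ACIDS
  colnames(trans) <- TRANS_COLS
  names(bg) <- AMINO_ACIDS
  hmm <- structure(
    list(M = M,
         match_emissions = match_emissions,
         insert_emissions = insert_emissions,
         trans = trans,
         bg = bg,
         consensus = paste(AMINO_ACIDS[max.col(match_emissions)],
                           collapse = ""),
         name = name),
    class = "profile_hmm")
  validate_profile_hmm(hmm)
  hmm
}

#' Check the stochasticity invariants of a profile HMM
#'
#' @param hmm A `profile_hmm`.
#' @param tol Tolerance on each sum-to-one check.
#' @return `hmm`, invisibly; errors if an invariant fails.
#' @export
validate_profile_hmm <- function(hmm, tol = 1e-9) {
  if (any(abs(rowSums(hmm$match_emissions) - 1) > tol))
    stop("match emission rows must sum to 1", call. = FALSE)
  if (any(abs(rowSums(hmm$insert_emissions) - 1) > tol))
    stop("insert emission rows must sum to 1", call. = FALSE)
  if (abs(sum(hmm$bg) - 1) > tol)
    stop("background distribution must sum to 1", call. = FALSE)
  if (any(hmm$match_emissions < 0) || any(hmm$insert_emissions < 0) ||
      any(hmm$trans < 0) || any(hmm$bg < 0))
    stop("negative probability in model", call. = FALSE)
  M <- hmm$M
  for (k in 0:M) {
    grp <- list(c("MM", "MI", "MD"), c("IM", "II", "ID"),
                c("DM", "DI", "DD"))
    for (g in grp) {
      if (k == 0L && g[1] == "DM") next
      s <- sum(hmm$trans[k + 1L, if (k == M) g[1:2] else g])
      if (abs(s - 1) > tol)
        stop(sprintf("transitions out of %s_%d sum to %.12f, not 1",
                     substr(g[1], 1, 1), k, s), call. = FALSE)
    }
  }
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("Profile HMM", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "with", x$M, "match states\n")
  cons <- x$consensus
  if (nchar(cons) > 60) cons <- paste0(substr(cons, 1, 57), "...")
  cat("  consensus:", cons, "\n")
  if (!is.null(x$nseq))
    cat("  trained on", x$nseq, "sequences, pseudocount",
        x$pseudocount, "\n")
  invisible(x)
}

#' @export
summary.profile_hmm <- function(object, ...) {
  max_match <- apply(object$match_emissions, 1, max)
  out <- list(M = object$M,
              consensus = object$consensus,
              mean_top_match_probability = mean(max_match),
              min_top_match_probability = min(max_match),
              background_entropy_bits =
                -sum(object$bg * log2(object$bg)))
  class(out) <- "summary.profile_hmm"
  out
}

#' @export
print.summary.profile_hmm <- function(x, ...) {
  cat("Profile HMM summary\n")
  cat("  match states:          ", x$M, "\n")
  cat("  consensus:             ",
      if (nchar(x$consensus) > 50)
        paste0(substr(x$consensus, 1, 47), "...") else x$consensus, "\n")
  cat("  mean top match prob:   ", signif(x$mean_top_match_probability, 4),
      "\n")
  cat("  min top match prob:    ", signif(x$min_top_match_probability, 4),
      "\n")
  cat("  background entropy:    ", signif(x$background_entropy_bits, 4),
      "bits\n")
  invisible(x)
}

#' @export
coef.profile_hmm <- function(object, ...) {
  list(match_emissions = object$match_emissions,
       insert_emissions = object$insert_emissions,
       transitions = object$trans,
       background = object$bg)
}

#' Score protein sequences against a fitted profile HMM
#'
#' @param object A `profile_hmm`.
#' @param newdata Character vector of protein sequences (or an
#'   `AAStringSet`).
#' @param ... Unused.
#' @return A data frame with one row per sequence: `id`, `bit_score`
#'   (Viterbi log2-odds against the null model) and `probability` (the
#'   generation probability, see [generation_probability()]).
#' @export
predict.profile_hmm <- function(object, newdata, ...) {
  if (inherits(newdata, "AAStringSet")) {
    ids <- names(newdata)
    newdata <- as.character(newdata)
  } else ids <- names(newdata)
  if (is.null(ids)) ids <- paste0("seq", seq_along(newdata))
  bits <- vapply(newdata, function(s) viterbi_bit_score(object, s)$bit_score,
                 numeric(1), USE.NAMES = FALSE)
  data.frame(id = ids, bit_score = bits,
             probability = vapply(bits, generation_probability, numeric(1)),
             row.names = NULL)
}

#' Simulate protein sequences from a profile HMM
#'
#' Samples state paths from Begin to End according to the transition
#' probabilities and emits residues from the corresponding emission
#' distributions.
#'
#' @param object A `profile_hmm`.
#' @param nsim Number of sequences.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Character vector of `nsim` protein sequences.
#' @export
simulate.profile_hmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  M <- object$M
  out <- character(nsim)
  for (n in seq_len(nsim)) {
    res <- character(0)
    typ <- "M"; k <- 0L
    repeat {
      legal <- paste0(typ, c("M", "I", "D"))
      p <- object$trans[k + 1L, legal]
      nxt <- sample(c("M", "I", "D"), 1, prob = p)
      if (nxt == "I") {
        res <- c(res, sample(AMINO_ACIDS, 1,
                             prob = object$insert_emissions[k + 1L, ]))
        typ <- "I"
      } else {
        k <- k + 1L
        if (nxt == "M" && k > M) break   # reached End
        if (nxt == "M")
          res <- c(res, sample(AMINO_ACIDS, 1,
                               prob = object$match_emissions[k, ]))
        typ <- nxt
      }
    }
    out[n] <- paste(res, collapse = "")
  }
  out
}
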
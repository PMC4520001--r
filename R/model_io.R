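# HMMER3 ASCII stores probabilities as negative natural logs, "*" for 0.
nl_to_p <- function(x) {
  p <- numeric(length(x))
  star <- x == "*"
  p[!star] <- exp(-as.numeric(x[!star]))
  p
}
p_to_nl <- function(p) ifelse(p <= 0, "*", sprintf("%.7f", -log(p)))

#' Read a HMMER3 ASCII profile (.hmm)
#'
#' Parses the `HMMER3/f` text format (amino alphabet only) into a
#' `profile_hmm`.  Emission and transition probabilities are recovered
#' from the negative-log lines; because the Plan7 topology has no
#' insert-to-delete or delete-to-insert transitions, those are zero in
#' the resulting model.  The file's `COMPO` composition line, when
#' present, provides the background (null) distribution; otherwise the
#' background is uniform.
#'
#' @param path Path to a `.hmm` file (first model in the file).
#' @return A `profile_hmm`.
#' @export
read_hmmer3_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^HMMER3", lines[1]))
    stop("not a HMMER3 ASCII model: ", path, call. = FALSE)
  name <- NULL
  M <- NA_integer_
  i <- 2L
  while (i <= length(lines) && !grepl("^HMM\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(kv) >= 2) {
      if (kv[1] == "NAME") name <- kv[2]
      if (kv[1] == "LENG") M <- as.integer(kv[2])
      if (kv[1] == "ALPH" && tolower(kv[2]) != "amino")
        stop("unsupported alphabet '", kv[2],
             "': only amino-acid models are supported", call. = FALSE)
    }
    i <- i + 1L
  }
  if (i > length(lines)) stop("malformed .hmm: no HMM section",
                              call. = FALSE)
  if (is.na(M)) stop("malformed .hmm: missing LENG", call. = FALSE)
  i <- i + 2L   # skip the HMM header line and the transition label line

  toks <- function(ln) strsplit(trimws(ln), "\\s+")[[1]]
  bg <- rep(1 / 20, 20)
  if (grepl("^\\s*COMPO", lines[i])) {
    v <- nl_to_p(toks(lines[i])[-1])
    bg <- v / sum(v)
    i <- i + 1L
  }
  insert_emissions <- matrix(0, M + 1, 20)
  trans <- matrix(0, M + 1, 9, dimnames = list(NULL, TRANS_COLS))
  match_emissions <- matrix(0, M, 20)

  insert_emissions[1, ] <- nl_to_p(toks(lines[i]))
  tr0 <- nl_to_p(toks(lines[i + 1L]))
  trans[1, c("MM", "MI", "MD", "IM", "II")] <- tr0[1:5]
  i <- i + 2L
  for (k in seq_len(M)) {
    mline <- toks(lines[i])
    if (as.integer(mline[1]) != k)
      stop("malformed .hmm: expected node ", k, call. = FALSE)
    match_emissions[k, ] <- nl_to_p(mline[2:21])
    insert_emissions[k + 1L, ] <- nl_to_p(toks(lines[i + 1L])[1:20])
    tr <- nl_to_p(toks(lines[i + 2L])[1:7])
    trans[k + 1L, c("MM", "MI", "MD", "IM", "II", "DM", "DD")] <- tr
    i <- i + 3L
  }
  # renormalise away the finite-precision loss of the text encoding
  match_emissions <- match_emissions / rowSums(match_emissions)
  insert_emissions <- insert_emissions / rowSums(insert_emissions)
  for (k in 0:M) {
    for (g in list(c("MM", "MI", "MD"), c("IM", "II", "ID"),
                   c("DM", "DI", "DD"))) {
      if (k == 0L && g[1] == "DM") next
      s <- sum(trans[k + 1L, g])
      if (s > 0) trans[k + 1L, g] <- trans[k + 1L, g] / s
    }
  }
  new_profile_hmm(match_emissions, insert_emissions, trans,
                  bg / sum(bg), name = name)
}

#' Write a profile HMM as HMMER3 ASCII
#'
#' Emits the `HMMER3/f` text layout.  The Plan7 topology has no
#' insert-to-delete or delete-to-insert transitions, so models with
#' nonzero `ID`/`DI` probabilities are projected: those probabilities
#' are dropped and the remaining transitions renormalised (a warning is
#' issued).  Writing a model read by [read_hmmer3_model()] round-trips
#' exactly up to the text precision.
#'
#' @param hmm A `profile_hmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmmer3_model <- function(hmm, path) {
  trans <- hmm$trans
  if (any(trans[, c("ID", "DI")] > 0)) {
    warning("model has insert<->delete transitions; projected onto the ",
            "Plan7 topology for HMMER3 output")
    trans[, c("ID", "DI")] <- 0
    for (k in 0:hmm$M) {
      for (g in list(c("IM", "II", "ID"), c("DM", "DI", "DD"))) {
        if (k == 0L && g[1] == "DM") next
        s <- sum(trans[k + 1L, g])
        if (s > 0) trans[k + 1L, g] <- trans[k + 1L, g] / s
      }
    }
  }
  fmt20 <- function(p) paste(vapply(p, p_to_nl, character(1)),
                             collapse = "  ")
  out <- c(
    "HMMER3/f [jointvar profile HMM]",
    paste0("NAME  ", if (is.null(hmm$name)) "model" else hmm$name),
    paste0("LENG  ", hmm$M),
    "ALPH  amino",
    paste0("HMM          ", paste(AMINO_ACIDS, collapse = "        ")),
    paste0("            m->m     m->i     m->d     i->m     i->i     ",
           "d->m     d->d"),
    paste0("  COMPO   ", fmt20(hmm$bg)),
    paste0("          ", fmt20(hmm$insert_emissions[1, ])),
    paste0("          ",
           paste(vapply(trans[1, c("MM", "MI", "MD", "IM", "II")],
                        p_to_nl, character(1)), collapse = "  "),
           "  0.0000000  *"))
  for (k in seq_len(hmm$M)) {
    tr <- trans[k + 1L, c("MM", "MI", "MD", "IM", "II", "DM", "DD")]
    out <- c(out,
             sprintf("%7d   %s", k, fmt20(hmm$match_emissions[k, ])),
             paste0("          ", fmt20(hmm$insert_emissions[k + 1L, ])),
             paste0("          ",
                    paste(vapply(tr, p_to_nl, character(1)),
                          collapse = "  ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Serialise a profile HMM to JSON
#'
#' A lossless dump of every parameter matrix (full double precision),
#' the package's native model interchange format.
#'
#' @param hmm A `profile_hmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_hmm_json <- function(hmm, path) {
  jsonlite::write_json(
    list(format = "jointvar_profile_hmm", version = 1L,
         name = hmm$name, M = hmm$M,
         alphabet = paste(AMINO_ACIDS, collapse = ""),
         match_emissions = hmm$match_emissions,
         insert_emissions = hmm$insert_emissions,
         transitions = hmm$trans,
         background = unname(hmm$bg)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a profile HMM from its JSON dump
#'
#' @param path Path written by [write_profile_hmm_json()].
#' @return A `profile_hmm`.
#' @export
read_profile_hmm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$format) || x$format != "jointvar_profile_hmm")
    stop("not a jointvar profile HMM JSON dump: ", path, call. = FALSE)
  new_profile_hmm(as.matrix(x$match_emissions),
                  as.matrix(x$insert_emissions),
                  as.matrix(x$transitions),
                  as.numeric(x$background),
                  name = x$name)
}

#' Load a profile model from JSON, HMMER3 or an alignment
#'
#' Convenience dispatcher used by the command-line tool: `.json` loads
#' the native dump, `.hmm` a HMMER3 ASCII model, anything else is read
#' as an aligned FASTA (or Stockholm, by sniffing the header) and
#' fitted with [profile_hmm()].
#'
#' @param path Model or alignment path.
#' @param pseudocount Pseudocount used when fitting from an alignment.
#' @return A `profile_hmm`.
#' @export
load_model <- function(path, pseudocount = 1) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") return(read_profile_hmm_json(path))
  if (ext == "hmm") return(read_hmmer3_model(path))
  first <- readLines(path, n = 1L, warn = FALSE)
  msa <- if (grepl("^#\\s*STOCKHOLM", first)) read_msa_stockholm(path)
         else read_msa_fasta(path)
  profile_hmm(msa, pseudocount = pseudocount)
}
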
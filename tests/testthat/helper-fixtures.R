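# Shared fixtures, all built in code.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# M = 1 toy model with a single forced path Begin -> M1 -> End:
# M1 emits 'A' with probability 0.8, the null emits 'A' at 0.05,
# so scoring "A" must give log2(0.8 / 0.05) = 4 bits exactly.
forced_path_hmm <- function() {
  me <- matrix(c(0.8, rep(0.2 / 19, 19)), 1, 20, byrow = TRUE)
  ie <- matrix(1 / 20, 2, 20)
  tr <- matrix(0, 2, 9)
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DI", "DD")
  tr[1, c("MM", "IM")] <- 1        # Begin -> M1; I0 -> M1 (unused)
  tr[2, c("MM", "IM", "DM")] <- 1  # M1 -> End etc.
  bg <- c(0.05, rep(0.95 / 19, 19))
  new_profile_hmm(me, ie, tr, bg)
}

# Random small profile HMM fitted from a random gapped alignment.
random_small_hmm <- function(max_match = 4L) {
  ncols <- sample(2:(max_match + 1L), 1L)
  nseq <- sample(2:5, 1L)
  rows <- replicate(nseq, {
    r <- sample(AA20, ncols, replace = TRUE)
    r[runif(ncols) < 0.2] <- "-"
    paste(r, collapse = "")
  })
  rows[1] <- gsub("-", "A", rows[1])  # keep at least one match column
  hmm <- tryCatch(profile_hmm(protein_msa(rows),
                              pseudocount = runif(1, 0.2, 2)),
                  error = function(e) NULL)
  if (is.null(hmm) || hmm$M > max_match) Recall(max_match) else hmm
}

random_protein <- function(max_len = 5L) {
  paste(sample(AA20, sample(1:max_len, 1L), replace = TRUE),
        collapse = "")
}

# Perfectly conserved family fixture for joint-score tests: a conserved
# 40-residue family, its profile HMM, and the reverse-translated CDS.
conserved_family_fixture <- function() {
  cfg <- simulation_config(seed = 42L, root_protein_length = 40L,
                           family_size = 8L, substitution_rate = 0,
                           conserved_fraction = 1)
  msa <- simulate_homolog_family(cfg)
  list(msa = msa,
       hmm = profile_hmm(msa),
       root = attr(msa, "root"),
       cds = reverse_translate(attr(msa, "root")))
}

# Deletion / insertion variant rows against a CDS (anchored VCF style).
del_variant <- function(cds, pos, id = "del") {
  data.frame(id = id, pos = pos,
             ref = substr(cds, pos, pos + 1L),
             alt = substr(cds, pos, pos))
}
ins_variant <- function(cds, pos, base = "A", id = "ins") {
  data.frame(id = id, pos = pos,
             ref = substr(cds, pos, pos),
             alt = paste0(substr(cds, pos, pos), base))
}
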
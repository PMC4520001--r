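Package: jointvar
Title: Joint Effect Prediction for Multiple Genetic Variants with Profile
    Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores the combined effect of sets of SNPs and indels on a
    protein using a profile hidden Markov model trained on a multiple
    alignment of homologous proteins.  The joint score is the odds ratio of
    the wild-type versus mutant generation probabilities under the model
    (Viterbi bit scores), with a bit-score difference alternative for pure
    SNP sets.  Includes genotype-based formation of per-individual,
    per-transcript variant sets from VCF data using ancestral-allele
    annotation, enumeration of frame-restoring compensatory indel sets by a
    windowed bounded subset-sum search, classification of scored sets as
    compensatory or noncompensatory, and deterministic simulators for every
    input (homolog families, transcripts, genotyped variants, indel
    catalogs) so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
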
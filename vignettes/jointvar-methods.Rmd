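---
title: "Scoring the joint effect of multiple variants with profile HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the joint effect of multiple variants with profile HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointvar)
```

## The problem

Most variant-effect predictors score one variant at a time. When several
variants sit on the same gene copy — compound mutations in cis — their
joint effect on the protein can differ qualitatively from any single
effect: a second frameshift indel can restore the reading frame broken
by the first, and two individually tolerated missense changes can be
ruinous together. `jointvar` scores a *set* of variants in its entirety:
the mutant protein carrying all variants simultaneously is compared with
the wild type under a profile hidden Markov model of the protein family,
so conservation signal accumulated over evolution judges the combined
product, not its parts.

## The model

A profile HMM is a left-to-right HMM with one match (M), insert (I) and
delete (D) state per consensus column of a multiple alignment of
homologous proteins. `profile_hmm()` fits it from an alignment:

* **Match columns.** A column is a consensus (match) column iff its gap
  fraction is strictly below 0.5 — the standard profile convention; the
  choice only matters for ragged alignments.
* **Emissions.** Match emissions are Laplace-smoothed column
  frequencies, $(c_{ja} + w)/(n_j + 20w)$ with default $w = 1$. We use
  flat Laplace pseudocounts rather than Dirichlet mixtures deliberately:
  every number in the model can be checked by hand, which the test suite
  exploits. Insert states emit the background distribution, so inserted
  residues are scored against the same frequencies as the null model and
  inserts are penalised through transitions only (the HMMER convention).
* **Transitions.** Counted from the state path each aligned row traces
  through the model, smoothed with the same $w$. The full nine-transition
  topology is kept (including I–D and D–I), which makes the fitted model
  exactly the maximum-a-posteriori model of the alignment; models read
  from HMMER3 files simply have those two probabilities equal to zero.
* **Null model.** I.i.d. emission of the alignment's overall residue
  frequencies (smoothed so it is strictly positive). We do not add a
  geometric length term: the package's score contract is
  `bit = log2 P(seq, best path | HMM) − log2 P(seq | null)` with the
  null a pure composition term, which keeps the single-forced-path case
  exactly `log2(e/bg)` per residue and makes hand-derived expectations
  possible. A length term would shift wild and mutant scores by nearly
  equal amounts and cancel almost entirely in the comparisons below.

Scoring is by the Viterbi algorithm (best single path, global mode).
`brute_force_best_path()` enumerates every path on tiny instances and is
the independent oracle for the dynamic program; the suite checks
equality to 1e-9 bits on random models.

## From bit scores to the odds ratio

The joint score of a variant set $V$ on a transcript is the odds ratio

$$O \;=\; \frac{P_w/(1-P_w)}{P_m/(1-P_m)},$$

where $P_w$ and $P_m$ are the probabilities that the wild-type and
mutant proteins were generated by the family HMM. $O > 1$ flags the set
as deleterious, $O \approx 1$ neutral, $O < 1$ beneficial. A Viterbi
score is a log-odds bit score, not a probability, so a bridge is
needed. We use the logistic bridge
$P = 2^{b}/(1 + 2^{b})$ (`generation_probability()`), under which the
odds of generation are exactly $2^{b}$ and the odds ratio collapses to
$O = 2^{\,b_w - b_m}$. This identity is also how `score_mutant()`
computes $O$ internally: working in log2-odds space keeps the score
finite and exact even when $P$ saturates to 1 in double precision
(which happens beyond roughly 50 bits). The bridge lives in one
function so it can be swapped without touching anything else.

For pure-SNP sets the bit-score difference $\log_2(P_w/P_m)$ is used
instead (`snp_score()`; `score_type = "auto"` selects it when no member
is an indel), reflecting that the odds ratio is the indel score and the
plain bit difference the SNP score. Both are reported on the log2
scale, so joint score $S$ and single scores $s_i$ are directly
comparable and a set mixing score types is rejected rather than
averaged.

The qualitative call uses a symmetric neutral band on the log2 scale:
neutral iff $|\log_2 O| \le 0.5$ (half a bit), configurable via
`neutral_band`. "Approximately 1" is not otherwise quantified anywhere,
and half a bit is small against the tens-of-bits effects of frameshifts.

## Variant sets from genotypes

Sequencing-derived genotypes do not phase multiple heterozygous
variants, so joint scoring is restricted to variants whose haplotype is
determined. For each (individual, transcript) pair every variant is
assigned exactly one class: (1) coding, homozygous, different from the
ancestral allele; (2) coding, homozygous, ancestral; (3) coding,
heterozygous; (4) outside the coding region. Only Class 1 variants —
derived homozygotes in coding sequence — form the scored set: they are
guaranteed to co-occur on both gene copies. Class 2 variants are logged
and dropped (they carry no mutation relative to the ancestor), Class 3
are never combined (phase unknown), Class 4 are outside the product.
"Different" is evaluated against the *ancestral* allele, not REF: a
reference allele can itself be the derived state. Lowercase
(low-confidence) ancestral calls are uppercased and flagged,
optionally skipped; a coding homozygote with no ancestral call cannot
be placed in Class 1 or 2 and is skipped with a logged reason.

Set identity is the sorted list of (chrom, pos, ref, alt) tuples,
hashed (FNV-1a) to a stable `set_id`, so identical member lists share
one id across individuals and transcripts and the individual /
transcript / set association is many-to-many, as
`association_table()` exposes.

## Compensatory indel search

For a frameshift indel, nearby indels whose combined length change is a
multiple of three can restore the reading frame. The search admits an
indel iff its length change is below five bases in magnitude and not
divisible by three (each member must itself be frame-shifting and
short), and looks for supersets of the target with net change in
$\{-3, 0, +3\}$ — net $\pm 3$ preserves frame while deleting or adding
one codon — whose members all fall within 20 base pairs, with at most
10 members per set and at most 20 reported sets per valid sum.

Two readings of "within 20 base pairs" are implemented: the default
reads it as the span from leftmost to rightmost member; `window_mode =
"anchor"` bounds each member's distance from the target instead. The
original bound is ambiguous between the two; span is the stricter and
therefore the default.

The enumeration sorts the windowed candidates by position and expands
bracketing (leftmost, rightmost) pairs in order of increasing span,
then interior subsets in order of increasing size — a windowed, bounded
subset-sum search. Because sets are produced directly in the
deterministic ranking (span ascending, then size, then lexicographic
member ids), the per-sum cap can stop the search early instead of
enumerating the exponential full space; on dense catalogs (the
`adversarial20_preset()` packs 36 admissible indels into 18 bp) the
caps bind after a tiny fraction of the space is touched. A guard of
2 × 10⁶ subset expansions protects against pathological catalogs where
a quota cannot fill; if it triggers, a warning marks the ranking as
possibly incomplete. The cap order itself is a design choice: no rule
for choosing *which* 20 sets survive is given anywhere, so we rank by
(span, size, member ids) purely to make the output deterministic.
`brute_force_sets()` enumerates all subsets on small catalogs and is
the oracle for the pre-cap output.

## CM / nonCM classification

Given a joint score $S$ and single scores $s_1..s_n$ of the same type,
a set is a compensatory-mutation (CM) set iff
$S \le \min s - 1.5(\max s - \min s)$ and a noncompensatory (nonCM)
set iff $S \ge \max s + 1.5(\max s - \min s)$; anything between is
`neither`. Two decisions were open:

* **Scale.** The rule is applied to log2-scale scores. The formula is
  scale-sensitive (it subtracts multiples of a range), and on the raw
  odds-ratio scale a modestly deleterious pair like scores 2.2/3.1 with
  joint 5.3 would place the thresholds asymmetrically around an
  exponential quantity; on the log scale the rule is
  translation-equivariant, which the suite verifies as a property.
  Tables of single and set scores like the cardiomyopathy compound
  mutations are consistent with either reading at the printed precision,
  so the equivariant one is used.
* **Degenerate range.** When all $s_i$ are equal both inequalities fire
  at $S = s$; such sets are labelled `neither` and flagged
  `degenerate`, since the definitions presuppose score dispersion.

## Synthetic data

All inputs are generated in code, deterministically from a seed:

* `simulate_homolog_family()` mutates independent copies of a random
  root protein (star phylogeny, uniform substitutions) with a fixed
  conserved column set. A star rather than a tree suffices to create
  the conservation gradient the HMM estimates, and is trivially
  verifiable; it does *not* reproduce the phylogenetic correlation or
  empirical substitution preferences of real homolog sets, so absolute
  bit scores here say nothing about real families — the tests only rely
  on comparisons within one fixture.
* `worked_example_preset()` hard-codes the three-transcript, eight-variant
  worked configuration (ancestral `T`, genotype `A|A` for `v1`, and so
  on) rather than sampling it, so the expected sets
  $\{v_1,v_3\}, \{v_3,v_6,v_8\}, \{v_6,v_8\}$ are a fixed point of the
  whole classification pipeline.
* `simulate_genotyped_variants()` emits variants with known class
  labels for classifier round-trips; `simulate_indel_catalog()` places
  indels with length changes in $\pm\{1..5\}$ so admission filters are
  exercised from both sides; `adversarial20_preset()` makes every
  search cap binding at once.

Default study-condition choices: families of 12 sequences with 10 %
per-site divergence and 40 % conserved columns (a mid-range,
moderately informative family); the conserved fixture used in scoring
tests is 8 × 40 residues at zero divergence, small enough that a full
Viterbi pass is instantaneous yet long enough that a frameshift
destroys tens of conserved matches.

## Numerical notes and limitations

* Bit scores are exact log2 arithmetic on double precision; the
  generation probability saturates to 0/1 beyond roughly ±50 bits, so
  all internal comparisons work in log-odds space and
  `odds_ratio()` refuses boundary probabilities rather than returning
  0 or infinity.
* Viterbi is the scoring contract (best path), not Forward; on the
  conserved fixtures the two are nearly identical, and the brute-force
  oracle enumerates best paths, so the equivalence test is exact.
* Premature stop codons truncate the mutant protein before scoring; a
  frameshift near the start therefore scores as a near-total loss,
  which is the intended biology.
* Overlapping variants and variants spanning an exon boundary are
  rejected with diagnostics, not guessed.
* Translation uses the standard genetic code only.
* The test problem sizes (families ≤ 12 × 120, catalogs ≤ 36 indels,
  oracle instances M ≤ 5) are chosen so every oracle comparison is
  exhaustive; they are fixtures for correctness, not benchmarks of
  scale.
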
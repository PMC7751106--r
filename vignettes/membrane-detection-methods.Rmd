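---
title: "Detecting membrane proteins with evidential ensemble voting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting membrane proteins with evidential ensemble voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memvote)
```

## The problem

Transmembrane-topology predictors detect proteins that span the lipid
bilayer, but roughly a fifth to a quarter of membrane proteins are
surface-bound — peripheral, lipid-anchored or GPI-anchored — and carry no
transmembrane segment (TMS) at all. A tool that answers *"is this protein a
membrane protein of any type?"* therefore has to learn a compositional and
evolutionary signal from the sequence itself, and can then exploit a topology
predictor's very reliable *positive* calls without inheriting its blindness
to the surface-bound class. `memvote` implements that strategy: fixed-length
sequence and profile encodings, a bank of evidential nearest-neighbour
classifiers, vote-fusion ensembles, and a weighted-vote integration rule.

## Encodings

All encodings use one canonical amino-acid order (alphabetical by one-letter
code); every reader permutes external column orders into it, which prevents
silent feature misalignment between sources.

* **AAC / PAAC.** Normalized residue and dipeptide frequencies. Both are unit
  simplexes (components non-negative, summing to one).
* **PseAAC.** The composition augmented with λ sequence-order correlation
  factors; factor `θ_k` is the mean over positions of the squared differences
  of three standardized residue scales — Tanford hydrophobicity, Hopp–Woods
  hydrophilicity, and side-chain mass — averaged over the three scales. Each
  scale is standardized over the 20 amino acids with the *population*
  (divide-by-20) standard deviation, because the 20 residues are the full
  population, not a sample. The scale tables are shipped as constants and are
  replaceable via `aa_scales(raw = ...)`, since the primary literature cites
  sources but prints no numbers. The weight ω (default 0.05, conventional
  range 0.05–0.7) balances the composition block against the correlation
  block; at λ = 0 the encoding reduces exactly to the AAC.
* **SAAC.** Separate compositions of the 25 N-terminal residues, the
  interior, and the 25 C-terminal residues. The 50-residue minimum length
  makes an empty interior legal; its block is defined as the zero vector
  rather than an error.
* **Pse-PSSM.** A PSI-BLAST profile has L rows; the descriptor compresses it
  to 40 numbers: the 20 column means and the 20 mean squared λ-lag
  differences. Two reading choices were open. First, which score block of the
  ASCII export feeds the descriptor: the log-odds block (first 20 numeric
  columns) is used, the weighted-percentage block being a sampling-frequency
  estimate rather than an evolutionary score. Second, the standardization:
  the profile is standardized per row to mean zero, *and divided by the row
  standard deviation* — a pure shift would leave the lag block
  scale-dependent. A `center_only` switch restores the shift-only behaviour
  for sensitivity analyses. A zero-variance row standardizes to zeros.

Sequences are normalized to the 20-letter alphabet. The default policy is
strict (any other character is an error naming the record and the
character); an optional mapping policy resolves the common ambiguity codes
(B→D, Z→E, J→L, U→C, O→K) while `X` remains an error, because none of the
encodings is defined for an unknown residue.

## Classifiers

Distances are Euclidean on the encoding vectors, the convention of the
nearest-neighbour literature this design follows. Neighbour ties are broken
by training-set index, making every prediction deterministic and
permutation-invariant up to that declared rule.

The **fused KNN** runs plain KNN for every K in 1..10 and takes the majority
of the ten sub-votes; its score is the fraction of positive sub-votes. The
**evidence-theoretic KNN** treats each of the K nearest neighbours as a piece
of evidence: a mass function with `α0 · exp(−γ_c · d²)` on the neighbour's
class and the rest on the whole frame. Masses combine by Dempster's rule
(associative, so a sequential two-class update suffices) and the pignistic
probability — the class mass plus half the frame mass — decides. Defaults:
`α0 = 0.95`; `γ_c` is the inverse mean squared pairwise distance within class
c, the standard evidential-KNN initialization, with an all-pairs fallback for
degenerate classes. The original method's exact parameterization
(α0, γ, any optimization) is not published, so parity with it cannot be
asserted; this heuristic is the main fidelity risk and is therefore
exercised against an exact brute-force Dempster oracle in the tests.

All vote ties — an even sub-vote split, or a tied ensemble column count —
resolve to the K = 1 (nearest-evidence) decision, a deterministic and
data-driven rule rather than a class-biased one. As γ grows the kernel mass
vanishes, every mass function becomes vacuous and the pignistic probability
collapses to ½; the tie rule then returns the nearest neighbour's label,
which is the correct degenerate behaviour.

SVM (RBF kernel), gradient-boosted trees and random forests are thin
adapters over `e1071`, `xgboost` and `randomForest`, with an internal
stratified-CV grid search whose ties go to the smallest parameter values.

## Ensembles

A **bank** holds one classifier per λ in 0..49 over the Pse-PSSM features
(50 members), or one per (λ, K) pair (500). *All voting* takes the plain
majority across the bank, ties resolving to the first member in bank order.
*Selective voting* first ranks the members by mRMR: relevance and redundancy
are measured with the correlation-based mutual information approximation
`MI = −½ ln(1 − ρ²)` (the phi coefficient on binary vote columns, mirroring
the continuous treatment of the reference mRMR implementation), and members
are added greedily by the relevance-minus-mean-redundancy (MID) criterion.
Perfectly correlated columns would make the MI diverge; it is capped at
`−½ ln(1e−12)`, which preserves the ordering while keeping arithmetic
finite. Zero-variance columns get MI 0. Incremental selection then evaluates
every prefix of the ranking by the accuracy of its majority vote and keeps
the best prefix, the smallest on ties.

The selection accuracy is computed on the same leave-one-out vote matrix
used for ranking, not on a nested cross-validation. The votes themselves are
held-out predictions, but re-using them for subset selection is optimistic
— the chosen subset size is fitted to this dataset. This matches how the
selection curves are usually reported; a fully unbiased estimate would
require an outer validation layer, which is out of scope.

## Topology integration

An external topology predictor's calls enter as a table of per-protein TMS
counts; a protein is deemed membrane if at least one TMS is called. The
integration rule is weighted voting in which a positive topology call
carries weight |S| − 1 (S the selected subset): equivalently, the ensemble
decision flips to positive **iff** at least one constituent classifier
agrees with the positive topology call (the equivalence is unit-tested for
|S| = 2..21). A negative topology call carries weight zero — it never
demotes — because only the positive calls of a high-specificity consensus
predictor are trustworthy, and surface-bound membrane proteins legitimately
receive negative topology calls. Consequently sensitivity can only rise and
specificity can only fall under integration; both directions are asserted
as invariants. When several call tables are supplied they merge by logical
OR on the membrane flag.

## Evaluation

Leave-one-out cross-validation is the primary protocol; for neighbour-based
learners it is computed by masking the held-out row of a precomputed
distance matrix, which the tests verify to be identical to naive per-fold
refitting (including the per-fold recomputation of the γ heuristic).
Stratified k-fold is available as an alternative; folds are seeded, balanced
within one sample overall and per class, and `k = n` reduces to
leave-one-out. Metrics are sensitivity, specificity, accuracy and MCC, with
MCC defined as 0 whenever a factor under its square root vanishes (the
"no better than random" convention), plus AUC by the midrank Mann–Whitney
method with ties counted half. Percentages print rounded to two decimals.

## The synthetic generator

`gen_dataset()` emulates the structure of a membrane/nonmembrane benchmark,
not its biology: positives carry 1–5 hydrophobic stretches of 18–25 residues
(drawn from {A, I, L, M, F, V, W}) inserted into a Swiss-Prot-like background
composition, one per equal-width block so segments never collide; 20% of
positives are surface-bound — no stretch, only a mild compositional shift
towards the same residue set; negatives are background-only. Lengths default
to 100–250 residues, respecting the 50-residue fragment floor. Profiles are
BLOSUM62 rows of the true residues plus seeded integer noise, so they are
integer-valued and round-trip exactly through the ASCII PSSM writer/reader.
The simulated topology predictor detects TMS-bearing positives with
sensitivity 0.72 and never detects surface-bound ones, with specificity
0.997 — the operating point of the best published tools on this task.

What passing tests on this generator do show: the pipeline's machinery is
correct (encodings, evidence combination, ranking, selection, integration,
metrics), the class signal is learnable, and the qualitative ordering —
selective voting ≥ all voting, integration raises sensitivity at essentially
no specificity cost — reproduces. What they do not show: real-data accuracy.
Synthetic profiles have no homology structure, no alignment noise, and a far
cleaner hydrophobicity signal than real membrane datasets; absolute numbers
on synthetic data are therefore higher than any real benchmark and are never
compared against published figures.

## Numerical and scale choices

Default problem sizes keep every analysis interactive on one CPU: test
fixtures use 12–30 proteins per class with λ banks truncated to 0..4, and
the end-to-end demonstrations use 60 + 60 proteins with λ = 0..9 and the
full K = 1..10 grid (100 members); the complete λ = 0..49 range (500
members) is exercised where only cardinality matters and remains available
everywhere by argument. Tolerances: exact-arithmetic identities are asserted
to 1e−9 or tighter; stochastic nulls to three standard errors over 200
seeds. Degenerate inputs are handled by declared conventions rather than
errors where the input is legal (zero-variance profile rows, empty SAAC
interior, MCC zero-denominator), and by early errors naming the offending
record otherwise (λ ≥ L, non-standard residues, malformed PSSM rows with
their line number).

## Limitations

The toolkit ingests precomputed PSI-BLAST profiles and topology calls; it
runs no searches and no topology predictors. The OET-KNN parameterization is
a documented heuristic, not a reproduction of any specific binary. The mRMR
implementation covers the MID scheme only (not the quotient variant), and
probability outputs are vote fractions or pignistic probabilities, not
calibrated posteriors.
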
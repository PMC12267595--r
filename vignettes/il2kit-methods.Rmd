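---
title: "il2kit: models, descriptors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{il2kit: models, descriptors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(il2kit)
```

# The problem

Interleukin-2 is a central T- and NK-cell growth factor; MHC-presented
peptides that trigger its secretion are candidate leads for cancer
immunotherapy and vaccine design. `il2kit` classifies peptides into IL-2
inducers and non-inducers from sequence alone, and layers peptide
engineering workflows (single-residue mutant design, protein window
scanning, motif scanning) on top of the classifier. This vignette
documents the models, the tunable parameters, the synthetic data the test
suite is built on, and the design choices made where the method left the
design open.

# Data model and curation

Sequences live in a `PeptideSet` (an S4 wrapper around a Biostrings
`AAStringSet` with a label factor). Only the 20 canonical residues are
accepted; records with B, J, O, U, X or Z are rejected in strict mode and
dropped with a warning in lenient mode — degenerate codes carry no
position-specific information for composition descriptors, and silently
recoding them would bias the feature space.

`curatePeptides()` applies the two curation rules in order: remove
peptides with length outside [8, 25] (the range suitable for MHC antigen
processing; both bounds inclusive) and then remove redundant peptides.
"Redundant" is exact, case-insensitive sequence identity across both
classes, first occurrence kept. A sequence observed with *both* labels is
contradictory evidence and is dropped entirely, reported separately in
the curation report — keeping either copy would inject label noise at
identical feature vectors. Curation is idempotent.

`splitPeptides()` holds out `round(ratio · N)` records (base `round`,
i.e. nearest integer, ties to even). This rounding reproduces the
published cohort sizes: 6574 peptides at ratio 0.2 give 5259 train / 1315
test, and 6858 give 5486 / 1372. (One published cohort is printed as
5487 + 1372 = 6859 peptides out of 6858 — an arithmetic inconsistency in
the source; the package follows its own rounding rule and reports
5486/1372 for N = 6858.) Splits are stratified by label by default with a
fixed default seed of 42; per-class test counts are allocated by largest
remainder so the total is exact.

# Descriptors

Composition-type descriptors are percentages so that peptides of
different lengths are comparable.

* **AAC** (20): `100·count(a)/L`; sums to 100.
* **DPC** (400): `100·count(xy)/(L−1)` over adjacent ordered pairs; sums
  to 100. **DPC_LEN** appends the raw residue count unscaled — scaling it
  would be undone by the tree ensembles that consume it, and a raw count
  keeps the feature interpretable.
* **CTD** (147): the classical composition/transition/distribution
  scheme over 7 physicochemical properties (hydrophobicity, normalized
  van der Waals volume, polarity, polarizability, charge, secondary
  structure, solvent accessibility), each splitting the 20 residues into
  3 groups. Per property: 3 group compositions, 3 unordered between-group
  transition percentages over the `L−1` adjacent pairs, and per group the
  sequence positions (as % of `L`) of its first, 25%, 50%, 75% and 100%
  occurrence (0 when absent; the index of the q-th occurrence is
  `ceiling(q·n_group)`, so the five entries are non-decreasing).
* **PCP** (25): percentage composition over 25 binary residue classes
  (charged, polar, aliphatic, aromatic, tiny, buried, ...). Classes
  overlap, so no sum constraint.
* **DDR** (20): `100·(sum of index gaps between successive occurrences
  of a)/L`, 0 when the residue occurs at most once.
* **RRI** (20): sum over maximal runs of a residue of the squared run
  length, divided by `L` (`"AAAC"` gives `RRI_A = 9/4`).
* **AAB** (320): one-hot residue identity at the N-terminal 8 and
  C-terminal 8 positions. For peptides shorter than 16 the windows
  overlap — each window is defined independently, mirroring the
  two-sample-logo convention — and there is no padding symbol column.

The upstream feature service the method used does not publish closed-form
definitions for PCP, DDR and RRI; the formulas above are this package's
explicit, versioned stand-ins, and the CTD/PCP group tables ship as
editable CSV resources (`inst/extdata/`) so they can be swapped for exact
parity with other implementations without code changes.

# Motif mining

`mineMotifs()` performs breadth-first enumeration of contiguous motifs:
level 1 is every symbol of the alphabet, and each level extends
candidates one symbol to the right. Because support is counted at the
sequence level (a motif "occurs in" a sequence if it matches at ≥ 1
offset), support is anti-monotone under extension, so a candidate whose
positive support drops below `minPos` is pruned with all its extensions.
Emitted motifs satisfy `pos_count ≥ minPos` and `neg_count ≤ fp`. Child
candidates are counted only within the parent's matching sequences, which
keeps mining on 400 + 400 peptides in the low seconds.

Alphabets: `NONE` uses the 20 residues (motifs are plain substrings);
`BETTS-RUSSELL` adds polar/hydrophobic/small group symbols and `KOOLMAN`
adds aliphatic/aromatic/sulfur/hydroxyl/basic/acidic-amide/imino, with
residue and group symbols freely mixable inside one motif. The group
tables ship as CSV resources; the source describes the schemes only by
name, so the tables are editable data, not code.

Defaults: `fp = 10` (the setting selected for the main dataset),
`maxLen = 7` (the longest published motif), and `minPos` = 2% of the
positive set — the source never states its positive-support threshold, so
a small fraction of the positive class is used rather than an absolute
count, keeping the default meaningful across dataset sizes. Only
contiguous motifs are supported: every published motif is contiguous, and
gaps would break the anti-monotone pruning argument above. Ranking is by
positive coverage (descending), then shorter length, then lexicographic —
coverage is what the published motif table reports; length and
lexicographic order are pure tie-breaks for reproducibility.

# Classifiers and evaluation

`trainModel()` runs an exhaustive grid search; each grid point is scored
by mean rank-based ROC AUC over 5 stratified folds of the training rows,
and the best point (first in grid order on ties) is refit on all training
rows. Held-out test rows are never touched by fold assignment or model
selection. Two determinism guarantees matter for reproducibility:

* all stochastic fitters receive seeds derived from the training seed;
* rows are canonicalized by (label, record id) before fold assignment,
  so the result is invariant to input row order.

The default grids are deliberately small and documented in
`defaultGrid()` (tree counts 200–500, `mtry ∈ {√p, p/4}`, and similar
2–4-point ranges elsewhere); the source states no grids, and small grids
keep the 21-fit protocol (4 points × 5 folds + refit) tractable. `SVR` is
a radial-kernel support-vector *regressor* used as a classifier, matching
the method's use of it: its predictions are clamped to [0, 1] to read as
probabilities (clamping does not change the AUC ranking of interior
scores). KNN is included with a default `k ∈ {3, 5, 9}` grid although the
source lists it inconsistently between its methods and results.

Metrics follow the standard definitions; accuracy is reported on the
0–100 scale and sensitivity/specificity/MCC/AUC on 0–1, mirroring the
published tables. MCC returns 0 whenever a denominator factor is 0. AUC
is the rank-based (Mann-Whitney) statistic with ties counted ½. A score
exactly at the decision threshold counts as a positive call — the source
is silent on ties, and the ≥ rule is stated explicitly so that confusion
counts are well defined.

Feature selection offers mRMR (greedy relevance-minus-mean-redundancy on
mutual information over 3-bin equal-frequency discretization; columns
with ≤ 3 distinct values keep their values as levels so binary indicators
are not collapsed), an L1-penalized logistic model (penalty relaxed along
the path until ≥ k nonzero coefficients, then top |coef|), recursive
feature elimination with an extra-trees ensemble (dropping 10% per
round), and impurity-based importance. The importance ranking is a
documented stand-in for SHAP: exact SHAP values are library- and
version-dependent, and only the downstream model quality of the selected
features is consumed.

# The hybrid score

The ensemble rule adds 0.5 to the model probability when any
inducer-motif matches and subtracts 0.5 for any non-inducer motif, with
any-hit semantics (multiple matches do not stack). The source adds and
subtracts from a probability without stating range handling; `il2kit`
clamps to [0, 1] so the output still reads as a probability (a
`clamp = FALSE` switch preserves the raw adjusted value). Clamping has a
visible consequence worth knowing: when the base model already assigns
near-1 probabilities to motif-bearing peptides, the +0.5 adjustment
saturates many of them at exactly 1.0 and the within-group ranking
collapses to ties, so the hybrid AUC can tie or dip marginally below the
base AUC on easy data. The adjustment earns its keep when the base model
is imperfect on motif-bearing peptides — the regime the published
ensemble improvement (AUC 0.82 → 0.84) reflects.

Class calls use a 0.5 threshold on the final score by default, exposed as
a parameter everywhere.

# Dataset characterization

`compositionComparison()` compares per-sequence residue composition
between classes — sequences, not pooled residues, are the sampling units,
since residues within a peptide are not independent. The default test is
Mann-Whitney U with Benjamini-Hochberg correction over the 20 residues;
Welch's t is selectable because the source attaches BH-adjusted p-values
to its composition figure without naming the test while using
Mann-Whitney elsewhere. `positionalEnrichment()` applies a position-wise
two-sample t-test to 0/1 residue indicators over the N-/C-terminal 8
positions; positions beyond a short peptide's span are skipped for that
sequence. Degenerate inputs are handled by rule rather than error: when
both groups are constant, p = 1 if the means agree and p = 0 otherwise
(complete separation of indicator variables), since `t.test()` is
undefined at zero variance.

# The synthetic generator

`syntheticConfig()` defaults define the conditions the test suite runs
under, chosen to emulate the structure of the experimental data:

* **Lengths 8–25 with mode 15 in both classes.** The class profiles
  differ, as in the real data: inducers use a left-skewed unimodal table
  (slightly shorter on average, lengths 12–20 dominant) and non-inducers
  a tri-modal table with secondary peaks at 17 and 20. This matters:
  peptide length carries genuine class signal, which is exactly why the
  DPC+length feature set outperforms DPC alone.
* **Composition bias.** Positives up-weight A, F, L, P, Y two-fold over
  a uniform background; negatives up-weight C, D, T — the residues the
  published composition analysis flags as class-enriched. Two-fold is a
  moderate, detectable enrichment; the source reports significance, not
  effect sizes.
* **Planted motif.** `ALEGSLQ` (the top published motif family) is
  written into 60% of positives at a uniform valid offset, overwriting
  residues so the drawn length distribution is preserved. A specific
  7-mer arises by chance in a 15-mer background at a rate ≪ 1 per 400
  sequences, so exclusivity holds without explicit screening.
* Duplicates are regenerated by rejection, so curation is a no-op on
  generated data and `curate(generate(c))` closure holds by
  construction.

What the generator does *not* emulate: MHC-allele structure and binding
biology, homology clusters (every peptide is drawn independently —
real epitope data contain near-duplicate families that inflate
naive cross-validation), position-specific composition beyond the
planted motif, and the real marginal dependence between residues.
Passing tests on synthetic data therefore demonstrate that the machinery
is correct and that the pipeline recovers planted signal at realistic
sizes — not that the real-data AUCs are reproduced. Those require the
deposited experimental dataset and are documented in the README as
optional replication.

# Problem sizes and numerical choices

The test suite and acceptance script run at the generator's default
scale, 400 peptides per class with an 80:20 split, the scale at which the
planted-signal checks (motif recovery ≥ 55% of positives with zero
negative coverage, extra-trees held-out AUC ≥ 0.9, label-shuffled control
at chance) are comfortably powered. Miner correctness is checked against
a brute-force oracle on ~50 random instances of ≤ 15 peptides (length
≤ 12) across all three alphabets, and metric formulas against O(n²)
pairwise computation on random vectors up to length 200. Tolerances:
metric identities at 1e-12 (pure arithmetic), descriptor sum constraints
at 1e-9, stochastic checks at the thresholds above.

# Known limitations

* PCP/DDR/RRI formulas are explicit stand-ins (see Descriptors); exact
  parity with other descriptor services is not claimed.
* Gapped motifs, PWMs and motif significance testing are out of scope.
* The similarity-annotation step requires NCBI blast+ on the PATH and
  inherits its e-value statistics, which are approximate for very short
  peptides.
* Deep and transformer models used for comparison in the source (1D CNN,
  TabNet, protBERT) are out of scope; the classical models above are the
  supported surface.
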
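---
title: "Methods: sequence descriptors, MRMD selection, and the three-stage ion-channel cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence descriptors, MRMD selection, and the three-stage ion-channel cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpred)
```

## The problem and the decision procedure

Ion channels are membrane proteins that form pores for the passive
transport of inorganic ions; they divide into voltage-gated channels
(opened by changes in membrane potential, with K, Ca, Na, and anion
subtypes) and ligand-gated channels (opened by ligand binding). `icpred`
predicts, from amino-acid sequence alone, whether a protein is an ion
channel and which kind, using a three-step decision procedure:

1. **Stage 1** — ion channel vs. non-ion protein. A non-ion verdict
   terminates the cascade.
2. **Stage 2** — voltage- vs. ligand-gated. A ligand-gated verdict
   terminates.
3. **Stage 3** — voltage-gated subtype: K, Ca, Na, or anion.

Each stage is an independent classifier (RBF-kernel SVM or random
forest) over a fixed-length numeric descriptor of the sequence, trained
on progressively narrower subsets of the data (all sequences; the ion
channels; the voltage-gated channels). The final output space is exactly
six labels, and each prediction carries its per-stage decision trail.

## Sequence validation

Only the 20 standard residues are admitted. Sequences containing
ambiguity codes — X, B, Z, and also J, O, U — are rejected rather than
imputed, and empty sequences are rejected. We additionally require a
minimum length, default 10 and configurable: the distribution
descriptors below report the positions of the 25%/50%/75% occurrence
quantiles of a residue group, which are degenerate on very short
sequences. Lower-case input is upper-cased rather than rejected, since
lower-case FASTA is a common dialect.

## The 188-D physicochemical descriptor

The descriptor concatenates:

* **Amino-acid composition** (20 values): the percentage of each residue,
  $E_i = A_i / L \times 100$, in fixed alphabetical order.
* For each of eight physicochemical properties — hydrophobicity,
  normalized van der Waals volume, polarity, polarizability, charge,
  surface tension, secondary-structure propensity, solvent
  accessibility — a 21-value CTD block over a fixed three-group
  partition of the alphabet:
  * **Composition** (3): percentage of residues in each group.
  * **Transition** (3): for each unordered group pair, the number of
    adjacent positions whose residues fall in the two different groups,
    divided by $L - 1$, times 100. A length-1 sequence has no adjacent
    pairs; its transitions are defined as 0.
  * **Distribution** (15): for each group with $m$ occurrences, the
    1-based positions of the 1st, $\lceil 0.25m \rceil$-th,
    $\lceil 0.50m \rceil$-th, $\lceil 0.75m \rceil$-th, and $m$-th
    occurrences, scaled by $L$ and expressed as percentages. An absent
    group contributes five zeros.

Total: $20 + 8 \times 21 = 188$ features. Two conventions here were
genuinely open and are declared, not derived: the **ceiling rule** for
the quantile occurrence index (a rounding rule would differ only on
small $m$, but some rule must be fixed), and the **all-zero quintuple**
for an absent group, which keeps vectors comparable across sequences.
The three-group partitions are the classical assignments of the CTD
descriptor literature; because they are data, not logic, they ship as an
editable table (`inst/extdata/ctd_property_groups.tsv`, accessible via
`ctd_property_groups()`), and the package verifies at load time that
each row is an exact partition of the alphabet. The property order of
that table is the canonical feature order.

## The 400-D k-skip-n-gram descriptor

For gap size $a$, the sequence yields the ordered residue pairs
$(s_i, s_{i+a+1})$ for all positions where both indices exist; the
number of intervening residues equals $a$. The descriptor pools these
pairs over $a = 1, \dots, k$ and reports each of the $20^2 = 400$
ordered pairs as a fraction of the pooled pair count. Pairs are
directional and never symmetrized — 400 dimensions only makes sense for
ordered pairs. A sequence too short to produce any pair yields the
all-zero vector.

Three choices were open:

* **The index bound.** The naive bound $i \le L - a$ puts the second
  position out of range at its endpoint; we use $i \le L - a - 1$, the
  only reading under which every pair is well defined.
* **Whether gap 0 (contiguous dipeptides) enters the union.** The
  defining union runs over gaps $1..k$, so the default excludes gap 0,
  but published skip-gram implementations disagree; the
  `include_zero_gap` flag provides the other behavior.
* **The value of k.** No canonical value exists. The default is
  $k = 2$; `k` is a required, logged configuration value so runs are
  reproducible. Only $n = 2$ is supported — $n \ge 3$ (8000+ features)
  is rejected with a clear error.

The fused encoder concatenates the 188-D block then the 400-D block
(588 columns).

## MRMD feature ranking and selection

Each feature $f$ receives:

* **Relevance** $MR_f$: the absolute Pearson correlation between the
  feature column and the class labels encoded as integers $0..C-1$ in
  first-seen order. A constant column, whose correlation is undefined,
  gets 0.
* **Distance (non-redundancy)** $MD_f$: columns are first min-max
  scaled to $[0,1]$ so the three distance functions operate on
  commensurate scales; then $MD_f$ is the mean over the other features
  of (a) Euclidean distance divided by $\sqrt{n}$, (b) $1 -$ cosine
  similarity, and (c) $1 -$ Tanimoto coefficient, averaged over the
  three functions. How the three distances are combined was not
  derivable from the method's description; the arithmetic mean is
  declared. Zero-norm columns need a convention: two zero columns are
  treated as identical (similarity 1), a zero against a non-zero column
  as maximally dissimilar (similarity 0).

The combined score is $w_r MR_f + w_d MD_f$ with default unit weights;
features are ranked by descending score with ties broken by original
column order (stable). Selection takes either an explicit subset size
$m$, or `m = "auto"`: nested prefixes of the ranking on a grid of every
5% of the feature count are scored by seeded stratified cross-validated
overall accuracy, and the smallest size within one standard error of
the best is kept (the standard error is taken across fold-wise
accuracies).

Two caveats are inherited from the method rather than introduced here:
Pearson correlation against an arbitrary integer encoding is a weak
relevance measure for unordered multi-class labels, and the distance
term is label-blind. Both are noted rather than "fixed", because the
package implements the method as defined.

## Classification, cross-validation, and metrics

**Backends.** The RBF-kernel SVM (libsvm via `e1071`) and the random
forest (`randomForest`, default 100 trees, seeded). SVM grid search is
exhaustive over powers-of-two grids ($c = 2^{-5}..2^{15}$,
$g = 2^{-15}..2^3$, steps of $2^2$ — the libsvm convention), scored by
seeded stratified CV overall accuracy, ties broken by smaller $c$ then
smaller $g$.

**Preprocessing discipline.** Each stage model fits per-feature min-max
ranges — and any MRMD selection — on its training data only, and stores
them for exact reapplication; inside cross-validation this happens per
fold, never on held-out data. The suite contains a regression test
pitting this against a deliberately leaky variant (scaling fitted on the
full matrix) on data with a held-out-fold outlier, where the two must
disagree.

**Folds.** Stratified, seeded, and keyed on instance ids sorted before
shuffling, so the id-to-fold map is invariant to row order. If the
smallest class has fewer members than the requested folds, the fold
count is reduced with a warning (relevant to the subtype stage, where
the benchmark's Na class has only 12 members).

**Metrics**, computed from the confusion matrix pooled over all folds:
per-class sensitivity $Sn(i) = TP_i/(TP_i+FN_i) \times 100$; overall
accuracy $OA = \sum_i TP_i / N \times 100$; average accuracy
$AA = \frac{1}{n}\sum_i Sn(i)$. A class with no evaluated instances has
undefined sensitivity and is excluded from AA with a warning. OA is
algebraically the row-total-weighted mean of the sensitivities, and the
suite checks that identity on random matrices.

## The synthetic benchmark generator

No curated channel dataset is redistributable here, so the package
generates its own study conditions. `benchmark_profiles()` defines six
classes with the counts of the curated benchmark it emulates — 81 K,
29 Ca, 12 Na, 26 anion, 150 ligand-gated, 300 non-ion (598 sequences) —
with lengths uniform on 50–500 (wide enough to exercise the
distribution quantiles). Each class's residue-frequency vector boosts a
class-specific set of five residues above the uniform background
(pairwise overlaps between sets at most 2). At `"high"` separation the
boost is +0.08 per residue, giving pairwise total-variation distance of
at least 0.3 between any two class profiles; at `"low"` it is +0.012.
These constants live in one place (`benchmark_profiles()`), were fixed
once as what plausibly separable vs. hard compositional classes look
like, and are not tuned.

Sequences are drawn i.i.d. from the class frequency vector. That is
deliberate and honest: i.i.d. sampling exercises every compositional
encoder, the selection machinery, and the cascade, but carries no
positional motifs, no transmembrane topology, and no homology
structure. Passing the parameter-recovery suite therefore demonstrates
that the pipeline recovers compositional class structure when it
exists — not that it achieves any particular accuracy on real channel
data.

## Problem sizes and seeds used by the suite

The test suite runs the full 598-sequence benchmark for the stage-1
parameter-recovery check (188-D + random forest, 10-fold CV, dataset
and CV seed 42) and for the separation-monotonicity check (5 seeds,
subtype stage); the normalization properties are checked over 1000
random sequences of lengths 10–80; oracle equivalence uses random
sequences of length at most 50 and matrices of at most 8 features by 20
instances. These sizes were chosen to exercise the full study
conditions while keeping the suite quick to run. `scripts/acceptance.R`
re-runs the benchmark end to end at any seed and writes the descriptor
dimensionalities and per-stage CV accuracies it computes.

## Known limitations

* Compositional descriptors ignore residue order beyond adjacent and
  k-skip pairs; two sequences with identical composition are nearly
  indistinguishable.
* The MRMD relevance term's integer label encoding makes the 4-class
  subtype ranking order-dependent in principle (first-seen order is
  fixed and logged, so results are reproducible, but the measure itself
  is coarse).
* Redundancy clustering of homologous training sequences (CD-HIT-style)
  is out of scope; on real data the user should de-duplicate before
  training to avoid optimistic cross-validation.
* No probability calibration; stage decisions are hard labels, and
  stage errors compound down the cascade.
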
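# icpred

Sequence-based prediction of ion channels and their types.

Ion channels — membrane proteins that gate the passive transport of
inorganic ions — are major drug targets, and annotating a protein
sequence as a channel, and as which kind of channel, is a recurring
task in channel biology and drug discovery. `icpred` implements a
hierarchical, three-step decision procedure over fixed-length sequence
descriptors:

1. ion channel vs. non-ion protein (non-ion terminates);
2. voltage-gated vs. ligand-gated channel (ligand-gated terminates);
3. voltage-gated subtype: **K**, **Ca**, **Na**, or **anion**.

It is aimed at bioinformaticians who want an inspectable, reproducible
pipeline: every stage reads and writes plain text (FASTA in, TSV
feature matrices, rankings, and reports out), and every random step is
seeded.

## Methods at a glance

* **188-D physicochemical descriptor.** Amino-acid composition
  E<sub>i</sub> = A<sub>i</sub>/L × 100 (20 values) plus, for each of 8
  physicochemical properties (hydrophobicity, van der Waals volume,
  polarity, polarizability, charge, surface tension, secondary
  structure, solvent accessibility), a composition/transition/
  distribution (CTD) block of 21 values over a fixed three-group
  residue partition: 20 + 8 × 21 = 188.
* **400-D k-skip-n-gram descriptor (n = 2).** Ordered residue pairs
  pooled over gap sizes a = 1..k and normalized by the pooled pair
  count, N(p)/N(T); 20² = 400 dimensions. Default k = 2; contiguous
  dipeptides (gap 0) optionally included.
* **Fused 588-D features**: the 188-D block concatenated with the 400-D
  block.
* **MRMD feature selection.** Per-feature score
  w<sub>r</sub>·MR + w<sub>d</sub>·MD, where MR is the absolute Pearson
  correlation with the class and MD the mean
  Euclidean/cosine/Tanimoto distance to the other features on min-max
  scaled columns.
* **Classifiers.** RBF-kernel SVM (libsvm via `e1071`, with exhaustive
  c/g grid search) and random forest, evaluated by stratified 10-fold
  cross-validation with per-class sensitivity
  Sn(i) = TP<sub>i</sub>/(TP<sub>i</sub>+FN<sub>i</sub>), overall
  accuracy OA = Σ TP<sub>i</sub>/N, and average accuracy
  AA = mean Sn(i), all from the pooled confusion matrix.

A seeded synthetic benchmark generator (`benchmark_profiles()`,
`generate_dataset()`) emulates the structure of the curated channel
benchmark — 81 K, 29 Ca, 12 Na, 26 anion, 150 ligand-gated, 300
non-ion sequences — with class-distinct residue-frequency profiles, so
the whole pipeline is testable without any download. See the methods
vignette (`vignettes/ion-channel-cascade.Rmd`) for the full model
description and design rationale.

## Worked example

```r
library(icpred)

## a seeded 598-sequence six-class benchmark
d <- generate_dataset(benchmark_profiles("high"), seed = 42)
table(d$label)
#>        anion           Ca            K ligand-gated           Na      non-ion
#>           26           29           81          150           12          300

## train the three-stage cascade (188-D descriptor + random forest per stage)
cascade <- train_cascade(d)

## classify new sequences; each prediction carries its decision trail
kp <- benchmark_profiles("high")[[1]]   # the K-channel profile
novel <- generate_dataset(list(class_profile("K", kp$freqs, c(50, 500), 3)),
                          seed = 7)
predict_cascade(cascade, novel)
#>       id stage1        stage2 stage3 final
#> 1 K_0001    ion voltage-gated      K     K
#> 2 K_0002    ion voltage-gated      K     K
#> 3 K_0003    ion voltage-gated      K     K
```

The trail reads: stage 1 called the sequence an ion channel, stage 2
called it voltage-gated, stage 3 assigned the K subtype. A non-ion
verdict at stage 1 leaves `stage2`/`stage3` as `NA` and the final label
`non-ion`.

Individual descriptors are plain named vectors:

```r
v <- extract_188(novel$residues[1])
round(v[c("AAC.A", "hydrophobicity.C1", "polarity.D1.q50")], 2)
#>           AAC.A hydrophobicity.C1   polarity.D1.q50
#>           10.95             34.29             50.43
```

(10.95% alanine; 34.29% of residues in hydrophobicity group 1; the
median occurrence of polarity group 1 sits at 50.43% of the sequence.)

A command-line dispatcher over the same functions ships at
`inst/cli/icpred`, with subcommands `simulate`, `extract`, `select`,
`evaluate`, `train-cascade`, and `predict`:

```sh
Rscript inst/cli/icpred simulate --fasta bench.fasta --labels bench.labels.tsv --seed 42
Rscript inst/cli/icpred extract  --fasta bench.fasta --out bench.188.tsv --encoder ctd188
Rscript inst/cli/icpred evaluate --matrix bench.188.tsv --labels bench.labels.tsv \
    --out report.tsv --backend random-forest --folds 10 --seed 42
```

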
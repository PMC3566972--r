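# AmyloHex

Classification of hexapeptides as amyloidogenic or not, for structural
bioinformaticians who need energy-criterion labels faster than threading can
deliver them.

Amyloid fibrils are driven by short *hot spot* segments — adequately
represented by six-residue peptides — that form steric zippers: two tightly
mated β-sheets. The structure-based classifier threads a hexapeptide onto
rigid zipper backbone templates, asks an external design program for
per-chain energies, and labels the peptide amyloidogenic when its minimal
chain energy E<sub>min</sub> satisfies

```
E_min ≤ −23 kcal/mol        (boundary inclusive)
```

with the minimum taken over a simplified grid of 54 rigid-body poses: shifts
of 0–8 Å along the chains × 6–11 Å separations across the sheets (1 Å steps).
The sequence-based classifiers replace that whole pipeline once a labeled
corpus exists. The package provides:

* **hexapeptide handling** — cysteine→serine sanitization, 80-residue
  chunking, 6-residue sliding windows, energy-threshold labeling,
  position-specific frequency matrices, dataset-agreement statistics;
* **an Alternating Decision Tree** learner over the 120 predicates
  `AA_j = residue`, trained by weight boosting with exhaustive minimization
  of `Z = 2(√(W₊W₋)|c + √(W₊W₋)|¬c) + W(outside)` at every iteration, scored
  by summing all prediction nodes on satisfied paths, with rules exported in
  the notation `n: AAj | X a | !X b`;
* **baselines** — categorical naive Bayes (Laplace α = 1) and a 120-60-1
  logistic perceptron (SGD with momentum on squared error, lr 0.1, momentum
  0.2, 500 epochs, seeded);
* **the evaluation protocol** — TPR/TNR/Acc, tie-aware trapezoid ROC/AUC
  (= Mann–Whitney with half-ties), 10 × 66/34 resampling, the corrected
  resampled paired t-test `t = mean(d)/√((1/k + n_test/n_train)·var(d))`,
  and win/draw/loss tabulation at α = 0.05;
* **zipper geometry** — template enumeration from an idealized (or
  user-supplied PDB) scaffold, peptide threading onto all ten chains, PDB
  export, and a pluggable per-chain energy adapter;
* **seeded synthetic generators** for peptide datasets (PFM-based, with a
  plantable motif signal and an exactly enumerated Bayes-optimal AUC) and
  paired energy tables.

## Worked example

```r
library(AmyloHex)

## generate an energy-labeled training corpus and a separate test set
cfgTrain <- sequenceGeneratorConfig(n = 4481, seed = 1)
cfgTest  <- sequenceGeneratorConfig(n = 1586, seed = 2)
train <- samplePeptides(cfgTrain)
test  <- samplePeptides(cfgTest)
train
#> HexDataset with 4481 hexapeptide(s): 890 amyloidogenic, 3591 non-amyloidogenic
#>   TNMQET(-) GIRGPT(-) SQRNSF(-) ANGQNM(-) ...

## train the alternating decision tree and inspect its top rules
adt <- trainADTree(train, iterations = 50)
head(formatRules(adt), 3)
#> [1] "1: AA4 | I 1.367 | !I -1.125" "2: AA4 | Q -1.598 | !Q 0.019"
#> [3] "3: AA5 | A -0.929 | !A 0.033"

## evaluate on the held-out set
round(evaluateScores(isAmyloid(test),
                     predict(adt, test, type = "prob"),
                     predicted = predict(adt, test, type = "class")), 3)
#>   TPR   TNR   Acc   AUC
#> 0.874 0.935 0.924 0.906

## the exact optimum for these generating conditions
round(bayesOptimalAuc(cfgTrain), 3)
#> [1] 0.92

## threshold a synthetic paired energy table at -23 kcal/mol
tab <- sampleEnergyTable(energyGeneratorConfig(n = 4481, seed = 1))
labeled <- labelByEnergy(tab, threshold = -23)
sum(isAmyloid(labeled))
#> [1] 807
round(energyAgreement(tab)$meanAbsDiff, 2)
#> [1] 0.98

## 54 steric-zipper templates from the idealized scaffold
length(enumerateTemplates(buildIdealScaffold()))
#> [1] 54
```

The first rule says isoleucine at position 4 adds +1.367 to the amyloid
score when present and −1.125 when absent — the planted generator signal
recovered as the most significant rule. The test AUC of 0.906 sits within
sampling error of the enumerated Bayes optimum 0.920 for these conditions,
and thresholding the synthetic energy table recovers the configured ≈18.4%
positive rate (807/4481) and ≈1 kcal/mol mean absolute difference between
the paired energy columns.

Real data drop into the same functions: `readProteinFasta()` +
`hexapeptidesFromSequences()` for FASTA, `readHexTable()` for tab-separated
sequence/energy/label tables, `readScaffoldPDB()` for a scaffold structure,
and any `(peptide, template) → 10 energies` function as the energy adapter.

A thin shell wrapper exposes the same pipeline as subcommands
(`extract`, `label`, `train`, `predict`, `eval`, `compare`, `simulate`,
`templates`):

```sh
Rscript inst/scripts/amylohex simulate --n 4481 --seed 1 --out train.tsv
Rscript inst/scripts/amylohex train --table train.tsv --method adtree --iterations 50 --out adt.model
```

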
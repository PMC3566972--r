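---
title: "AmyloHex: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AmyloHex: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AmyloHex)
```

## The problem

Short sequence segments — hot spots, adequately represented by hexapeptides —
can drive amyloid fibril formation when exposed. The structure-based route to
classifying a hexapeptide is to thread it onto rigid steric-zipper backbone
templates (two tightly mated β-sheets), compute an energy for each pose with a
side-chain design program, and call the peptide amyloidogenic when its minimal
chain energy falls at or below a threshold. That is accurate but expensive;
the sequence-based route is to train statistical classifiers on hexapeptides
already labeled by the energy criterion, after which classification costs
microseconds per peptide.

AmyloHex implements both halves of that program: a simplified 54-template
zipper enumeration with a pluggable energy adapter, the energy-threshold
labeling and dataset statistics around it, and three sequence classifiers —
an alternating decision tree (ADTree) written from scratch, categorical naive
Bayes, and a one-hidden-layer perceptron — plus the evaluation protocol
(confusion metrics, ROC/AUC, repeated 66/34 resampling with a corrected
resampled t-test, win/draw/loss tabulation) and seeded synthetic generators
that make every stage testable without any external data.

## Sequence handling

Protein sequences are uppercased and every cysteine is rewritten to serine
(`sanitizeSequence()`), so that threaded structures cannot form disulfide
bridges; the sanitized alphabet therefore has 19 letters in data, while the
model space keeps all 20 (conditions on C simply never fire). Sequences are
optionally cut into chunks of at most 80 residues and then into 6-residue
windows shifted by one position; a clean sequence of length L yields
max(0, L − 5) windows.

Two decisions here were genuinely open:

* **Chunk boundaries.** Chunking is non-overlapping and windows spanning a
  chunk boundary are not recovered. Chunking exists only to bound segment
  length ahead of redundancy reduction (out of scope here), so the lost
  boundary windows are immaterial; `hexapeptidesFromSequences(chunk = FALSE)`
  skips chunking entirely.
* **Non-standard symbols** (X, B, Z, U, O, J, `*`, `-`) have no
  representation in the 20-letter model space. Windows containing them are
  dropped and counted, never imputed.

Energy-threshold labeling uses −23 kcal/mol by default with an **inclusive**
boundary: a segment whose minimal chain energy is *not greater than* the
threshold is amyloidogenic, so −23.0 itself is positive.

## Zipper templates

The scaffold is two sheets of five extended 6-residue strands (backbone
N, Cα, C, O), 4.8 Å strand spacing, sheet 2 a rigid copy of sheet 1 at the
native separation (default 8.5 Å, a typical dry-zipper distance). The package
ships `buildIdealScaffold()`, an idealized synthetic geometry — flat sheets,
3.5 Å Cα spacing, alternating in-plane zig-zag — clearly labeled non-
experimental; any user PDB with ten chains can be read instead
(`readScaffoldPDB()`).

Templates are rigid-body poses of sheet 2: translations of 0–8 Å in 1 Å steps
along the chain axis crossed with 6–11 Å separations across the sheets,
9 × 6 = 54 poses, enumerated shift-major. The third displacement direction
used by full-profile enumerations is deliberately absent. Because no frame is
given with a user scaffold, the axes are recomputed from coordinates: chain
axis = mean Cα(i)→Cα(i+1) direction of sheet 1, inter-strand axis = mean
direction between strand centroids, sheet normal = their unit cross product
oriented toward sheet 2.

Energy computation is an adapter contract: `(peptide, template) → 10
per-chain energies`. The shipped `surrogateEnergyAdapter()` is a smooth
deterministic toy (hydropathy sum plus geometric penalties) for exercising
the machinery; it is explicitly non-physical and is not a re-implementation
of any design program. `minEnergyLabel()` takes the global minimum over
templates and chains and applies the threshold; adapter failures skip the
template with a log and are counted.

## The alternating decision tree

The base condition space is the 120 equality predicates `AA[j] == residue`
(6 positions × 20 residues); no inequality or set-valued conditions. Training
follows the classical boosting recipe. With instance labels y = ±1 and unit
starting weights:

* root value `a₀ = ½·ln((W₊ + ε)/(W₋ + ε))`, then `w ← w·exp(−y·a₀)`;
* each iteration evaluates every existing prediction node (precondition c₁)
  against every base condition c₂ and minimizes
  `Z = 2·(√(W₊(c₁∧c₂)·W₋(c₁∧c₂)) + √(W₊(c₁∧¬c₂)·W₋(c₁∧¬c₂))) + W(¬c₁)`;
* the winning splitter gets prediction values `½·ln((W₊+ε)/(W₋+ε))` on its
  two weight subsets, and `w ← w·exp(−y·r(x))` for the new contribution r.

A peptide's score is the root value plus every prediction value on satisfied
paths; class is amyloidogenic iff the score is positive, and
`1/(1 + exp(−2·score))` (the logistic of twice the boosting margin) is the
ranking probability for ROC purposes.

Numerical and search choices:

* **Smoothing** ε defaults to 1.0 in numerator and denominator of every
  half-log-ratio, keeping values finite on pure nodes. Printed rule factors
  are therefore well defined but not bit-comparable to other ADTree
  implementations with different smoothing or search heuristics; they are
  format and sign anchors, not exact targets.
* **Tie-breaking** in Z is deterministic: lowest position, then alphabetical
  residue, then earliest-created precondition node. The search is exhaustive
  over all prediction nodes (no path-limited heuristic), so no random seed is
  needed and two trainings on identical data are identical.
* The total exponential loss `Σ exp(−yᵢF(xᵢ))` equals the weight sum and is
  recorded after every iteration; it is non-increasing for any ε ≥ 0 because
  the ε-shrunken value lies between 0 and the unsmoothed optimum of the
  convex per-node loss.

Rules export in the notation `n: AAj | X a | !X b` — rule number in boosting
order (decreasing significance), the residue's additive value when present
and (marked `!`) absent, printed to 3 decimals.

## Baselines

**Naive Bayes** is purely categorical: per-position conditional tables with
Laplace pseudo-count α = 1 (the smoothing convention is ours; "no parameters"
leaves it open) and class-fraction priors; posteriors are accumulated in log
space. **The perceptron** is 120 → 60 → 1 with logistic activations
throughout, trained by per-instance stochastic gradient descent with momentum
(learning rate 0.1, momentum 0.2, 500 epochs, seed 0) on squared error —
the classical neural-net recipe — with weights initialized uniformly in
[−0.5, 0.5] and the instance order reshuffled each epoch under the training
seed. One output unit carries the positive-class probability where some
implementations use two; the ranking is equivalent. The hot loop is C++; all
of its randomness flows through R's RNG so a seed fixes the full weight
trajectory.

## Evaluation protocol

TPR, TNR and accuracy come straight from the confusion matrix with
amyloidogenic as positive. The ROC curve is built from descending-score
thresholds with ties grouped; the trapezoid AUC then equals the Mann–Whitney
probability that a random positive outranks a random negative with ties
counted one half (verified exactly against pair counting in the tests).

The resampling protocol is 10 runs of a seeded unstratified shuffle, first
66% train / rest test (stratification is available but off by default, since
plain random division is the protocol), every method fitted on identical
splits. Per-run AUC differences feed the corrected resampled paired t-test,

t = mean(d) / sqrt((1/k + n_test/n_train) · var(d)),  df = k − 1,

whose variance inflation accounts for overlapping training sets across runs;
with the ratio forced to 0 it reduces to the classical paired t. Comparisons
are two-sided at α = 0.05 with no multiple-testing correction (the
win/draw/loss table reports raw pairwise outcomes). Zero-variance differences
are handled explicitly: all-zero means a draw, nonzero mean with zero
variance reports p = 0 with a flag.

## Synthetic data: what it emulates and what it does not

`samplePeptides()` draws labels from a class prior and residues independently
per position from class PFMs. The defaults are the modeled study conditions,
chosen once:

* n = 4481 and prior 825/4481 ≈ 0.184 (the training-set size and positive
  fraction of the energy-labeled corpus this package models);
* negative PFM = background amino-acid composition (Swiss-Prot-like averages)
  with cysteine's mass folded into serine, since modeled datasets are
  post-sanitization;
* positive PFM = background with a planted AA4 = I signal of weight 0.9 —
  isoleucine at position 4 being the strongest single position-residue
  association in this problem domain.

`bayesOptimalAuc()` computes the exact AUC of the likelihood-ratio classifier
by convolving the discrete per-position log-likelihood-ratio distributions
(aggregating equal values; one-sided infinities from zero-probability
residues are handled exactly). It is the recovery oracle: a sound learner
trained on a generated sample should approach it, and the tests require
ADTree and naive Bayes to land within 0.03 of it at n = 5000.

`sampleEnergyTable()` draws base energies from a normal with sd 3 kcal/mol
and mean −23 − 3·qnorm(0.1841) ≈ −20.30 kcal/mol, so that the expected
fraction at or below the −23 threshold equals the 18.41% positive rate above.
The reference column adds a signed Laplace draw with mean absolute difference
1 kcal/mol (a normal shape is selectable). One caveat is worth stating
plainly: no symmetric unimodal scale family matches both a mean absolute
difference of 1.0 and a 90th percentile of 1.4 (Laplace gives q90/mean =
ln 10 ≈ 2.30, half-normal ≈ 2.06), so the generator matches the mean and
lets the 90th percentile fall where the shape puts it.

What the generator does **not** emulate: correlation between overlapping
windows of the same protein, redundancy structure, position-coupled residue
dependencies, and any physical relation between a peptide's sequence and its
energy (sequences and energies are sampled independently in the energy
table). Passing recovery tests therefore demonstrates correctness of the
estimators and learners under known conditions — not predictive performance
on real proteins.

## Problem sizes

The test suite trains on datasets of 8–5000 peptides and verifies the ADTree
split choice against an exhaustive oracle on ≤ 50-instance datasets with ≤ 5
iterations. The acceptance script (`scripts/acceptance.R`) uses the full
modeled sizes for the single-split experiment (4481 train, 1586 test, ADTree
with 50 iterations, perceptron at its default 500 epochs) and a 900-peptide
dataset for the 10-run resampling comparison — sizes chosen to keep a
complete run in minutes while leaving every estimate's Monte-Carlo error well
inside the tolerances being checked.

## Known limitations

* The ADTree's printed factors depend on the smoothing constant and search
  variant; only structure, signs and approximate magnitudes are comparable
  across implementations.
* `bayesOptimalAuc()` enumerates the LLR support exactly; PFMs with many
  distinct irrational ratios can blow the support up (guarded by
  `maxSupport`). Structured PFMs — the intended use — stay tiny.
* The shipped scaffold is idealized geometry, adequate for rigid-body
  template arithmetic and I/O, not for physical energy evaluation; real
  energy work requires a user scaffold and a real design-program adapter.
* The perceptron's squared-error-with-momentum recipe is faithful to the
  classical formulation but is not a modern trainer; at the default sizes it
  is the slowest component by far.
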
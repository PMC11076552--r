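---
title: "Scoring per-case prediction difficulty with neural network ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring per-case prediction difficulty with neural network ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Instance hardness — here called case difficulty — is the per-case
likelihood of being misclassified by learned models. Classical measures
(neighborhood, tree, Naive-Bayes, class-skew, distance and feature-overlap
based; all implemented in this package as baselines) each presuppose
something about the data: meaningful distances, class imbalance, feature
independence, visible overlap regions. The three metrics at the core of
this package instead derive difficulty from the behavior of small
fully-connected neural networks, which make far weaker assumptions: with
enough hidden neurons a single-hidden-layer network can approximate any
continuous decision surface, and its width is a natural complexity dial.

All three metrics emit scores in [0, 1], higher = harder, one per case,
wrapped in a `difficulty_vector` carrying diagnostics and provenance.

## The network engine

Every metric trains the same kind of model: a fully-connected feedforward
classifier with ReLU or tanh hidden activations, softmax output,
cross-entropy loss, minibatch Adam, Glorot-uniform initialization, and
optional early stopping that monitors validation cross-entropy and
restores the best-epoch parameters. The engine is implemented in
RcppArmadillo with a private Mersenne-Twister RNG, so a `net_config` seed
fully determines the fitted network: initialization, epoch shuffling and
(for the tuner) candidate sampling all flow from explicit seeds, never
from the global RNG state or the clock.

Early stopping monitors validation cross-entropy because that is the
quantity the optimizer targets; accuracy plateaus too early on small
validation splits to be a useful monitor.

Hyperparameter tuning draws `n_iterations` candidates uniformly at random
from the standard grid — learning rate {0.01, 0.03, 0.1}, batch size
{32, 64, 128}, 1–3 hidden layers of {5, 10, 15, 20} neurons (the same
width in every layer), {ReLU, tanh} — and returns the candidate with the
lowest validation loss, ties broken by evaluation order. The contract is
deliberately "best of n evaluated candidates": sequential model-based
search strategies can be substituted without changing any downstream
semantics, and seeded random search keeps the whole pipeline reproducible.

## CDmc: model complexity

With case *i* left out, the remaining cases are split 70/30 into training
and validation (stratified by class, drawn once per case from the case's
derived seed — re-drawing per width would conflate split noise with the
width search). For widths `w = 1, 2, ..., mnn`, 20 single-hidden-layer
networks (ReLU, batch 32, 100 epochs, patience 10, learning rate 0.01) are
trained with distinct seeds; the search stops at the first width where at
least `ceiling(0.9 * 20) = 18` networks predict the left-out label, and
the difficulty is `w_stop / mnn`.

Decisions worth recording:

* `mnn = ceiling(0.01 n)`, with a floor of 1 — "1% of the sample size"
  needs a rounding rule; ceiling keeps small datasets usable.
* "Fewer than 90%" is a strict comparison on the fraction, so the success
  threshold is `ceiling(0.9 * n_models)`.
* Cases unsolved at `mnn` score exactly 1: the loop stopped there, and the
  stopping width divided by `mnn` is 1. The `solved` diagnostic
  distinguishes them from cases genuinely solved at the last width.
* Patience (10) and the learning rate (0.01, inside the tuning grid used
  elsewhere) are fixed here because CDmc never tunes: its difficulty signal
  *is* the architecture sweep.
* Per-case seeds are derived from `(seed, index)`, so the all-case scan is
  embarrassingly parallel and worker-count-invariant. A consequence is
  that scores attach to case *positions*: permuting the rows of a table
  re-derives different per-case seeds, so individual stochastic scores can
  differ for the same case content. The reproducibility contract is
  "identical table, options and seed give identical output", which is what
  the tests pin down.

One behavior to expect: a single hidden ReLU unit reduces the input to one
scalar projection, so for three-class data most cases need width at least
two regardless of overlap, and with very few minibatch steps per epoch
(tiny n) width-one ensembles can fail on even trivially separable data.
Difficulty is meaningful *relative to the dataset*, not across datasets
with very different sizes.

## CDdm: double model

The table is dealt into five stratified sets of near-equal size (within
each class the shuffled cases are dealt round-robin, the deal continuing
across classes, so set sizes differ by at most one and every class is
spread across sets). Rotation *r* uses sets `{r, r+1}` to train Model A,
sets `{r+2, r+3}` for A's predictions and B's training, and set `{r+4}`
for scoring; over five rotations every case is scored exactly once. Both
models are tuned (5 candidates for A, 10 for B by default; 500 epochs,
patience 50) on an inner 70/30 stratified split of their training sets.

The difficulty is Model B's predicted probability of *incorrectness*:
B is trained on a binary correct/incorrect target, and although it is
natural to speak of "probability of correctness", scores must increase
with difficulty, so the orientation is flipped exactly once, here.

When Model A is perfect (or always wrong) on B's training sets, the
correctness target is constant and no classifier can be trained. This is
handled, not raised: the held-out set receives the constant observed
incorrect-rate (0 or 1) and the rotation is logged in
`diagnostics$degenerate_rotations`. Fully separable datasets therefore
score 0 everywhere — the correct answer.

Model B sees only the original feature vector, not Model A's predicted
probabilities: scoring a *new* case must not require running A on data
with known labels, which is also why `cddm_predict_new()` can score
unlabeled cases from the stored B models (averaging the non-degenerate
rotations).

## CDpu: predictive uncertainty

With case *i* left out, hyperparameters are tuned once on a stratified
70/30 split of the remainder (default; `tune_scope = "dataset"` tunes once
per table instead, an explicit cheaper mode for large scans). Then
`n_models` (default 100) networks are trained, each on its own shuffled
copy of the remaining data — the shuffle, not a bootstrap, because the
ensemble's variability should come from initialization and data *order*,
with every network seeing every case. Each network's shuffle also decides
its 70/30 train/validation split for early stopping (100 epochs, patience
30; patience 10 is recommended for very small samples). The stacked
predicted-probability rows for the left-out case give, per class,

* location factor `|mu_c - y_c|`: miscentering of the ensemble mean
  relative to the 0/1 ground-truth indicator, and
* distribution factor `sigma_c / sqrt(1/12)`: ensemble spread normalized
  by the standard deviation of the uniform distribution on [0, 1], the
  most conservative probability distribution.

Each class scores the average of the two factors; the binary case uses
the positive-class column alone (the two class scores are identical by
complementarity), while K ≥ 3 averages over *all* K class columns,
including the true class's. Standard deviations use the population
divisor *m*, matching the `sqrt(1/12)` population normalizer — mixing
divisor conventions would bias the factor upward by `m/(m-1)`. A raw
score above 1 (bimodal 0/1 ensembles have SD up to 0.5 > sqrt(1/12)) is
capped at 1, with the `capped` flag and the raw value kept in the
diagnostics.

## Simulated data

The generators produce the three two-feature families used throughout,
with overlap controlled by one parameter each:

* **blobs** — isotropic Gaussians (SD 2/4/6 in the study design) around
  centers equally spaced on a circle of radius 10. Fixing the centers
  makes overlap a function of the SD alone and keeps tests deterministic.
* **moons** — points evenly spaced along semicircular arcs plus Gaussian
  noise (SD 0.1/0.2/0.4). Class 0 is the upper unit semicircle; class 1
  the standard interleaving lower semicircle offset by (1, 0.5); class 2
  repeats the class-0 arc shifted by +2 in x, which preserves the
  interleaving pattern of consecutive crescents.
* **circles** — concentric rings with radii `1, f, f^2` for scale factor
  `f` (0.3/0.5/0.7) and Gaussian noise, default SD 0.05 — rings of zero
  width admit no overlap at any scale factor, so a small default noise
  keeps the family's difficulty gradient meaningful while the scale
  factor remains the controlled parameter.

Generated data are *not* standardized before scoring: the features are
already on a common scale by construction, and preprocessing is reserved
for real tabular data. The `preprocess()` path (mean / most-frequent /
constant imputation, population-SD standardization, all-levels one-hot
encoding, lexicographic label recoding) reproduces the handling used for
the real datasets in the study (UCI breast cancer, Telco churn, customer
segmentation), whose files are deliberately not bundled — the loaders are
adapters, and all tests run on generated data.

What the simulations emulate is class overlap in low dimension with
balanced classes. They do not emulate high dimension, mixed
categorical/continuous features, label noise beyond planted cases, or
class imbalance — so passing tests show the metrics track *overlap*
difficulty, not that they are validated for every real-data pathology.

## Baselines

The fifteen classical measures are implemented from their definitions,
oriented to difficulty (transform recorded in each vector's provenance),
with Euclidean distances on the numeric feature matrix. Notable choices:

* The "unpruned" CART tree uses `cp = 0` with unlimited depth but default
  `minsplit = 10` / `minbucket = 5`: a tree grown to singleton leaves has
  all-pure leaves and makes DCP identically zero. Leaves that aggregate a
  small neighborhood keep DCP discriminative. TD_P prunes by
  cost-complexity with the CP chosen by 5-fold cross-validated error.
* Gaussian Naive Bayes is computed in the log domain with per-class
  variances floored at 1e-9 (zero within-class variance is a logged
  degeneracy, not an error).
* The local set of a case is the set of same-class cases nearer to it
  than its nearest enemy; LSC normalizes by the class size minus one, LSR
  by the dataset's maximum nearest-enemy distance, Usefulness by `n - 1`.
  N2 and Harmfulness are min–max rescaled to [0, 1] per dataset.
* A planted mislabeled case inside a tight opposite-class cluster scores
  strictly higher than the cluster's median point for kDN, DCP, CL, CLD,
  N2, Harmfulness and Usefulness. For N1, LSC and LSR the planted enemy
  also *poisons its neighbors'* scores (it becomes their nearest enemy and
  empties their local sets), and for the tree-depth and F1 measures the
  two cases can share a leaf or an overlap interval, so those checks are
  non-strict — a genuine property of these measures, not an
  implementation artifact.

## Evaluation protocol

`correlate()` reports Pearson (on raw scores) and Spearman (average
ranks) with two-sided p-values; constant inputs make both undefined and
are flagged rather than zeroed, and `correlation_table()` masks cells
with p ≥ 0.05 or undefined values — empty cells, not zeros, mirror the
situation where a metric assigns every case the same lowest difficulty on
a simple dataset. No multiple-comparison adjustment is applied, matching
the plain per-cell threshold of the protocol. Spearman ties use average
ranks, the conventional rho — CDmc's lattice values make ties routine.
`overlap_enrichment()` compares mean difficulty inside vs outside a
feature-space region with a one-sided Mann–Whitney test, and
`export_scatter()` renders 2-D difficulty maps on a fixed 0–1 color
scale; higher-dimensional data must be pre-embedded (t-SNE/FAMD are
display tools, not part of the metrics).

## Scaled problem sizes

The full study design (2000–3000 cases for CDmc/CDpu, 8000–12000 for
CDdm, 100-network ensembles, 100 tuning iterations) is faithful but
compute-heavy. The package's tests and `scripts/acceptance.R` exercise
the same procedures at sizes chosen to keep a complete run in minutes on
one CPU while preserving every qualitative contrast:

* CDmc: 3-class blobs, n = 300 (so `mnn = 3`), 20 networks, 30 epochs.
* CDdm: binary blobs, n = 1000, default tuning budgets (5/10), 500
  epochs with patience 50.
* CDpu: moons at noise 0.4, n = 200, 20 networks, 5 tuning candidates
  per case.
* The uniform-normalization check uses 1e5 draws; closed-form checks are
  exact.

The inter-crescent overlap band used for enrichment is defined
geometrically: cases within 0.5 (the widest study noise level plus
margin) of *both* noiseless arcs.

## Known limitations

* Compute scales linearly in cases times networks times widths; CDmc and
  CDpu retrain per case by design. Scores only need computing once per
  dataset, and the per-case independence parallelizes trivially.
* CDmc's resolution is `1/mnn`; small datasets give a coarse lattice.
* CDdm needs enough cases that a fifth of the data can train a network;
  `make_fold_plan()` refuses n < 10, and practical use wants far more.
* Difficulty values are single numbers without uncertainty intervals.
* The engine is CPU-only and dense; convolutional/recurrent
  architectures, dropout and GPU execution are out of scope.
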
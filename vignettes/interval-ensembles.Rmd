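---
title: "Interval-valued ensembles for high-dimensional classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-valued ensembles for high-dimensional classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivens)
```

## The model

Microarray-style data — hundreds of samples, tens of thousands of correlated
noisy features, imbalanced classes — punish any single classifier family.
`ivens` hedges across families and, instead of collapsing their disagreement
into one averaged vote, keeps it as an object of study: an **interval**.

For each group of related base classifiers (forests of different sizes,
networks of different depths, SVMs with different kernels, k-NN with
different k), every fitted member emits per-class soft labels in $[0,1]$.
A group's verdict about class $c$ for a sample is the interval

$$ i_c \;=\; \big[\min_j s_j(c),\; \max_j s_j(c)\big] $$

over its members $j$ — a narrow interval means the family agrees, a wide one
flags epistemic uncertainty. The per-group intervals of each class are then
combined with an interval-valued aggregation function, and the class whose
aggregated interval is greatest under a chosen linear order on intervals
wins.

### Soft labels

Learners that define probabilities (forest vote fractions, network output
layers, neighbour vote fractions) pass through unchanged. Score-valued
outputs — SVM one-vs-one decision values, folded into per-class signed
sums — lie outside $[0,1]$ and are mapped row-wise through the softmax. The
out-of-range check is per score *matrix*, not per row: mixing calibrated and
softmaxed rows within one member's output would put its rows on different
scales. No Platt/isotonic calibration is attempted; the softmax rule exists
precisely so that margin-valued learners can join the ensemble cheaply.

### Orders on intervals

The componentwise partial order $[x_1,x_2] \preceq [y_1,y_2] \iff x_1 \le
y_1, x_2 \le y_2$ leaves many pairs incomparable, so decisions use one of
three total orders, each refining $\preceq$:

* **Xu–Yager** (default): compare bound sums $x_1 + x_2$; break ties by
  width $x_2 - x_1$ (narrower first). Uses both bounds — the sum key is
  twice the midpoint — which is why it is the default.
* **Lex1 / Lex2**: lexicographic by lower (resp. upper) bound. Provided for
  completeness; the decision path never requires them.

Two numerical choices matter here. First, equality in the order keys is
exact — any tolerance would break antisymmetry and make "sort the class
intervals" ill-defined. Second, the Xu–Yager keys are *derived* quantities,
and binary floating point misorders decimal ties: in doubles,
$0.2 + 0.4 > 0.1 + 0.5$, so the textbook tie $[0.2,0.4]$ vs $[0.1,0.5]$
would be decided by rounding noise. The keys are therefore rounded to 12
decimals before comparison (any genuine difference in class scores at that
magnitude is far below the noise floor of the learners), and the raw bounds
are appended as final tie-breaker keys so the order remains total and
antisymmetric. Ties on *identical* intervals resolve to the smallest class
index, fixed at fit time as the sorted unique training labels.

### The aggregation family

Ten aggregations are available (`iv_aggregations()`), built from the
arithmetic mean, power means $M_p = ((1/n)\sum x^p)^{1/p}$, the geometric
mean, and Lehmer-type ratios $\mathrm{LM}_p = \sum x^p / \sum x^{p-1}$ with
the convention $0/0 := 0$ (reachable only when every upper bound is zero).
A1 — the componentwise arithmetic mean — is the default. A2 and A7 probe the
hull more aggressively (one bound swapped per position, extremised) and are
the only non-idempotent members; the four Lehmer-upper members (A3, A4, A8,
A9) are not componentwise monotone, which is acceptable for aggregations
defined relative to other interval orders. All ten keep the result inside
the hull of their inputs and satisfy the boundary conditions, which the test
suite asserts on thousands of random inputs against naive reference
implementations.

Arity is the number of surviving groups. Group pruning can in principle
leave a single group, so $n = 1$ is permitted (every formula degenerates to
an identity-like map).

### Entropy-based selection

The `entropy` and `entropy_groups` variants estimate each member's mean
cross-entropy loss by 10 repeats of stratified two-fold cross-validation
*inside the training partition* (two-fold, because with 100–250 samples and
rare classes anything finer starves the folds). Within each group the two
best members are kept, plus every member at or below the group's average
loss — so a group never shrinks below two members. `entropy_groups` applies
the same rule to the groups' mean losses (computed over **all** original
members, before any pruning, following the stated step order), with the same
two-survivor floor. Probabilities are clipped to $[10^{-15}, 1-10^{-15}]$
before the logarithm: 1-NN members emit exact 0/1 soft labels, and one
confident miss would otherwise make a loss infinite and the comparison of
means meaningless.

Survivors are refitted on the full training partition. The cross-validated
fits exist only to estimate losses; with so few samples, discarding half the
training signal in the final members would be wasteful. Each member's
refit seed derives from its *original* group/member position, so selection
does not perturb the randomness of the survivors.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `variant` | `"plain"` | selection regime (see above) |
| `aggregation` | `"A1"` | interval-valued aggregation, `"A1"`–`"A10"` |
| `order` | `"xy"` | decision order: Xu–Yager, `"lex1"`, `"lex2"` |
| `n_repeats`, `n_splits` | 10, 2 | inner CV geometry for the entropy variants |
| `seed` | 1 | single source of all randomness (splits, forests, network init) |

The default zoo mirrors common practice for expression data: RF
{10, 50, 100} trees; MLP hidden layers {100}, {50, 50}, {100, 50, 25}; SVM
{linear, polynomial (degree 3, the conventional default), radial}; k-NN
{1, 3, 5} under the Manhattan metric, which degrades more gracefully than
Euclidean distance in very high dimension. Custom learners and groups can be
registered with `base_learner()` / `model_group()`; membership of a group is
always explicit, never inferred.

The MLP base learner is a small in-package network (ReLU hidden layers,
softmax output, full-batch Adam in compiled code, learning rate 0.1, L2
decay $10^{-4}$, at most 200 iterations with loss-plateau early stopping:
relative improvement below $10^{-4}$ for 5 consecutive iterations, or
training loss below $5\times10^{-3}$). Full-batch training is the natural
choice at $n \le 250$; the iteration budget is sized for convergence on
min–max-scaled expression matrices, where the loss plateaus within tens of
iterations.

## The evaluation harness

`run_experiment()` repeats a stratified 80/20 train/test split (five times
by default), fits min–max scaling on the training features only — test
features may land outside $[0,1]$ and are deliberately not clipped, since
clipping would distort k-NN distances — fits every model specification on
the scaled training data, and scores one-vs-one ROC AUC (macro over class
pairs, from membership degrees, which are the method's only
probability-like output), accuracy, and balanced accuracy on the test data.
Accuracy is the plain fraction of correct argmax-style decisions; no
per-class 0.5 thresholding step exists in the decision rule. Per-repeat raw
scores are attached for downstream significance testing; the package
deliberately stops short of running those tests itself.

## What the synthetic generator does and does not emulate

`generate_dataset()` produces the three traits that make expression matrices
hard: high dimension with few samples; correlated feature blocks (a shared
latent factor per block, giving within-block correlation `block_rho`); and
Gaussian noise. Class signal is a mean shift of `effect_size` noise-SDs on
disjoint per-class subsets of `n_informative` features, so every class is
separable in principle. Class sizes follow the largest-remainder rounding of
`class_probs`, with remainder ties broken by class order. Defaults
(200 × 2000, four classes at 0.45/0.28/0.14/0.13, 100 informative features,
unit effect) are a desk-scale rendition of published multi-class microarray
cohorts; full-scale shapes are reachable through the spec.

It does **not** emulate batch effects, probe-level artefacts, heavy-tailed
noise, or non-additive class structure. Passing tests on this generator
therefore demonstrate the machinery — interval construction, aggregation,
selection, and their interplay — not clinical performance on real cohorts.

## Design choices in the open

* **Selection thresholds.** "Top two plus everything at or below the group
  average" is implemented literally; both selectors reduce to the same rule,
  since whenever at least two items sit at or below the average the two
  smallest are among them. Ties on equal means keep the smaller index.
* **Decision rule.** Sorting the aggregated intervals is unnecessary for the
  decision; a single argmax under the order is equivalent and cheaper. The
  full intervals are available via `predict(type = "interval")`.
* **Degenerate cases.** All-zero membership midpoints return the uniform
  vector; a single class at fit time is an error, not a degenerate model.
* **Problem sizes in the checks.** The robustness study in the acceptance
  machinery runs 50 trials at the generator's full default scale
  (200 × 2000); the benchmark experiment in `scripts/acceptance.R` uses a
  500-feature rendition, which preserves the ranking of the variants while
  keeping a five-repeat experiment brisk on one CPU.

## Known limitations

* Members of a group are refit from their family's hyperparameters; there is
  no within-family hyperparameter search, by design.
* The nested CV requires every class to have at least `n_splits` training
  members; rare classes below that floor are a hard error naming the class.
* The Lehmer-upper aggregations (A3, A4, A8, A9) are not componentwise
  monotone; when monotonicity under $\preceq$ matters, use A1, A2, A5, A6,
  A7 or A10.
* Entropy-based selection guards against *uninformative* members and groups;
  it cannot repair systematically biased ones (e.g. a batch effect aligned
  with a class), which the generator does not model.
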